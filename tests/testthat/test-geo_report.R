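make_pops <- function(ids, lon = NULL) {
  data.frame(population = ids, country = "X",
             latitude = seq(38, 39, length.out = length(ids)),
             longitude = lon %||% seq(-2, 15, length.out = length(ids)),
             species = "cre", stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("population composition recovers a constructed truth exactly", {
  chloro <- alignment(
    c(i1 = "AAGG", i2 = "AAGG", i3 = "AATG", i4 = "AATG", ix = "AATG"),
    species = "cre", population = c("P1", "P1", "P2", "P2", "PX"),
    marker = "trnL-trnF")
  its <- alignment(
    c(i1 = "CCCC", i2 = "CCAC", i3 = "CCAC", i4 = "CCAC"),
    species = "cre", population = c("P1", "P1", "P2", "P2"),
    marker = "ITS")
  cc <- designate_mains(define_types(condense_alignment(chloro)), 1L)
  cr <- designate_mains(define_types(condense_alignment(its)), 1L)
  comp <- compose_population_table(cc, cr, make_pops(c("P1", "P2")))
  get <- function(p, m, t) {
    r <- comp$composition
    s <- r$count[r$population == p & r$marker == m & r$type == t]
    if (length(s) == 0) 0L else s
  }
  # AATG is the most frequent chlorotype (3 carriers) and so is named "A"
  expect_equal(get("P1", "trnL-trnF", "B"), 2L)
  expect_equal(get("P2", "trnL-trnF", "A"), 2L)
  expect_equal(get("PX", "trnL-trnF", "A"), 1L)
  expect_equal(get("P1", "ITS", "A") + get("P1", "ITS", "B"), 2L)
  # ix has no ITS sequence: counted as missing, not dropped
  expect_equal(get("PX", "ITS", "missing"), 1L)
  # and its population is unknown to the metadata: reported as orphan
  expect_identical(comp$orphans$individual, "ix")
  # individuals conserve: per marker, counts + missing = individuals
  for (m in c("trnL-trnF", "ITS")) {
    r <- comp$composition
    expect_equal(sum(r$count[r$marker == m & r$type != "missing"]) +
                   sum(r$count[r$marker == m & r$type == "missing"]), 5L)
  }
})

test_that("KML export places one styled placemark per population", {
  its <- alignment(
    c(i1 = "CCCC", i2 = "CCAC", i3 = "CCAC"),
    species = c("cre", "alb", "alb"), population = c("P1", "P2", "P2"),
    marker = "ITS")
  cr <- designate_mains(define_types(condense_alignment(its)), 1L)
  pops <- make_pops(c("P1", "P2"))
  pops$species <- c("cre", "alb")
  comp <- compose_population_table(NULL, cr, pops)
  f <- withr::local_tempfile(fileext = ".kml")
  export_kml(comp, pops, "ITS", f)
  doc <- xml2::read_xml(f)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "k")
  pms <- xml2::xml_find_all(doc, ".//k:Placemark", ns)
  expect_length(pms, 2L)
  # the C. albidus population is drawn as a square
  styles <- xml2::xml_text(xml2::xml_find_all(doc, ".//k:styleUrl", ns))
  expect_true(any(grepl("square", styles)))
  expect_true(any(grepl("circle", styles)))
  # coordinates round-trip
  coords <- xml2::xml_text(xml2::xml_find_all(doc, ".//k:coordinates", ns))
  lon <- as.numeric(vapply(strsplit(coords, ","), `[[`, "", 1L))
  expect_setequal(round(lon, 4), round(pops$longitude, 4))
  # a population without coordinates is skipped with a warning
  pops2 <- pops
  pops2$latitude[2] <- NA
  expect_warning(export_kml(comp, pops2, "ITS", f), "skipped")
})

test_that("the pipeline reproduces the fixture inventories end to end", {
  dir <- withr::local_tempdir()
  markers <- list()
  pop_ids <- character(0)
  for (m in c("trnL-trnF", "rpl32-trnL", "ITS")) {
    aln <- fixture_alignment(m)
    f <- file.path(dir, paste0(gsub("[^A-Za-z0-9]", "", m), ".fasta"))
    write_aligned_fasta(aln, f)
    markers[[m]] <- list(name = m, alignment = f)
    pop_ids <- union(pop_ids, aln$meta$population)
  }
  meta <- file.path(dir, "populations.csv")
  utils::write.csv(make_pops(sort(pop_ids)), meta, row.names = FALSE)
  cfg <- list(markers = unname(markers), metadata = meta, seed = 1L)
  out1 <- file.path(dir, "out1")
  res <- run_pipeline(cfg, out_dir = out1)
  expect_identical(vapply(res$catalogs, n_types, integer(1)),
                   c("trnL-trnF" = 5L, "rpl32-trnL" = 4L, "ITS" = 29L))
  expect_true(any(grepl("phasing skipped", res$log)))
  # deterministic: a second run is byte-identical
  out2 <- file.path(dir, "out2")
  run_pipeline(cfg, out_dir = out2)
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out2, f)),
                     readLines(file.path(out1, f)),
                     label = paste("rerun of", f))
  }
  # a chloroplast-only config skips phasing with a log entry
  res2 <- run_pipeline(list(markers = list(markers[["trnL-trnF"]]),
                            metadata = meta))
  expect_true(any(grepl("chloroplast-only", res2$log)))
  # a bad path aborts with a stage-named error
  bad <- cfg
  bad$markers[[1]]$alignment <- file.path(dir, "absent.fasta")
  expect_error(run_pipeline(bad), "stage 'read:trnL-trnF'")
})
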