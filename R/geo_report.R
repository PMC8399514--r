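#' @name geo_report
#' @title Per-population haplotype composition and map export
NULL

# default rule linking a catalog sequence id to its individual: phased rows
# carry suffixes "_p1"/"_p2"/"_dom" added by the pipeline
default_individual_of <- function(id) sub("_(p1|p2|dom)$", "", id)

# per-individual type sets for one catalog
.individual_types <- function(cat, individual_of) {
  if (length(cat$assignment) == 0L)
    return(data.frame(individual = character(0), type = character(0)))
  ind <- individual_of(names(cat$assignment))
  df <- unique(data.frame(individual = ind, type = unname(cat$assignment),
                          stringsAsFactors = FALSE))
  df[order(df$individual, df$type), , drop = FALSE]
}

#' Compose per-population haplotype tables and clade calls
#'
#' Joins the chloroplast and ITS catalog assignments on individuals (an
#' individual may contribute two ITS sequences when heterozygous), counts
#' types per population and marker, and calls each individual's clade via
#' [assign_clade()]. Individuals missing one marker are counted under
#' `"missing"` for that marker and are still clade-called on the marker
#' present; individuals whose population is absent from the metadata are
#' listed in an orphans table, never dropped silently.
#'
#' @param cat_chloro,cat_ribo `cis_catalog`s with designated mains and
#'   per-sequence assignments (`cat_ribo` may be `NULL` for a
#'   chloroplast-only run).
#' @param pops population metadata from [read_population_table()].
#' @param individual_of function mapping a sequence id to its individual id.
#' @param ... passed to [assign_clade()] (`em_chlorotype`, `wm_chlorotypes`,
#'   ...).
#' @return list with `composition` (population x marker x type counts),
#'   `clades` (one row per individual), `orphans`.
#' @export
compose_population_table <- function(cat_chloro, cat_ribo, pops,
                                     individual_of = default_individual_of,
                                     ...) {
  cats <- list()
  if (!is.null(cat_chloro)) cats[[cat_chloro$marker]] <- cat_chloro
  if (!is.null(cat_ribo)) cats[[cat_ribo$marker]] <- cat_ribo
  if (length(cats) == 0L) stop("need at least one catalog", call. = FALSE)

  per_ind <- lapply(cats, .individual_types, individual_of = individual_of)
  pop_of <- character(0)
  for (cat in cats) {
    if (is.null(cat$meta)) next
    p <- stats::setNames(cat$meta$population, individual_of(cat$meta$id))
    pop_of[names(p)] <- p
  }
  individuals <- sort(unique(unlist(lapply(per_ind, function(d) d$individual))))

  comp <- list()
  for (m in names(cats)) {
    d <- per_ind[[m]]
    missing_ind <- setdiff(individuals, d$individual)
    d <- rbind(d, data.frame(individual = missing_ind,
                             type = rep("missing", length(missing_ind))))
    d$population <- unname(pop_of[d$individual])
    agg <- stats::aggregate(cbind(count = rep(1L, nrow(d))) ~ population + type,
                            data = d, FUN = sum)
    agg$marker <- m
    comp[[m]] <- agg[, c("population", "marker", "type", "count")]
  }
  composition <- do.call(rbind, comp)
  composition <- composition[order(composition$population, composition$marker,
                                   composition$type), , drop = FALSE]
  rownames(composition) <- NULL

  clades <- NULL
  if (!is.null(cat_chloro) && !is.null(cat_ribo) &&
      !all(cat_chloro$roles$role == "unassigned")) {
    ct <- per_ind[[cat_chloro$marker]]
    rt <- per_ind[[cat_ribo$marker]]
    clades <- data.frame(individual = individuals,
                         population = unname(pop_of[individuals]),
                         chlorotype = ct$type[match(individuals, ct$individual)],
                         ribotypes = vapply(individuals, function(i)
                           paste(rt$type[rt$individual == i], collapse = ","),
                           ""),
                         stringsAsFactors = FALSE)
    clades$clade <- vapply(seq_len(nrow(clades)), function(i) {
      rts <- strsplit(clades$ribotypes[i], ",", fixed = TRUE)[[1L]]
      assign_clade(clades$chlorotype[i], rts[nzchar(rts)],
                   cat_chloro, cat_ribo, ...)
    }, "")
    rownames(clades) <- NULL
  }

  known <- individuals %in% names(pop_of) &
    pop_of[individuals] %in% pops$population
  orphans <- data.frame(individual = individuals[!known],
                        population = unname(pop_of[individuals[!known]]),
                        stringsAsFactors = FALSE)
  list(composition = composition, clades = clades, orphans = orphans)
}

# small fixed KML colour palette (aabbggrr), cycled over sorted type names
.KML_COLOURS <- c("ff0000ff", "ffff0000", "ff00aa00", "ff00ffff", "ffff00ff",
                  "ffffaa00", "ff7700bb", "ff005577", "ff888888", "ff000000")

#' Export a per-population haplotype map as KML
#'
#' One placemark per population (OGC KML 2.2), styled by the population's
#' dominant type for the chosen marker (ties broken by type name); species is
#' encoded by icon shape, squares for *C. albidus* populations and circles
#' otherwise, following the convention of published distribution maps.
#' Populations without coordinates are skipped with a warning.
#'
#' @param comp result of [compose_population_table()].
#' @param pops population metadata.
#' @param marker marker whose composition is mapped.
#' @param path output `.kml` path.
#' @param albidus_species species labels drawn as squares (default `"alb"`).
#' @return `path`, invisibly.
#' @export
export_kml <- function(comp, pops, marker, path, albidus_species = "alb") {
  cc <- comp$composition[comp$composition$marker == marker &
                           comp$composition$type != "missing", , drop = FALSE]
  if (nrow(cc) == 0L) stop("no composition rows for marker ", marker, call. = FALSE)
  types <- sort(unique(cc$type))
  colour <- stats::setNames(rep(.KML_COLOURS, length.out = length(types)), types)

  doc <- xml2::xml_new_root("kml", xmlns = "http://www.opengis.net/kml/2.2")
  d <- xml2::xml_add_child(doc, "Document")
  xml2::xml_add_child(d, "name", paste0(marker, " haplotype distribution"))
  shapes <- c(square = "http://maps.google.com/mapfiles/kml/shapes/placemark_square.png",
              circle = "http://maps.google.com/mapfiles/kml/shapes/placemark_circle.png")
  for (tp in types) {
    for (sh in names(shapes)) {
      st <- xml2::xml_add_child(d, "Style", id = paste0(tp, "_", sh))
      ic <- xml2::xml_add_child(st, "IconStyle")
      xml2::xml_add_child(ic, "color", colour[[tp]])
      xml2::xml_add_child(xml2::xml_add_child(ic, "Icon"), "href", shapes[[sh]])
    }
  }
  for (p in sort(unique(cc$population))) {
    row <- pops[pops$population == p, , drop = FALSE]
    if (nrow(row) == 0L || anyNA(row$latitude[1L]) || anyNA(row$longitude[1L])) {
      warning("population '", p, "' has no coordinates; placemark skipped")
      next
    }
    sub <- cc[cc$population == p, , drop = FALSE]
    dom <- sub$type[order(-sub$count, sub$type)][1L]
    shape <- if (row$species[1L] %in% albidus_species) "square" else "circle"
    pm <- xml2::xml_add_child(d, "Placemark")
    xml2::xml_add_child(pm, "name", p)
    xml2::xml_add_child(pm, "description",
                        paste(sprintf("%s: %d", sub$type, sub$count),
                              collapse = "; "))
    xml2::xml_add_child(pm, "styleUrl", paste0("#", dom, "_", shape))
    xml2::xml_add_child(xml2::xml_add_child(pm, "Point"), "coordinates",
                        paste0(row$longitude[1L], ",", row$latitude[1L], ",0"))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
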