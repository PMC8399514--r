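test_that("superposition forms the IUPAC union of the two templates", {
  expect_identical(superimpose("ACGT", "ACGT")$read, "ACGT")
  expect_identical(superimpose("ACGT", "AGGT")$read, "ASGT")
  expect_error(superimpose("AC-T", "ACGT"), "ungapped")
  # insertion: clean before the insertion point, noisy after
  set.seed(11)
  r1 <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  p <- 220L
  r2 <- paste0(substr(r1, 1, p - 1), "CGTCCT", substr(r1, p, 300))
  tr <- superimpose(r1, r2)
  ch <- strsplit(tr$read, "")[[1]]
  amb <- ch %in% c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  expect_false(any(amb[1:(p - 1)]))
  # downstream density close to the mismatch rate of r1 vs r1 shifted by 6
  c1 <- strsplit(r1, "")[[1]]
  expected_rate <- mean(c1[p:294] != c1[(p - 6):(294 - 6)])
  expect_equal(mean(amb[p:300]), expected_rate, tolerance = 0.15)
})

test_that("heterozygote detection requires a sustained ambiguity run", {
  clean <- mixed_trace(paste(rep("ACGT", 50), collapse = ""))
  det <- detect_heterozygote(clean)
  expect_false(det$is_heterozygous)
  expect_true(is.na(det$breakpoint))
  # one isolated additive site and a clean tail is typed, not phased
  one <- mixed_trace(paste0(paste(rep("ACGT", 20), collapse = ""), "R",
                            paste(rep("ACGT", 20), collapse = "")))
  det1 <- detect_heterozygote(one)
  expect_false(det1$is_heterozygous)
  expect_equal(det1$additive_sites, 81L)
  expect_error(detect_heterozygote(clean, window = 3, min_run = 4), "parameter")
})

test_that("the breakpoint localises the insertion point of a fixture-type pair", {
  # ribotypes differing like A and D: one SNP plus the 6 bp insertion
  set.seed(7)
  r1 <- paste(sample(c("A", "C", "G", "T"), 693, replace = TRUE), collapse = "")
  c2 <- strsplit(r1, "")[[1]]
  c2[475] <- setdiff(c("A", "C", "G", "T"), c2[475])[1]
  p <- 569L
  r2 <- paste0(paste(c2[1:(p - 1)], collapse = ""), "CGTCCT",
               paste(c2[p:693], collapse = ""))
  det <- detect_heterozygote(superimpose(r1, r2))
  expect_true(det$is_heterozygous)
  expect_lte(abs(det$breakpoint - p), 6L)
  expect_equal(det$additive_sites, 475L)
})

test_that("detection is monotone under added ambiguities", {
  set.seed(13)
  for (i in 1:20) {
    pr <- generate_trace_pair(simulation_spec(), seed = i, indel_prob = 1)
    det <- detect_heterozygote(pr$trace)
    expect_true(det$is_heterozygous)
    ch <- strsplit(pr$trace$read, "")[[1]]
    clean_pos <- which(ch %in% c("A", "C", "G", "T"))
    k <- sample(clean_pos, 1)
    ch[k] <- "R"
    more <- mixed_trace(paste(ch, collapse = ""))
    expect_true(detect_heterozygote(more)$is_heterozygous)
  }
})

test_that("base subtraction inverts the forward model exactly", {
  set.seed(5)
  # SNPs only: full-length recovery
  r1 <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  c2 <- strsplit(r1, "")[[1]]
  for (k in c(50, 200, 350)) c2[k] <- setdiff(c("A", "C", "G", "T"), c2[k])[1]
  r2 <- paste(c2, collapse = "")
  res <- subtract_reference(superimpose(r1, r2), r1)
  expect_identical(res$ribotype_2, r2)
  expect_equal(res$resolved_through, 400L)
  # insertion pair: the inserted allele is recovered over the read window
  pr <- generate_trace_pair(simulation_spec(), seed = 99, indel_prob = 1)
  res <- subtract_reference(pr$trace, pr$R1)
  expect_identical(res$ribotype_2, substr(pr$R2, 1, nchar(pr$trace$read)))
  # symmetry in the reference choice
  res_b <- subtract_reference(pr$trace, pr$R2)
  expect_identical(res_b$ribotype_2, substr(pr$R1, 1, nchar(pr$trace$read)))
})

test_that("phasing round-trips over seeded random ribotype pairs", {
  spec <- simulation_spec()
  for (s in 1:150) {
    pr <- generate_trace_pair(spec, seed = 1000 + s)
    w <- nchar(pr$trace$read)
    res <- subtract_reference(pr$trace, pr$R1)
    expect_identical(res$ribotype_2, substr(pr$R2, 1, w))
    res_b <- subtract_reference(pr$trace, pr$R2)
    expect_identical(res_b$ribotype_2, substr(pr$R1, 1, w))
  }
})

test_that("skewed mixtures yield the dominant template only", {
  pr <- generate_trace_pair(simulation_spec(), seed = 3, indel_prob = 1)
  tr <- superimpose(pr$R1, pr$R2, mixing = "skewed", seed = 8, minor_rate = 0.1)
  res <- subtract_reference(tr, pr$R2)
  expect_identical(res$mode, "dominant_only")
  expect_null(res$ribotype_2)
  expect_identical(res$dominant, pr$R1)
})

test_that("reference candidates are tried in geographic order with tie rules", {
  pr <- generate_trace_pair(simulation_spec(), seed = 21, indel_prob = 1)
  decoy <- paste(sample(c("A", "C", "G", "T"), nchar(pr$R2), replace = TRUE),
                 collapse = "")
  cand <- data.frame(id = c("far_correct", "near_decoy", "mid_decoy"),
                     sequence = c(pr$R2, decoy, decoy),
                     distance = c(30, 5, 10))
  res <- phase_individual(pr$trace, cand)
  expect_identical(res$reference_id, "far_correct")
  expect_identical(res$ribotype_2, substr(pr$R1, 1, nchar(pr$trace$read)))
  expect_error(phase_individual(pr$trace, cand[0, ]), "no candidate")
  # equal distance, equally consistent: first by id order
  cand2 <- data.frame(id = c("ref_b", "ref_a"),
                      sequence = c(pr$R2, pr$R2), distance = c(7, 7))
  expect_identical(phase_individual(pr$trace, cand2)$reference_id, "ref_a")
})
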