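test_that("trnL-trnF fixture yields the printed variable columns and events", {
  aln <- fixture_alignment("trnL-trnF")
  expect_equal(aln_length(aln), 427L)
  cols <- extract_variable_columns(aln)
  expect_setequal(cols$position[cols$kind == "substitution"],
                  c(48, 50, 86, 91, 160, 166, 357, 359))
  ev <- group_indel_events(aln, cols)
  expect_equal(ev[, c("start", "end")],
               data.frame(start = c(261L, 262L, 293L, 366L),
                          end = c(261L, 262L, 296L, 366L)))
  ev <- flag_homopolymer_indels(aln, ev)
  expect_identical(ev$homopolymer_attached, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("ITS fixture groups the 6 bp insertion into one event at 569-574", {
  aln <- fixture_alignment("ITS")
  cols <- extract_variable_columns(aln)
  ev <- group_indel_events(aln, cols)
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$start, ev$end, ev$length), c(569L, 574L, 6L))
})

test_that("invariant and minimal alignments behave at the edges", {
  expect_equal(nrow(extract_variable_columns(
    mini_alignment(c("ACGTACGT", "ACGTACGT")))), 0L)
  cols <- extract_variable_columns(mini_alignment(c("ACGTACGT", "ACTTACGT")))
  expect_equal(cols$position, 3L)
  expect_equal(cols$kind, "substitution")
  # single gapped column forms one event of length 1
  aln <- mini_alignment(c("ACGTACGT", "AC-TACGT"))
  ev <- group_indel_events(aln, extract_variable_columns(aln))
  expect_equal(c(ev$start, ev$end, ev$length), c(3L, 3L, 1L))
})

test_that("adjacent gap columns with different gap patterns split into events", {
  aln <- mini_alignment(c("AC--ACGT", "AC-GACGT", "ACTGACGT"))
  ev <- group_indel_events(aln, extract_variable_columns(aln))
  expect_equal(ev$start, c(3L, 4L))
  expect_equal(ev$length, c(1L, 1L))
})

test_that("homopolymer flagging follows the base-and-context rule", {
  # 1 bp T indel inside a TTTTTT context
  aln <- mini_alignment(c("ACGTTTTTTTACG", "ACGTTT-TTTACG"))
  ev <- flag_homopolymer_indels(aln, group_indel_events(
    aln, extract_variable_columns(aln)), base = "T", min_run = 4L)
  expect_true(ev$homopolymer_attached)
  expect_identical(ev$homopolymer_base, "T")
  # 1 bp A indel in a T context is not flagged (base mismatch)
  aln <- mini_alignment(c("ACGTTTATTTACG", "ACGTTT-TTTACG"))
  ev <- flag_homopolymer_indels(aln, group_indel_events(
    aln, extract_variable_columns(aln)), base = "T", min_run = 4L)
  expect_false(ev$homopolymer_attached)
  # insufficient context
  aln <- mini_alignment(c("ACGCTTCGACG", "ACGCT-CGACG"))
  ev <- flag_homopolymer_indels(aln, group_indel_events(
    aln, extract_variable_columns(aln)), base = "T", min_run = 4L)
  expect_false(ev$homopolymer_attached)
  expect_error(flag_homopolymer_indels(aln, ev, min_run = 1L), "min_run")
})

test_that("condensation retains one column per substitution and event", {
  cm <- condense_alignment(fixture_alignment("trnL-trnF"))
  expect_equal(nrow(cm$columns), 12L)
  expect_identical(cm$columns$label[cm$columns$excluded], c("261", "262"))
  expect_equal(sum(!cm$columns$excluded), 10L)
  expect_identical(cm$columns$label[cm$columns$kind == "indel" &
                                      !cm$columns$excluded],
                   c("293-296", "366"))
  # without exclusion every event is retained
  cm_all <- condense_alignment(fixture_alignment("trnL-trnF"),
                               exclude_homopolymer = FALSE)
  expect_equal(sum(!cm_all$columns$excluded), 12L)
  # retained columns never exceed variable columns
  expect_lte(sum(!cm$columns$excluded),
             nrow(extract_variable_columns(fixture_alignment("trnL-trnF"))))
})

test_that("state vectors are a pure function of residues", {
  aln <- fixture_alignment("rpl32-trnL")
  perm <- rev(seq_len(nrow(aln$mat)))
  aln2 <- alignment(
    stats::setNames(apply(aln$mat[perm, ], 1L, paste, collapse = ""),
                    rownames(aln$mat)[perm]),
    species = aln$meta$species[perm], population = aln$meta$population[perm],
    provenance = aln$meta$provenance[perm], marker = aln$marker)
  cm1 <- condense_alignment(aln)
  cm2 <- condense_alignment(aln2)
  expect_identical(cm2$states, cm1$states[perm, , drop = FALSE])
})
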