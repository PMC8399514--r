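test_that("type definition partitions sequences and reproduces the inventories", {
  for (m in c("trnL-trnF", "rpl32-trnL", "ITS")) {
    cm <- condense_alignment(fixture_alignment(m))
    cat <- define_types(cm)
    expected <- c("trnL-trnF" = 5L, "rpl32-trnL" = 4L, "ITS" = 29L)[[m]]
    expect_equal(n_types(cat), expected)
    # partition: every row assigned exactly once, counts sum to rows
    expect_equal(sum(cat$counts), nrow(cm$states))
    expect_setequal(names(cat$assignment), rownames(cm$states))
    # every assigned sequence's retained states equal its type's
    keep <- !cat$columns$excluded
    for (i in seq_len(nrow(cm$states))) {
      tn <- cat$assignment[rownames(cm$states)[i]]
      expect_identical(unname(cm$states[i, keep]),
                       unname(cat$states[tn, keep]))
    }
  }
})

test_that("row permutation leaves the set of type vectors and counts unchanged", {
  cm <- condense_alignment(fixture_alignment("trnL-trnF"))
  cat1 <- define_types(cm)
  perm <- sample(nrow(cm$states))
  cm2 <- cm
  cm2$states <- cm$states[perm, , drop = FALSE]
  cm2$meta <- cm$meta[perm, , drop = FALSE]
  cat2 <- define_types(cm2)
  key <- function(cat) {
    k <- apply(cat$states, 1L, paste, collapse = "|")
    stats::setNames(rowSums(cat$counts), k)[order(k)]
  }
  expect_identical(key(cat1), key(cat2))
})

test_that("sequence assignment is exact-match with nearest-type reporting", {
  cat <- fixture_catalog("trnL-trnF")
  rs <- cat$states[, !cat$columns$excluded]
  expect_identical(assign_sequence(rs["D", ], cat)$type, "D")
  v <- rs["A", ]
  v[1] <- "G"  # one new state on top of A
  res <- assign_sequence(v, cat)
  expect_true(res$novel)
  expect_identical(res$nearest, "A")
  expect_length(res$differing, 1L)
  # the all-consensus vector matches no chlorotype
  cons <- cat$columns$consensus[!cat$columns$excluded]
  expect_true(assign_sequence(cons, cat)$novel)
  expect_error(assign_sequence(rs["A", 1:3], cat), "length")
})

test_that("main designation reproduces the published main types", {
  c3 <- designate_mains(fixture_catalog("ITS"), min_main_count = 10L)
  expect_setequal(c3$roles$name[c3$roles$role == "main"],
                  c("A", "B", "C", "D"))
  tab <- tabulate_counts(c3)
  expect_equal(tab$roles$total[tab$roles$role == "main"], 109L)

  c1 <- designate_mains(fixture_catalog("trnL-trnF"), min_main_count = 10L)
  expect_setequal(c1$roles$name[c1$roles$role == "main"], c("A", "D", "E"))
  # at threshold 1, structural supersets of mains are still demoted
  c1_all <- designate_mains(fixture_catalog("trnL-trnF"), min_main_count = 1L)
  expect_false("B" %in% c1_all$roles$name[c1_all$roles$role == "main"])
  expect_identical(c1_all$roles$main1[c1_all$roles$name == "B"], "A")
  # designation is idempotent
  expect_identical(designate_mains(c1, 10L)$roles, c1$roles)
})

test_that("variants and intermediates are classified as published", {
  c3 <- designate_mains(fixture_catalog("ITS"))
  roles <- c3$roles
  get <- function(n) roles[roles$name == n, ]
  expect_identical(get("A1")$role, "variant")
  expect_identical(get("A1")$main1, "A")
  # nine local variants of ribotype A
  a_vars <- roles$name[roles$role == "variant" & roles$main1 == "A"]
  expect_length(a_vars, 9L)
  # D3 is the intermediate between ribotype D and ribotype B
  expect_identical(get("D3")$role, "intermediate")
  expect_setequal(c(get("D3")$main1, get("D3")$main2), c("B", "D"))
  # classify_variant rejects a vector equal to a main
  rs <- c3$states
  cons <- c3$columns$consensus
  mains <- rs[c("A", "B", "C", "D"), ]
  expect_error(classify_variant(rs["A", ], mains, cons), "non-main")
  # example from the module contract: D3 against mains {B, D}
  cl <- classify_variant(rs["D3", ], rs[c("B", "D"), ], cons)
  expect_identical(cl$role, "intermediate")
  expect_setequal(c(cl$main1, cl$main2), c("B", "D"))
})

test_that("count tabulation reports per-species totals and heterozygote-derived rows", {
  c2 <- fixture_catalog("rpl32-trnL")
  tab <- tabulate_counts(c2)
  expect_equal(tab$types$total[tab$types$name == "D"], 60L)
  expect_equal(tab$types$cre[tab$types$name == "D"], 59L)
  expect_equal(tab$types$can[tab$types$name == "D"], 1L)
  c3 <- fixture_catalog("ITS")
  tab3 <- tabulate_counts(c3)
  expect_equal(sum(tab3$types$total), 143L)
  expect_equal(tab3$types$het_derived[tab3$types$name == "F"], 2L)
  expect_equal(tab3$types$het_derived[tab3$types$name == "A"], 0L)
})

test_that("clade assignment follows the combined chloro/ribotype rule", {
  cc <- designate_mains(fixture_catalog("trnL-trnF"))
  cr <- designate_mains(fixture_catalog("ITS"))
  expect_identical(assign_clade("A", "A", cc, cr), "EM")
  expect_identical(assign_clade("A", c("A", "A2"), cc, cr), "EM")
  expect_identical(assign_clade("D", c("A", "D"), cc, cr), "WM")
  expect_identical(assign_clade("E", "A", cc, cr), "WM")
  expect_identical(assign_clade("A", "C3", cc, cr), "admixed")
  # chlorotype B is a rare variant of A and inherits its group
  expect_identical(assign_clade("B", "A", cc, cr), "EM")
  # one failed marker does not downgrade the call
  expect_identical(assign_clade(NA, "A", cc, cr), "EM")
  expect_identical(assign_clade("A", character(0), cc, cr), "EM")
  expect_identical(assign_clade(NA, character(0), cc, cr), "undetermined")
  expect_error(assign_clade("Z", "A", cc, cr), "unknown type")
})
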