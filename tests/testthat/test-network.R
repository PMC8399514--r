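test_that("Provesti distance matches its definition and handles missing data", {
  expect_equal(provesti_distance(c("A", "C", "G"), c("A", "C", "G")), 0)
  expect_equal(provesti_distance(c("A", "C", "G", "T"), c("C", "G", "T", "A")), 1)
  expect_error(provesti_distance(c("A", "C"), c("A")), "length")
  # N columns drop out of the denominator
  expect_equal(provesti_distance(c("A", "N", "G", "T"), c("A", "C", "G", "A")),
               1 / 3)
  # gap is a state; ambiguity characters compare literally
  expect_equal(provesti_distance(c("A", "-"), c("A", "T")), 1 / 2)
  expect_equal(provesti_distance(c("R", "A"), c("A", "A")), 1 / 2)
  expect_equal(provesti_distance(c("R", "A"), c("A", "A"), mode = "overlap"), 0)
  # published ribotypes A and B differ at the indel event and column 632
  c3 <- fixture_catalog("ITS")
  rs <- retained_states(c3)
  expect_equal(provesti_distance(rs["A", ], rs["B", ]), 2 / 26)
})

test_that("Provesti is a metric and agrees with the brute-force comparer", {
  set.seed(101)
  for (i in 1:300) {
    v <- random_state_vectors(3, 12)
    d12 <- provesti_distance(v[[1]], v[[2]])
    d13 <- provesti_distance(v[[1]], v[[3]])
    d23 <- provesti_distance(v[[2]], v[[3]])
    expect_equal(d12, brute_provesti(v[[1]], v[[2]]))
    expect_equal(d12, provesti_distance(v[[2]], v[[1]]))
    expect_equal(provesti_distance(v[[1]], v[[1]]), 0)
    expect_gte(d12 + d23 + 1e-12, d13)
  }
})

test_that("event distances reproduce the published network annotations", {
  c1 <- fixture_catalog("trnL-trnF")
  ac <- event_distance("A", "C", c1)
  expect_equal(ac$substitutions, 5L)
  expect_equal(ac$homopolymer_indels, 1L)
  de <- event_distance("D", "E", c1)
  expect_equal(de$substitutions, 1L)
  expect_equal(de$homopolymer_indels, 1L)
  ad2 <- event_distance("A", "D", fixture_catalog("rpl32-trnL"))
  expect_equal(ad2$substitutions, 3L)
  expect_equal(ad2$total, ad2$substitutions + ad2$indel_events)
  expect_error(event_distance("A", "Z", c1), "unknown type")
})

test_that("event counts are invariant under column reordering", {
  c1 <- fixture_catalog("trnL-trnF")
  perm <- sample(nrow(c1$columns))
  c1p <- c1
  c1p$columns <- c1$columns[perm, , drop = FALSE]
  c1p$states <- c1$states[, perm, drop = FALSE]
  for (pair in list(c("A", "C"), c("D", "E"), c("A", "E")))
    expect_identical(event_distance(pair[1], pair[2], c1),
                     event_distance(pair[1], pair[2], c1p))
})

test_that("pairwise matrices are symmetric with the expected extremes", {
  c2 <- fixture_catalog("rpl32-trnL")
  d <- pairwise_matrix(c2, metric = "events_total")
  expect_true(isSymmetric(d))
  expect_equal(dim(d), c(4L, 4L))
  # brute-force over the 6 pairs: the maximum involves D
  mx <- which(d == max(d), arr.ind = TRUE)
  expect_true(all(apply(mx, 1, function(r) "D" %in% rownames(d)[r])))
})

test_that("minimum spanning networks keep exact ties as alternative edges", {
  nm <- c("x", "y", "z")
  equi <- matrix(1, 3, 3, dimnames = list(nm, nm)); diag(equi) <- 0
  net <- build_msn(equi)
  expect_equal(sum(!net$edges$alternative), 2L)
  expect_equal(sum(net$edges$alternative), 1L)
  chain <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, dimnames = list(nm, nm))
  net2 <- build_msn(chain)
  expect_equal(sum(net2$edges$alternative), 0L)
  expect_setequal(paste(net2$edges$from, net2$edges$to),
                  c("x y", "y z"))
})

test_that("primary edges match the exhaustive spanning-tree oracle", {
  set.seed(77)
  for (i in 1:60) {
    n <- sample(3:6, 1)
    nm <- paste0("t", seq_len(n))
    d <- matrix(0, n, n, dimnames = list(nm, nm))
    vals <- sample(1:4, n * (n - 1) / 2, replace = TRUE)
    d[upper.tri(d)] <- vals
    d <- d + t(d)
    net <- build_msn(d)
    expect_equal(msn_weight(net), brute_mst_weight(d))
    # alternatives are exactly the zero-epsilon ties: a non-tree edge whose
    # weight equals the maximum edge weight on the tree path it closes
    tree <- net$edges[!net$edges$alternative, , drop = FALSE]
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      in_tree <- any((tree$from == nm[a] & tree$to == nm[b]) |
                       (tree$from == nm[b] & tree$to == nm[a]))
      if (in_tree) next
      is_alt <- any(net$edges$alternative &
                      ((net$edges$from == nm[a] & net$edges$to == nm[b]) |
                         (net$edges$from == nm[b] & net$edges$to == nm[a])))
      expect_identical(is_alt,
                       d[nm[a], nm[b]] == tree_path_max(tree, nm[a], nm[b]))
    }
  }
})

test_that("disconnected inputs fall back to component-wise trees with a warning", {
  nm <- c("a", "b", "c", "d")
  d <- matrix(Inf, 4, 4, dimnames = list(nm, nm)); diag(d) <- 0
  d["a", "b"] <- d["b", "a"] <- 1
  d["c", "d"] <- d["d", "c"] <- 2
  expect_warning(net <- build_msn(d), "disconnected")
  expect_equal(nrow(net$edges), 2L)
})

test_that("network export is lossless and rejects unknown formats", {
  c1 <- designate_mains(fixture_catalog("trnL-trnF"))
  net <- build_msn(pairwise_matrix(c1, "events_total"),
                   sizes = rowSums(c1$counts), cat = c1)
  f <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, f, "graphml")
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
  expect_true("alternative" %in% igraph::edge_attr_names(g))
  expect_equal(sort(igraph::V(g)$size), sort(net$nodes$size))
  fd <- withr::local_tempfile(fileext = ".dot")
  suppressWarnings(export_network(net, fd, "dot"))
  expect_true(any(grepl("--", readLines(fd), fixed = TRUE)))
  expect_error(export_network(net, f, "svg"))
})
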