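# Shared helpers: tiny alignments built in code and independent brute-force
# oracles used to verify the package's own implementations.

mini_alignment <- function(seqs, ...) {
  alignment(stats::setNames(seqs, paste0("s", seq_along(seqs))), ...)
}

# independent per-column Provesti comparer (the definition, written directly)
brute_provesti <- function(a, b) {
  keep <- !(a %in% c("N", "?")) & !(b %in% c("N", "?"))
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0L) return(0)
  n_diff <- 0L
  for (i in seq_along(a)) if (a[i] != b[i]) n_diff <- n_diff + 1L
  n_diff / length(a)
}

# exhaustive minimum-spanning-tree weight by enumerating all edge subsets
brute_mst_weight <- function(d) {
  n <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ne <- nrow(pairs)
  best <- Inf
  for (subset in utils::combn(ne, n - 1L, simplify = FALSE)) {
    # spanning check by union-find
    comp <- seq_len(n)
    for (k in subset) {
      a <- comp[pairs[k, 1L]]; b <- comp[pairs[k, 2L]]
      comp[comp == b] <- a
    }
    if (length(unique(comp)) == 1L)
      best <- min(best, sum(d[pairs[subset, , drop = FALSE]]))
  }
  best
}

# max edge weight on the unique tree path between two nodes (tree as edge df)
tree_path_max <- function(edges, from, to) {
  dfs <- function(node, target, visited, wmax) {
    if (node == target) return(wmax)
    for (i in seq_len(nrow(edges))) {
      nxt <- if (edges$from[i] == node) edges$to[i]
             else if (edges$to[i] == node) edges$from[i] else next
      if (nxt %in% visited) next
      r <- dfs(nxt, target, c(visited, nxt), max(wmax, edges$weight[i]))
      if (!is.na(r)) return(r)
    }
    NA_real_
  }
  dfs(from, to, from, -Inf)
}

random_state_vectors <- function(n, len, states = c("A", "C", "G", "T", "-", "R", "Y")) {
  replicate(n, sample(states, len, replace = TRUE), simplify = FALSE)
}
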