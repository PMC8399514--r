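#' Provesti distance between two state vectors
#'
#' The proportion of compared characters at which two haplotypes differ:
#' (number of differing columns) / (number of compared columns). The gap
#' character is a state; ambiguity characters compare literally by default
#' (`R` differs from `A`). Columns where either vector carries the
#' missing-data symbol `N` (or `?`) are dropped from the denominator. An
#' optional `"overlap"` mode scores two states as equal when their IUPAC base
#' sets intersect; it is off by default, consistent with literal-state typing.
#'
#' @param a,b character state vectors of equal length.
#' @param mode `"literal"` (default) or `"overlap"`.
#' @return a fraction in `[0, 1]`.
#' @export
provesti_distance <- function(a, b, mode = c("literal", "overlap")) {
  mode <- match.arg(mode)
  a <- as.character(a)
  b <- as.character(b)
  if (length(a) != length(b))
    stop("state vectors differ in length", call. = FALSE)
  keep <- !(a %in% c("N", "?")) & !(b %in% c("N", "?"))
  a <- a[keep]
  b <- b[keep]
  if (length(a) == 0L) return(0)
  if (mode == "literal") return(sum(a != b) / length(a))
  overlap <- vapply(seq_along(a), function(i) {
    if (a[i] == b[i]) return(TRUE)
    if (a[i] == "-" || b[i] == "-") return(FALSE)
    if (nchar(a[i]) > 1L || nchar(b[i]) > 1L) return(a[i] == b[i])
    length(intersect(iupac_bases(a[i]), iupac_bases(b[i]))) > 0L
  }, logical(1))
  sum(!overlap) / length(a)
}

#' Mutation-event distance between two catalog types
#'
#' Counts, between two types, the differing substitution columns and the
#' differing indel-event columns, with homopolymer-attached events (putative
#' slippage artifacts) tallied separately and excluded from the headline
#' counts -- mirroring network annotations of the form "five mutations (plus
#' one poly-T stretch related indel)".
#'
#' @param a,b type names.
#' @param cat a `cis_catalog`.
#' @return list with `substitutions`, `indel_events` (non-homopolymer),
#'   `homopolymer_indels` and `total` (= substitutions + indel_events).
#' @export
event_distance <- function(a, b, cat) {
  stopifnot(inherits(cat, "cis_catalog"))
  for (nm in c(a, b))
    if (!nm %in% rownames(cat$states))
      stop("unknown type name '", nm, "'", call. = FALSE)
  differ <- cat$states[a, ] != cat$states[b, ]
  kind <- cat$columns$kind
  hp <- cat$columns$homopolymer
  subs <- sum(differ & kind == "substitution")
  indel <- sum(differ & kind == "indel" & !hp)
  hpoly <- sum(differ & kind == "indel" & hp)
  list(substitutions = as.integer(subs), indel_events = as.integer(indel),
       homopolymer_indels = as.integer(hpoly),
       total = as.integer(subs + indel))
}

#' Pairwise distance matrix over catalog types
#'
#' @param cat a `cis_catalog` with at least two types.
#' @param metric `"provesti"` (on retained columns) or `"events_total"`
#'   (substitutions + non-homopolymer indel events).
#' @return symmetric numeric matrix with type-name dimnames.
#' @export
pairwise_matrix <- function(cat, metric = c("provesti", "events_total")) {
  metric <- match.arg(metric)
  stopifnot(inherits(cat, "cis_catalog"))
  nms <- rownames(cat$states)
  if (length(nms) < 2L) stop("need at least two types", call. = FALSE)
  d <- matrix(0, length(nms), length(nms), dimnames = list(nms, nms))
  rs <- retained_states(cat)
  for (i in seq_along(nms)[-length(nms)]) {
    for (j in (i + 1L):length(nms)) {
      v <- if (metric == "provesti")
        provesti_distance(rs[i, ], rs[j, ])
      else event_distance(nms[i], nms[j], cat)$total
      d[i, j] <- d[j, i] <- v
    }
  }
  d
}

#' Build a minimum spanning haplotype network
#'
#' Kruskal-style growth over edges in ascending weight (ties by endpoint
#' names): an edge joining two different components becomes a primary edge;
#' an edge within one component whose weight equals the threshold at which its
#' endpoints' components were merged is kept as an *alternative* edge -- an
#' equally minimal connection the spanning tree could have used instead
#' (epsilon = 0: only exact ties qualify). Primary edges form a spanning tree
#' of each connected component; with infinite distances the network decomposes
#' into component-wise trees with a warning.
#'
#' @param d symmetric distance matrix with dimnames.
#' @param sizes optional named sample sizes attached to nodes.
#' @param species optional named species-composition strings attached to
#'   nodes.
#' @param cat optional catalog; when given, edges are annotated with
#'   [event_distance()] counts.
#' @return object of class `cis_network`: list with `nodes` (name, size,
#'   species) and `edges` (from, to, weight, alternative, and event counts
#'   when annotated).
#' @export
build_msn <- function(d, sizes = NULL, species = NULL, cat = NULL) {
  nms <- rownames(d)
  if (is.null(nms) || !identical(nms, colnames(d)))
    stop("distance matrix needs identical row/column names", call. = FALSE)
  if (!isTRUE(all.equal(d, t(d))))
    stop("distance matrix must be symmetric", call. = FALSE)
  n <- length(nms)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  edges <- data.frame(from = nms[pairs[, 1L]], to = nms[pairs[, 2L]],
                      weight = d[pairs], stringsAsFactors = FALSE)
  edges <- edges[is.finite(edges$weight), , drop = FALSE]
  edges <- edges[order(edges$weight, edges$from, edges$to), , drop = FALSE]

  comp <- stats::setNames(seq_len(n), nms)
  merge_w <- matrix(NA_real_, n, n, dimnames = list(nms, nms))
  primary <- logical(nrow(edges))
  alternative <- logical(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    a <- edges$from[e]; b <- edges$to[e]; w <- edges$weight[e]
    if (comp[a] != comp[b]) {
      primary[e] <- TRUE
      in_a <- names(comp)[comp == comp[a]]
      in_b <- names(comp)[comp == comp[b]]
      merge_w[in_a, in_b] <- w
      merge_w[in_b, in_a] <- w
      comp[comp == comp[b]] <- comp[a]
    } else if (!is.na(merge_w[a, b]) && w == merge_w[a, b]) {
      alternative[e] <- TRUE
    }
  }
  if (length(unique(comp)) > 1L)
    warning("distance graph is disconnected; returning component-wise networks")

  keep <- primary | alternative
  out_edges <- edges[keep, , drop = FALSE]
  out_edges$alternative <- alternative[keep]
  rownames(out_edges) <- NULL
  if (!is.null(cat)) {
    ann <- t(vapply(seq_len(nrow(out_edges)), function(i) {
      ed <- event_distance(out_edges$from[i], out_edges$to[i], cat)
      c(substitutions = ed$substitutions, indel_events = ed$indel_events,
        homopolymer_indels = ed$homopolymer_indels)
    }, c(substitutions = 0L, indel_events = 0L, homopolymer_indels = 0L)))
    out_edges <- cbind(out_edges, ann)
  }
  nodes <- data.frame(name = nms,
                      size = if (is.null(sizes)) rep(1, n) else
                        as.numeric(sizes[nms]),
                      species = if (is.null(species)) rep("", n) else
                        as.character(species[nms]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = out_edges), class = "cis_network")
}

#' @export
print.cis_network <- function(x, ...) {
  cat("<cis_network> ", nrow(x$nodes), " nodes; ",
      sum(!x$edges$alternative), " primary + ",
      sum(x$edges$alternative), " alternative edges\n", sep = "")
  invisible(x)
}

#' Total primary-edge weight of a network
#' @param net a `cis_network`
#' @return numeric
#' @export
msn_weight <- function(net) sum(net$edges$weight[!net$edges$alternative])

#' Export a haplotype network
#'
#' Lossless attribute export (weights, event labels, alternative flags, node
#' sizes) to GraphML or DOT via igraph.
#'
#' @param net a `cis_network`.
#' @param path output path.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "cis_network"))
  edges <- net$edges
  edges$alternative <- as.integer(edges$alternative)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = net$nodes)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
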