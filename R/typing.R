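#' @name typing
#' @title Haplotype (chlorotype/ribotype) definition and classification
#'
#' @description
#' A haplotype catalog names every distinct state vector observed over the
#' retained columns of a condensed matrix. Roles (main type, local variant of
#' a main, intermediate between two mains, unique) are recorded separately
#' from names: a rare type structurally derived from a frequent one keeps its
#' own name, and its relation is carried in the role table.
NULL

# spreadsheet-style deterministic names: A..Z, AA, AB, ...
type_names <- function(n) {
  nm <- character(n)
  for (i in seq_len(n)) {
    v <- i
    s <- ""
    while (v > 0L) {
      r <- (v - 1L) %% 26L
      s <- paste0(LETTERS[r + 1L], s)
      v <- (v - 1L) %/% 26L
    }
    nm[i] <- s
  }
  nm
}

.new_catalog <- function(marker, columns, states, counts, assignment, meta,
                         het_derived = NULL) {
  roles <- data.frame(name = rownames(states), role = "unassigned",
                      main1 = NA_character_, main2 = NA_character_,
                      stringsAsFactors = FALSE)
  structure(list(marker = marker, columns = columns, states = states,
                 counts = counts, assignment = assignment, meta = meta,
                 roles = roles,
                 het_derived = het_derived %||%
                   stats::setNames(rep(0L, nrow(states)), rownames(states))),
            class = "cis_catalog")
}

#' @export
print.cis_catalog <- function(x, ...) {
  cat("<cis_catalog> marker=", x$marker, ": ", nrow(x$states), " types over ",
      sum(!x$columns$excluded), " retained columns; ",
      sum(x$counts), " sequences\n", sep = "")
  invisible(x)
}

#' Number of types in a catalog
#' @param cat a `cis_catalog`
#' @return integer
#' @export
n_types <- function(cat) nrow(cat$states)

# retained-column state matrix / consensus of a catalog
retained_states <- function(cat) {
  cat$states[, !cat$columns$excluded, drop = FALSE]
}
retained_consensus <- function(cat) {
  cat$columns$consensus[!cat$columns$excluded]
}

#' Define haplotypes from a condensed matrix
#'
#' One type per distinct state vector over the non-excluded columns; counts
#' accumulated per species; names assigned deterministically by descending
#' total count, ties by first occurrence (`A`, `B`, `C`, ...). States at
#' excluded columns (which may vary within a type) are represented by the
#' first member sequence, deterministically.
#'
#' @param cm a [condense()] result.
#' @param log optional audit log.
#' @return a `cis_catalog`: list with `states` (type x column matrix including
#'   excluded columns), `counts` (type x species matrix), `assignment`
#'   (sequence id -> type name), `roles`, `columns`, `meta`.
#' @export
define_types <- function(cm, log = NULL) {
  stopifnot(inherits(cm, "cis_condensed"))
  if (nrow(cm$states) == 0L) stop("empty condensed matrix", call. = FALSE)
  keep <- !cm$columns$excluded
  key <- apply(cm$states[, keep, drop = FALSE], 1L, paste, collapse = "\r")
  first_idx <- which(!duplicated(key))
  grp <- match(key, key[first_idx])
  total <- tabulate(grp, nbins = length(first_idx))
  ord <- order(-total, first_idx)
  names_ordered <- type_names(length(first_idx))
  type_of_group <- character(length(first_idx))
  type_of_group[ord] <- names_ordered

  row_order <- order(match(type_of_group, names_ordered))
  states <- cm$states[first_idx[row_order], , drop = FALSE]
  rownames(states) <- type_of_group[row_order]

  assignment <- stats::setNames(type_of_group[grp], rownames(cm$states))
  species <- cm$meta$species[match(rownames(cm$states), cm$meta$id)]
  counts <- table(factor(assignment, levels = rownames(states)),
                  factor(species, levels = sort(unique(species))))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  het <- cm$meta$provenance[match(rownames(cm$states), cm$meta$id)] != "direct"
  het_derived <- vapply(rownames(states), function(tn)
    sum(het[assignment == tn]), integer(1))
  log_note(log, "defined ", nrow(states), " types for marker ", cm$marker)
  .new_catalog(cm$marker, cm$columns, states, counts, assignment, cm$meta,
               het_derived)
}

#' Build a catalog from a published-style type table
#'
#' Constructs a catalog directly from a type-by-column state matrix (rows
#' already named, e.g. transcribed from a published variable-site table) and
#' per-species counts, bypassing per-sequence assignment.
#'
#' @param marker marker label.
#' @param columns column definition data frame as in a `cis_condensed`.
#' @param states named type-by-column state matrix.
#' @param counts type-by-species count matrix.
#' @param het_derived optional named vector: sequences per type extracted
#'   solely from heterozygous plants.
#' @return a `cis_catalog`.
#' @export
catalog_from_table <- function(marker, columns, states, counts,
                               het_derived = NULL) {
  keep <- !columns$excluded
  key <- apply(states[, keep, drop = FALSE], 1L, paste, collapse = "\r")
  if (anyDuplicated(key))
    stop("distinct types must have distinct state vectors", call. = FALSE)
  .new_catalog(marker, columns, states, counts,
               assignment = stats::setNames(character(0), character(0)),
               meta = NULL, het_derived = het_derived)
}

#' Assign a state vector to a catalog type
#'
#' Exact-state matching (ambiguity characters compare literally: `R` does not
#' match `A`). A vector matching no type is reported as novel, together with
#' the nearest type (fewest differing retained columns, ties by type name) and
#' the differing columns.
#'
#' @param states character vector of states over the catalog's retained
#'   columns.
#' @param cat a `cis_catalog`.
#' @return list with `type` (name or `"novel"`), `novel` flag, `nearest`,
#'   `differing` (labels of differing columns; empty for exact matches).
#' @export
assign_sequence <- function(states, cat) {
  stopifnot(inherits(cat, "cis_catalog"))
  rs <- retained_states(cat)
  if (length(states) != ncol(rs))
    stop("state vector length ", length(states), " does not match catalog (",
         ncol(rs), " retained columns)", call. = FALSE)
  diffs <- rowSums(sweep(rs, 2L, as.character(states), FUN = "!="))
  hit <- which(diffs == 0L)
  if (length(hit) == 1L)
    return(list(type = rownames(rs)[hit], novel = FALSE,
                nearest = rownames(rs)[hit], differing = character(0)))
  nearest <- rownames(rs)[order(diffs, rownames(rs))][1L]
  differ <- colnames(rs)[rs[nearest, ] != states]
  list(type = "novel", novel = TRUE, nearest = nearest, differing = differ)
}

# non-consensus retained columns of one type row (named state vector)
.nc_cols <- function(row, consensus) which(row != consensus)

# is `t` expressible as main `m` plus extra non-consensus states?
.superset_of <- function(t_row, m_row, consensus) {
  nc_m <- .nc_cols(m_row, consensus)
  if (!all(t_row[nc_m] == m_row[nc_m])) return(FALSE)
  nc_t <- .nc_cols(t_row, consensus)
  length(setdiff(nc_t, nc_m)) > 0L
}

# does state x (single char) cover both a and b as an IUPAC ambiguity?
.covers_both <- function(x, a, b) {
  if (!is_ambiguous(x)) return(FALSE)
  if (nchar(a) != 1L || nchar(b) != 1L || a == "-" || b == "-") return(FALSE)
  if (is_ambiguous(a) || is_ambiguous(b)) return(FALSE)
  all(c(a, b) %in% iupac_bases(x))
}

#' Designate main types
#'
#' A type is designated a main type when its total count reaches
#' `min_main_count` and it is not expressible as an already designated main
#' plus extra non-consensus states; candidates are processed in descending
#' count order (ties by name), so a frequent derived type defers to its more
#' frequent structural ancestor. All remaining types are classified by
#' [classify_variant()]. The default threshold 10 separates the published main
#' types (n >= 13) from the largest local variant (n = 7).
#'
#' @param cat a `cis_catalog`.
#' @param min_main_count minimum total count for a main type (default 10).
#' @return the catalog with its `roles` table filled in.
#' @export
designate_mains <- function(cat, min_main_count = 10L) {
  stopifnot(inherits(cat, "cis_catalog"))
  # full representative vectors, excluded columns included: types that differ
  # only at a down-weighted homopolymer indel still differ structurally
  rs <- cat$states
  cons <- cat$columns$consensus
  total <- rowSums(cat$counts)
  ord <- rownames(rs)[order(-total, rownames(rs))]
  mains <- character(0)
  for (tn in ord) {
    if (total[tn] < min_main_count) next
    sup <- any(vapply(mains, function(m)
      .superset_of(rs[tn, ], rs[m, ], cons), logical(1)))
    if (!sup) mains <- c(mains, tn)
  }
  roles <- cat$roles
  roles$role <- "unassigned"
  roles$main1 <- NA_character_
  roles$main2 <- NA_character_
  for (i in seq_len(nrow(roles))) {
    tn <- roles$name[i]
    if (tn %in% mains) {
      roles$role[i] <- "main"
      roles$main1[i] <- tn
    } else {
      cl <- classify_variant(rs[tn, ], rs[mains, , drop = FALSE], cons)
      roles$role[i] <- cl$role
      roles$main1[i] <- cl$main1
      roles$main2[i] <- cl$main2
    }
  }
  cat$roles <- roles
  cat
}

#' Classify a non-main type against the main types
#'
#' A type is a *variant* of main `M` when it equals `M` plus extra
#' non-consensus states confined to columns where all other mains are
#' consensus; a type carrying `M`'s full distinctive pattern may additionally
#' hold an additive (ambiguity) site overlapping `M`'s own state at another
#' main's discriminating column (the most specific qualifying main wins).
#' It is an *intermediate*
#' between mains `M1` and `M2` when, at every column distinguishing `M1` from
#' `M2`, its state is `M1`'s, `M2`'s, or an IUPAC ambiguity covering both, and
#' the pair's states are genuinely mixed (at least one ambiguity covering
#' both, or both mains' states represented). When several pairs qualify, the
#' winner is chosen by, in order: the highest fraction of ambiguity-covered
#' distinguishing columns (additive sites between the two mains are the
#' strongest intermediacy signal), the highest fraction of the type's own
#' non-consensus columns that the pair explains, the fewest distinguishing
#' columns, then name order. Everything else is *unique*.
#'
#' @param t_row named state vector of the type over retained columns.
#' @param mains state matrix of the main types (rows named).
#' @param consensus consensus state vector over retained columns.
#' @return list with `role` (`"variant"`, `"intermediate"`, `"unique"`),
#'   `main1`, `main2`.
#' @export
classify_variant <- function(t_row, mains, consensus) {
  if (nrow(mains) > 0L) {
    same <- apply(mains, 1L, function(m) all(m == t_row))
    if (any(same))
      stop("type equals main '", rownames(mains)[same][1L],
           "'; classify_variant expects a non-main type", call. = FALSE)
  }
  # variant-of: most specific qualifying main. An extra state must sit at a
  # column where every other main is consensus (a private mutation), except
  # that a type carrying a main's full distinctive pattern may additionally
  # hold an additive (ambiguity) site overlapping the main's own state even
  # at another main's discriminating column -- read as a heterozygous
  # position on that main's background, not as intermediacy.
  cand <- character(0)
  spec <- integer(0)
  for (m in rownames(mains)) {
    m_row <- mains[m, ]
    nc_m <- .nc_cols(m_row, consensus)
    if (!all(t_row[nc_m] == m_row[nc_m])) next
    extra <- setdiff(.nc_cols(t_row, consensus), nc_m)
    if (length(extra) == 0L) next
    others <- setdiff(rownames(mains), m)
    ok <- all(vapply(extra, function(cc) {
      if (all(mains[others, cc] == consensus[cc])) return(TRUE)
      length(nc_m) > 0L && is_ambiguous(t_row[cc]) &&
        nchar(m_row[cc]) == 1L && !is_ambiguous(m_row[cc]) &&
        m_row[cc] != "-" && m_row[cc] %in% iupac_bases(t_row[cc])
    }, logical(1)))
    if (ok) { cand <- c(cand, m); spec <- c(spec, length(nc_m)) }
  }
  if (length(cand) > 0L) {
    best <- cand[order(-spec, cand)][1L]
    return(list(role = "variant", main1 = best, main2 = NA_character_))
  }
  # intermediate between a pair of mains
  best <- NULL
  nc_t <- .nc_cols(t_row, consensus)
  if (nrow(mains) >= 2L) {
    prs <- utils::combn(sort(rownames(mains)), 2L)
    for (k in seq_len(ncol(prs))) {
      m1 <- prs[1L, k]; m2 <- prs[2L, k]
      d12 <- which(mains[m1, ] != mains[m2, ])
      if (length(d12) == 0L) next
      covered <- vapply(d12, function(cc)
        .covers_both(t_row[cc], mains[m1, cc], mains[m2, cc]), logical(1))
      pure1 <- t_row[d12] == mains[m1, d12] & !covered
      pure2 <- t_row[d12] == mains[m2, d12] & !covered
      if (!all(covered | pure1 | pure2)) next
      mixed <- any(covered) || (any(pure1 & !pure2) && any(pure2 & !pure1))
      if (!mixed) next
      explained <- if (length(nc_t) == 0L) 1 else
        mean(nc_t %in% d12)
      score <- c(mean(covered), explained, -length(d12))
      better <- is.null(best)
      if (!better) {
        for (s in seq_along(score)) {
          if (score[s] != best$score[s]) {
            better <- score[s] > best$score[s]
            break
          }
        }
      }
      if (better) best <- list(m1 = m1, m2 = m2, score = score)
    }
  }
  if (!is.null(best))
    return(list(role = "intermediate", main1 = best$m1, main2 = best$m2))
  list(role = "unique", main1 = NA_character_, main2 = NA_character_)
}

#' Tabulate per-type, per-species counts
#'
#' @param cat a `cis_catalog` (roles optional; `"unassigned"` when mains have
#'   not been designated).
#' @return list with `types` (one row per type: role, relation, per-species
#'   counts, total, and the number of member sequences extracted from
#'   heterozygous plants) and `roles` (totals per role class).
#' @export
tabulate_counts <- function(cat) {
  stopifnot(inherits(cat, "cis_catalog"))
  types <- data.frame(name = rownames(cat$states),
                      role = cat$roles$role,
                      main1 = cat$roles$main1,
                      main2 = cat$roles$main2,
                      stringsAsFactors = FALSE)
  types <- cbind(types, as.data.frame.matrix(cat$counts))
  types$total <- rowSums(cat$counts)
  types$het_derived <- cat$het_derived[types$name]
  roles <- stats::aggregate(total ~ role, data = types, FUN = sum)
  list(types = types, roles = roles)
}

# main-group of a type: its own name for mains, its main for variants, NA else
.type_group <- function(name, cat) {
  i <- match(name, cat$roles$name)
  if (is.na(i)) stop("unknown type name '", name, "' for marker ",
                     cat$marker, call. = FALSE)
  switch(cat$roles$role[i],
         main = name,
         variant = cat$roles$main1[i],
         NA_character_)
}

#' Assign an individual to an evolutionary clade
#'
#' Combines an individual's chlorotype with its (possibly two, for
#' heterozygotes) ribotypes into a clade call, following the combined
#' chloroplast/ribosomal rule for the two *C. creticus* lineages: the Eastern
#' Mediterranean (EM) clade carries the widespread chlorotype-A group together
#' with ribotype-A-group sequences only; the Western/Central Mediterranean
#' (WM) clade carries chlorotype C, D or E (or a co-occurring non-A main
#' ribotype); a chlorotype-A individual carrying only rare non-A ribotype
#' variants (the pattern of Greek contact populations) is called admixed.
#'
#' A missing marker does not by itself downgrade the call: an individual is
#' judged on the marker(s) present and becomes `"undetermined"` only when
#' both markers are absent or neither pattern applies.
#'
#' @param chlorotype chlorotype name (or `NA` when the marker failed).
#' @param ribotypes character vector of ribotype names (may be empty).
#' @param chloro_cat,ribo_cat catalogs with designated mains.
#' @param em_chlorotype,em_ribotype names of the EM main types (default `"A"`).
#' @param wm_chlorotypes names of the WM main chlorotypes (default
#'   `c("C","D","E")`).
#' @return one of `"EM"`, `"WM"`, `"admixed"`, `"undetermined"`.
#' @export
assign_clade <- function(chlorotype, ribotypes, chloro_cat, ribo_cat,
                         em_chlorotype = "A", em_ribotype = "A",
                         wm_chlorotypes = c("C", "D", "E")) {
  if (all(chloro_cat$roles$role == "unassigned") ||
      all(ribo_cat$roles$role == "unassigned"))
    stop("designate_mains() must be applied to both catalogs first", call. = FALSE)
  ribotypes <- ribotypes[!is.na(ribotypes)]
  if (is.na(chlorotype) && length(ribotypes) == 0L) return("undetermined")
  ribo_groups <- if (length(ribotypes) > 0L)
    vapply(ribotypes, .type_group, "", cat = ribo_cat) else character(0)
  ribo_main <- ribotypes %in% ribo_cat$roles$name[ribo_cat$roles$role == "main"]
  non_em_main <- any(ribo_main & ribo_groups != em_ribotype)
  all_em_ribo <- length(ribotypes) > 0L &&
    all(!is.na(ribo_groups) & ribo_groups == em_ribotype)

  if (is.na(chlorotype)) {
    if (non_em_main) return("WM")
    if (all_em_ribo) return("EM")
    return("undetermined")
  }
  cgroup <- .type_group(chlorotype, chloro_cat)
  if (!is.na(cgroup) && cgroup %in% wm_chlorotypes) return("WM")
  if (non_em_main) return("WM")
  if (!is.na(cgroup) && cgroup == em_chlorotype) {
    if (length(ribotypes) == 0L || all_em_ribo) return("EM")
    return("admixed")
  }
  "undetermined"
}

#' Export a catalog as a TSV type table
#'
#' Mirrors the layout of published variable-site tables: one row per type,
#' columns the retained 1-based positions, `.` marking the consensus state.
#'
#' @param cat a `cis_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_catalog <- function(cat, path) {
  stopifnot(inherits(cat, "cis_catalog"))
  keep <- !cat$columns$excluded
  rs <- cat$states[, keep, drop = FALSE]
  cons <- cat$columns$consensus[keep]
  disp <- rs
  for (j in seq_len(ncol(disp))) disp[rs[, j] == cons[j], j] <- "."
  tab <- data.frame(type = rownames(rs), role = cat$roles$role,
                    n = rowSums(cat$counts), disp, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# marker=", cat$marker, "; consensus=",
                    paste(cons, collapse = ",")), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
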