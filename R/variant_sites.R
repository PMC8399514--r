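#' Extract variable columns from an alignment
#'
#' A column is variable when it shows at least two distinct states across
#' sequences (the gap character counts as a state). The consensus is the
#' majority state; ties are broken by the state of the first sequence and
#' recorded in the audit log. IUPAC ambiguity characters are treated as literal
#' states here: an `R` is a state of its own, not "A or G" -- published
#' ribotype tables define types (e.g. those with additive polymorphic sites)
#' by their ambiguity characters, and interpretation as a superposition is the
#' job of the phasing module.
#'
#' @param aln a [alignment()].
#' @param log optional audit log.
#' @return data frame with one row per variable column: `position` (1-based
#'   alignment column), `kind` (`"substitution"` or `"gap_member"`),
#'   `consensus_state`, `observed_states` (slash-separated, sorted).
#' @export
extract_variable_columns <- function(aln, log = NULL) {
  stopifnot(inherits(aln, "cis_alignment"))
  mat <- aln$mat
  out <- lapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    states <- unique(col)
    if (length(states) < 2L) return(NULL)
    tab <- table(col)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      cons <- if (col[1L] %in% top) col[1L] else top[1L]
      log_note(log, "consensus tie at column ", j,
               "; resolved by first-sequence state '", cons, "'")
    } else {
      cons <- top
    }
    data.frame(
      position = j,
      kind = if ("-" %in% states) "gap_member" else "substitution",
      consensus_state = cons,
      observed_states = paste(sort(states), collapse = "/"),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(position = integer(0), kind = character(0),
                      consensus_state = character(0),
                      observed_states = character(0))
  res
}

# which sequences are gapped at column j (logical vector keyed by row)
.gap_pattern <- function(mat, j) mat[, j] == "-"

#' Group gap columns into indel events
#'
#' Simple indel coding: each maximal run of adjacent gap-containing columns
#' whose gap pattern (the set of gapped sequences) is identical forms one
#' event, to be treated downstream as a single evolutionary character. A
#' multi-residue insertion therefore counts as one event, not one per column;
#' adjacent gap columns with different presence/absence patterns split into
#' separate events.
#'
#' @param aln a [alignment()].
#' @param cols variable columns from [extract_variable_columns()] on `aln`.
#' @return data frame with one row per event: `start`, `end` (1-based,
#'   inclusive), `length`, `homopolymer_attached` (NA until
#'   [flag_homopolymer_indels()] is applied), `homopolymer_base`.
#' @export
group_indel_events <- function(aln, cols) {
  stopifnot(inherits(aln, "cis_alignment"))
  gapcols <- sort(cols$position[cols$kind == "gap_member"])
  if (length(gapcols) == 0L)
    return(data.frame(start = integer(0), end = integer(0), length = integer(0),
                      homopolymer_attached = logical(0),
                      homopolymer_base = character(0)))
  events <- list()
  run_start <- gapcols[1L]
  prev <- gapcols[1L]
  prev_pat <- .gap_pattern(aln$mat, gapcols[1L])
  for (j in gapcols[-1L]) {
    pat <- .gap_pattern(aln$mat, j)
    if (j == prev + 1L && identical(pat, prev_pat)) {
      prev <- j
    } else {
      events[[length(events) + 1L]] <- c(run_start, prev)
      run_start <- j
      prev <- j
      prev_pat <- pat
    }
  }
  events[[length(events) + 1L]] <- c(run_start, prev)
  ev <- do.call(rbind, events)
  data.frame(start = ev[, 1L], end = ev[, 2L],
             length = ev[, 2L] - ev[, 1L] + 1L,
             homopolymer_attached = NA,
             homopolymer_base = NA_character_,
             stringsAsFactors = FALSE)
}

#' Flag homopolymer-attached indel events
#'
#' Single-base indels attached to mononucleotide stretches (classically
#' poly-T in chloroplast spacers) are common replication-slippage artifacts
#' and are conventionally down-weighted when haplotypes are defined. An event
#' is flagged when (a) every inserted/deleted residue equals `base` and (b)
#' the adjacent ungapped context carries a run of at least `min_run` copies of
#' `base` (left and right flanking runs combined, gap columns skipped).
#'
#' @param aln a [alignment()].
#' @param events events from [group_indel_events()].
#' @param base homopolymer base, default `"T"`.
#' @param min_run minimum adjacent run length, default 4 (the shortest run
#'   plausibly called a stretch); must be >= 2.
#' @return `events` with `homopolymer_attached`/`homopolymer_base` filled in.
#' @export
flag_homopolymer_indels <- function(aln, events, base = "T", min_run = 4L) {
  stopifnot(inherits(aln, "cis_alignment"))
  if (min_run < 2L) stop("parameter error: min_run must be >= 2", call. = FALSE)
  if (nrow(events) == 0L) return(events)
  mat <- aln$mat
  for (i in seq_len(nrow(events))) {
    cls <- events$start[i]:events$end[i]
    carriers <- which(mat[, cls[1L], drop = TRUE] != "-")
    if (length(carriers) == 0L) { events$homopolymer_attached[i] <- FALSE; next }
    residues <- unique(as.vector(mat[carriers, cls, drop = FALSE]))
    if (!all(residues == base)) { events$homopolymer_attached[i] <- FALSE; next }
    # context measured on the first carrier, skipping gap columns
    row <- mat[carriers[1L], ]
    run_from <- function(idx, step) {
      n <- 0L
      while (idx >= 1L && idx <= length(row)) {
        if (row[idx] == "-") { idx <- idx + step; next }
        if (row[idx] != base) break
        n <- n + 1L
        idx <- idx + step
      }
      n
    }
    ctx <- run_from(events$start[i] - 1L, -1L) + run_from(events$end[i] + 1L, +1L)
    events$homopolymer_attached[i] <- ctx >= min_run
    if (events$homopolymer_attached[i]) events$homopolymer_base[i] <- base
  }
  events
}

#' Condense an alignment to its variable characters
#'
#' Builds the condensed matrix from which haplotypes are defined: one retained
#' column per substitution-type variable column and one per indel event (an
#' event's state is the concatenated inserted residue string, or `"-"` when
#' absent). Homopolymer-attached events can be excluded from type definition;
#' excluded columns stay in the matrix, marked, so that event distances can
#' still report them separately.
#'
#' @param aln a [alignment()].
#' @param cols variable columns from [extract_variable_columns()].
#' @param events flagged events from [flag_homopolymer_indels()].
#' @param exclude_homopolymer exclude homopolymer-attached events from type
#'   definition (default TRUE).
#' @param log optional audit log.
#' @return an object of class `cis_condensed`: list with `columns` (data frame
#'   `label`, `start`, `end`, `kind`, `homopolymer`, `excluded`, `consensus`),
#'   `states` (sequence-by-column character matrix over all columns), `meta`,
#'   `marker`.
#' @export
condense <- function(aln, cols, events, exclude_homopolymer = TRUE, log = NULL) {
  stopifnot(inherits(aln, "cis_alignment"))
  if (exclude_homopolymer && anyNA(events$homopolymer_attached))
    stop("events carry unset homopolymer flags; run flag_homopolymer_indels() first",
         call. = FALSE)
  subs <- cols[cols$kind == "substitution", , drop = FALSE]
  coldef <- data.frame(
    label = c(as.character(subs$position),
              ifelse(events$length == 1L, as.character(events$start),
                     paste0(events$start, "-", events$end))),
    start = c(subs$position, events$start),
    end = c(subs$position, events$end),
    kind = c(rep("substitution", nrow(subs)), rep("indel", nrow(events))),
    homopolymer = c(rep(FALSE, nrow(subs)),
                    ifelse(is.na(events$homopolymer_attached), FALSE,
                           events$homopolymer_attached)),
    stringsAsFactors = FALSE
  )
  coldef <- coldef[order(coldef$start), , drop = FALSE]
  rownames(coldef) <- NULL
  coldef$excluded <- exclude_homopolymer & coldef$homopolymer

  mat <- aln$mat
  states <- vapply(seq_len(nrow(coldef)), function(k) {
    cls <- coldef$start[k]:coldef$end[k]
    if (coldef$kind[k] == "substitution") return(mat[, cls, drop = TRUE])
    apply(mat[, cls, drop = FALSE], 1L, function(r) {
      r <- r[r != "-"]
      if (length(r) == 0L) "-" else paste(r, collapse = "")
    })
  }, character(nrow(mat)))
  if (nrow(mat) == 1L) states <- matrix(states, nrow = 1L)
  colnames(states) <- coldef$label
  rownames(states) <- rownames(mat)

  coldef$consensus <- vapply(seq_len(nrow(coldef)), function(k) {
    tab <- table(states[, k])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      cons <- if (states[1L, k] %in% top) states[1L, k] else top[1L]
      log_note(log, "consensus tie at condensed column ", coldef$label[k],
               "; resolved by first-sequence state '", cons, "'")
      cons
    } else top
  }, "")

  if (any(coldef$excluded))
    log_note(log, "excluded homopolymer-attached indel column(s): ",
             paste(coldef$label[coldef$excluded], collapse = ", "))

  structure(list(columns = coldef, states = states, meta = aln$meta,
                 marker = aln$marker),
            class = "cis_condensed")
}

#' @export
print.cis_condensed <- function(x, ...) {
  cat("<cis_condensed> marker=", x$marker, ": ", nrow(x$states), " sequences x ",
      nrow(x$columns), " columns (", sum(!x$columns$excluded), " retained)\n",
      sep = "")
  invisible(x)
}

#' Run the full variable-site extraction on an alignment
#'
#' Convenience wrapper: [extract_variable_columns()] +
#' [group_indel_events()] + [flag_homopolymer_indels()] + [condense()].
#'
#' @inheritParams condense
#' @inheritParams flag_homopolymer_indels
#' @return a `cis_condensed`.
#' @export
condense_alignment <- function(aln, base = "T", min_run = 4L,
                               exclude_homopolymer = TRUE, log = NULL) {
  cols <- extract_variable_columns(aln, log = log)
  events <- group_indel_events(aln, cols)
  events <- flag_homopolymer_indels(aln, events, base = base, min_run = min_run)
  condense(aln, cols, events, exclude_homopolymer = exclude_homopolymer, log = log)
}

#' Export a condensed matrix as TSV
#'
#' Rows are sequence ids, columns the retained 1-based positions, cells the
#' states; excluded columns are listed in a leading comment header.
#'
#' @param cm a `cis_condensed`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_condensed <- function(cm, path) {
  stopifnot(inherits(cm, "cis_condensed"))
  keep <- !cm$columns$excluded
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# marker=", cm$marker, "; excluded_columns=",
                    paste(cm$columns$label[!keep], collapse = ",")), con)
  tab <- data.frame(id = rownames(cm$states),
                    cm$states[, keep, drop = FALSE], check.names = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
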