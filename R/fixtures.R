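#' @name fixtures
#' @title Reconstructed chlorotype/ribotype tables of the Cistus
#'   creticus/albidus marker study
#'
#' @description
#' The published variable-site tables for the three markers -- *trnL-trnF*
#' (427 bp alignment, 15 variable columns, 5 chlorotypes), *rpl32-trnL*
#' (899 bp, 5 substitution columns, 4 chlorotypes) and nuclear ITS (699 bp,
#' 25 variable nucleotide positions plus the 6 bp CGTCCT insertion at columns
#' 569--574, 29 ribotypes) -- are transcribed here as package fixtures. Each
#' marker is available both as a type catalog (rows exactly as printed, `.`
#' expanded to the consensus) and as a full-length gapped alignment with one
#' sequence per sampled individual (per-type `n` column), the invariant
#' background filled from a fixed-seed stream so fixture alignments are
#' byte-stable. The poly-T context around the two 1 bp chloroplast indels is
#' embedded so that homopolymer flagging fires; the published type inventories
#' (5 / 4 / 29) are recoverable from the alignments by
#' [condense_alignment()] + [define_types()].
NULL

# ---- table transcriptions -------------------------------------------------
# Each row: "name species_counts het_flag states..." with "." = consensus.
# Event columns hold the inserted residue string or "-" for absence; "."
# expands to the consensus event state.

.TAB1 <- list(
  marker = "trnL-trnF", length = 427L,
  labels = c("48", "50", "86", "91", "160", "166", "261", "262", "293-296",
             "357", "359", "366"),
  start = c(48L, 50L, 86L, 91L, 160L, 166L, 261L, 262L, 293L, 357L, 359L, 366L),
  end   = c(48L, 50L, 86L, 91L, 160L, 166L, 261L, 262L, 296L, 357L, 359L, 366L),
  kind  = c(rep("substitution", 6L), "indel", "indel", "indel",
            "substitution", "substitution", "indel"),
  homopolymer = c(rep(FALSE, 6L), TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
  consensus = c("C", "T", "T", "G", "T", "C", "-", "-", "-", "T", "C", "T"),
  rows = c(
    "A cre=55,alb=30,can=1 0 . G . T G . . . . G . .",
    "B cre=1 0 . G G T G . . . . G . .",
    "C cre=6,can=1 0 T . . . . . T . . . . .",
    "D cre=48 0 T . . . . . T T CTTT . T -",
    "E cre=16 0 T . . . . T T . CTTT . T -"
  )
)

.TAB2 <- list(
  marker = "rpl32-trnL", length = 899L,
  labels = c("194", "315", "411", "435", "739"),
  start = c(194L, 315L, 411L, 435L, 739L),
  end   = c(194L, 315L, 411L, 435L, 739L),
  kind  = rep("substitution", 5L),
  homopolymer = rep(FALSE, 5L),
  consensus = c("G", "C", "G", "A", "G"),
  rows = c(
    "A cre=51,alb=26,can=1 0 . . . . .",
    "B cre=3 0 . A . . .",
    "C cre=1 0 . . . . T",
    "D cre=59,can=1 0 T . T G ."
  )
)

.TAB3 <- list(
  marker = "ITS", length = 699L,
  labels = c("17", "66", "100", "111", "150", "151", "152", "153", "188",
             "229", "241", "386", "442", "453", "454", "455", "475", "526",
             "569-574", "591", "598", "606", "632", "640", "647", "651"),
  start = c(17L, 66L, 100L, 111L, 150L, 151L, 152L, 153L, 188L, 229L, 241L,
            386L, 442L, 453L, 454L, 455L, 475L, 526L, 569L, 591L, 598L,
            606L, 632L, 640L, 647L, 651L),
  end   = c(17L, 66L, 100L, 111L, 150L, 151L, 152L, 153L, 188L, 229L, 241L,
            386L, 442L, 453L, 454L, 455L, 475L, 526L, 574L, 591L, 598L,
            606L, 632L, 640L, 647L, 651L),
  kind  = c(rep("substitution", 18L), "indel", rep("substitution", 7L)),
  homopolymer = rep(FALSE, 26L),
  consensus = c("C", "G", "C", "C", "G", "T", "C", "G", "G", "C", "C", "C",
                "G", "C", "T", "G", "A", "C", "CGTCCT", "G", "A", "G", "C",
                "C", "C", "C"),
  rows = c(
    "A cre=48,alb=3 0 . . . . . . . . . . . . . . . . . . - . . . T . . .",
    "A1 cre=2 0 . . . . . . . . . . . . . . . . . . - A . . T . . .",
    "A2 cre=1 0 . S . . . . . . . . . . . . . . . . - . . . T . . .",
    "A3 cre=1 1 . . . T . . . . . . . T . . . . . . - . . . T . . .",
    "A4 cre=1 1 . . . . T . . . . . . . . . . . . . - . . . T . . .",
    "A5 cre=1 0 . . . . . . . . . . . . R . . . . . - . . . T . . .",
    "A6 cre=1 1 . . . . . . . . . . . . . . . . R . - . . . T . . .",
    "A7 cre=1 1 . . . . . . . . . . . . . . . . . Y - . . . T . . .",
    "A8 cre=1 1 . . . . . . . . . . . . . . . . . . - . . . T . . G",
    "A9 cre=1 1 . . . . . . . . . . . . . . . . . . - . . . T . G G",
    "B alb=13 0 . . . . . . . . . . . . . . . . . . . . . . . . . .",
    "B1 alb=2 0 . . . . . Y . . . . . . . . . . . . . . . . . . . .",
    "B2 alb=7 0 . . . . . C . . . . . . . . . . . . . . . . . . . .",
    "C cre=18 0 . . . . . . . T . . . . . . C A . . . . . . . . . .",
    "C1 cre=1 0 S . . . . . . T . . . . . . C A . . . . . . . . . .",
    "C2 cre=1 0 S . . . . . . T . . M . . . C A . . . . . . . . . .",
    "C3 cre=1 0 . . . . . . . T . Y . . . . C A . . . . . . . . . .",
    "C4 cre=1 0 . . . . . . . T A . . . . . C A . . . . . . . . . .",
    "C5 cre=1 0 . . . . . . . T . . . . . T C A . . . . . . . . . .",
    "C7 cre=1 1 . . . . . . . T . . . . . . . A . . . . . . . . . .",
    "C8 cre=1 0 . . . . . . S T . . . . . . C A . . . . . . . . . .",
    "C10 cre=1 0 . . Y . . . . K . . . . . . Y A . . . . R . Y . . .",
    "D cre=27 0 . . . . . . . . . . . . . . . . G . . . . . . . . .",
    "D1 cre=1 0 . . . . . . . . . . . . . . . . G T . . . . . . . .",
    "D2 cre=1 0 . . . . . . . . . . . . . . . . G Y . . . . . . . .",
    "D3 cre=1 1 . . . . . . . . . . . . . . . . R . . . . R . Y . .",
    "E cre=1 1 . . . . . . . . . . . . . . . . . . . . . . . A . .",
    "E1 cre=1 1 . . . . T . . . . . . . . . . . . . . . . T . A . .",
    "F cre=2 1 . . T T . . . . . . . . . . . R . . . . G A T . . ."
  )
)

.fixture_tables <- function() {
  list("trnL-trnF" = .TAB1, "rpl32-trnL" = .TAB2, "ITS" = .TAB3)
}

# parse a table definition into (states matrix, counts matrix, het vector)
.parse_table <- function(tab) {
  parts <- strsplit(tab$rows, " ", fixed = TRUE)
  names_ <- vapply(parts, `[[`, "", 1L)
  het <- as.integer(vapply(parts, `[[`, "", 3L))
  states <- t(vapply(parts, function(p) {
    st <- p[-(1:3)]
    ifelse(st == ".", tab$consensus, st)
  }, character(length(tab$labels))))
  rownames(states) <- names_
  colnames(states) <- tab$labels
  species <- sort(unique(unlist(lapply(parts, function(p) {
    sub("=.*", "", strsplit(p[[2L]], ",", fixed = TRUE)[[1L]])
  }))))
  counts <- matrix(0L, nrow(states), length(species),
                   dimnames = list(names_, species))
  for (i in seq_along(parts)) {
    for (tok in strsplit(parts[[i]][[2L]], ",", fixed = TRUE)[[1L]]) {
      kv <- strsplit(tok, "=", fixed = TRUE)[[1L]]
      counts[i, kv[1L]] <- as.integer(kv[2L])
    }
  }
  # het_flag marks types whose sequences were extracted solely from
  # heterozygous plants
  het_derived <- stats::setNames(ifelse(het == 1L, rowSums(counts), 0L), names_)
  list(states = states, counts = counts, het_derived = het_derived)
}

.fixture_columns <- function(tab, exclude_homopolymer = TRUE) {
  data.frame(label = tab$labels, start = tab$start, end = tab$end,
             kind = tab$kind, homopolymer = tab$homopolymer,
             excluded = exclude_homopolymer & tab$homopolymer,
             consensus = tab$consensus, stringsAsFactors = FALSE)
}

#' Catalog fixture for one marker, as printed
#'
#' @param marker `"trnL-trnF"`, `"rpl32-trnL"` or `"ITS"`.
#' @param exclude_homopolymer mark the poly-T-attached 1 bp indel columns as
#'   excluded from type definition (default TRUE, the published convention).
#' @return a `cis_catalog` with the published type names, state vectors and
#'   per-species counts.
#' @export
fixture_catalog <- function(marker = c("trnL-trnF", "rpl32-trnL", "ITS"),
                            exclude_homopolymer = TRUE) {
  marker <- match.arg(marker)
  tab <- .fixture_tables()[[marker]]
  p <- .parse_table(tab)
  catalog_from_table(marker, .fixture_columns(tab, exclude_homopolymer),
                     p$states, p$counts, p$het_derived)
}

# deterministic invariant background for a fixture alignment
.fixture_background <- function(tab) {
  bg <- with_seed(20160101L + tab$length,
                  sample(c("A", "C", "G", "T"), tab$length, replace = TRUE))
  if (tab$marker == "trnL-trnF") {
    # poly-T stretch to which the 1 bp indels at 261/262 are attached
    bg[257:260] <- "T"
    # keep the 1 bp deletion at 366 away from any homopolymer context
    bg[363:365] <- c("A", "C", "G")
    bg[367:370] <- c("A", "C", "G", "A")
  }
  bg
}

# expand one type row into full-length residue characters
.expand_row <- function(tab, bg, states_row) {
  res <- bg
  for (k in seq_along(tab$labels)) {
    cls <- tab$start[k]:tab$end[k]
    st <- states_row[k]
    if (st == "-") {
      res[cls] <- "-"
    } else {
      ch <- strsplit(st, "", fixed = TRUE)[[1L]]
      if (length(ch) != length(cls))
        stop("fixture state '", st, "' does not fill columns ",
             tab$labels[k], call. = FALSE)
      res[cls] <- ch
    }
  }
  res
}

#' Alignment fixture for one marker
#'
#' Expands the published table into a full-length gapped alignment with one
#' sequence per sampled individual (the per-type, per-species `n` counts),
#' over a fixed invariant background. Sequences of types extracted solely
#' from heterozygous plants carry `provenance = "extracted_from_heterozygote"`.
#' Individuals are numbered within type and species; populations are assigned
#' as consecutive pairs (two individuals per population, the study's sampling
#' unit).
#'
#' @inheritParams fixture_catalog
#' @return a `cis_alignment`.
#' @export
fixture_alignment <- function(marker = c("trnL-trnF", "rpl32-trnL", "ITS")) {
  marker <- match.arg(marker)
  tab <- .fixture_tables()[[marker]]
  p <- .parse_table(tab)
  bg <- .fixture_background(tab)
  ids <- character(0); sp <- character(0); prov <- character(0)
  seqs <- character(0)
  for (i in seq_len(nrow(p$states))) {
    row_res <- paste(.expand_row(tab, bg, p$states[i, ]), collapse = "")
    for (s in colnames(p$counts)) {
      n <- p$counts[i, s]
      if (n == 0L) next
      tn <- rownames(p$states)[i]
      new_ids <- sprintf("%s_%s_%02d", tn, s, seq_len(n))
      ids <- c(ids, new_ids)
      sp <- c(sp, rep(s, n))
      prov <- c(prov, rep(if (p$het_derived[i] > 0L)
        "extracted_from_heterozygote" else "direct", n))
      seqs <- c(seqs, rep(row_res, n))
    }
  }
  pops <- sprintf("P%03d", (seq_along(ids) + 1L) %/% 2L)
  alignment(stats::setNames(seqs, ids), species = sp, population = pops,
            provenance = prov, marker = marker)
}

#' All marker fixtures
#'
#' @return list with one entry per marker, each holding `alignment`,
#'   `catalog` (as printed) and `condensed` (the alignment run through
#'   [condense_alignment()]).
#' @export
paper_fixtures <- function() {
  out <- lapply(names(.fixture_tables()), function(m) {
    aln <- fixture_alignment(m)
    list(alignment = aln,
         catalog = fixture_catalog(m),
         condensed = condense_alignment(aln))
  })
  stats::setNames(out, names(.fixture_tables()))
}

#' Write fixture bundles to a directory
#'
#' Emits, for each marker, the alignment FASTA, the catalog TSV and the
#' condensed-matrix TSV.
#'
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(.fixture_tables())) {
    stem <- file.path(dir, gsub("[^A-Za-z0-9]", "", m))
    aln <- fixture_alignment(m)
    write_aligned_fasta(aln, paste0(stem, ".fasta"))
    export_catalog(fixture_catalog(m), paste0(stem, "_types.tsv"))
    export_condensed(condense_alignment(aln), paste0(stem, "_condensed.tsv"))
  }
  invisible(dir)
}
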