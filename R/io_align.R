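#' Construct a marker alignment
#'
#' An alignment is the package's central container: a set of equal-length,
#' gapped nucleotide sequences with per-sequence metadata (species label,
#' population id, provenance). All column coordinates reported anywhere in the
#' package are 1-based alignment-column indices, matching the convention of
#' published variable-site tables; unaligned (degapped) coordinates appear only
#' inside the phasing forward model and are labelled as such.
#'
#' @param residues named character vector of gapped sequences (names are
#'   sequence ids). Case-insensitive; stored uppercase; `U` is mapped to `T`.
#' @param species,population character vectors recycled to the number of
#'   sequences; default `"unknown"`.
#' @param provenance one of `"direct"`, `"extracted_from_heterozygote"`,
#'   `"dominant_only"` per sequence. Sequences recovered from mixed reads carry
#'   a provenance flag so that downstream tabulations can report them
#'   separately.
#' @param marker marker label, e.g. `"ITS"`, `"trnL-trnF"`, `"rpl32-trnL"`.
#' @param log optional audit log environment from [new_log()].
#'
#' @return an object of class `cis_alignment`: a list with elements `mat`
#'   (sequence-by-column character matrix), `meta` (data frame of id, species,
#'   population, provenance) and `marker`.
#' @export
alignment <- function(residues, species = "unknown", population = "unknown",
                      provenance = "direct", marker = "other", log = NULL) {
  if (length(residues) < 1L) stop("alignment needs at least one sequence", call. = FALSE)
  ids <- names(residues)
  if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids))
    stop("every sequence needs a non-empty id", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicated sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)

  residues <- toupper(residues)
  if (any(grepl("U", residues, fixed = TRUE))) {
    residues <- gsub("U", "T", residues, fixed = TRUE)
    log_note(log, "input contained 'U' residues; mapped to 'T'")
  }

  lens <- nchar(residues)
  if (length(unique(lens)) != 1L)
    stop("alignment-shape error: sequence lengths differ (",
         paste(unique(lens), collapse = ", "), ")", call. = FALSE)

  mat <- do.call(rbind, strsplit(residues, "", fixed = TRUE))
  rownames(mat) <- ids
  ok <- matrix(valid_residues(mat), nrow = nrow(mat))
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("character error: illegal residue '", mat[bad[1, 1], bad[1, 2]],
         "' in sequence '", ids[bad[1, 1]], "' at column ", bad[1, 2],
         call. = FALSE)

  provenance <- rep_len(provenance, length(ids))
  ok <- provenance %in% c("direct", "extracted_from_heterozygote", "dominant_only")
  if (!all(ok))
    stop("unknown provenance: ", paste(unique(provenance[!ok]), collapse = ", "),
         call. = FALSE)

  meta <- data.frame(
    id = ids,
    species = rep_len(as.character(species), length(ids)),
    population = rep_len(as.character(population), length(ids)),
    provenance = provenance,
    stringsAsFactors = FALSE
  )
  structure(list(mat = mat, meta = meta, marker = marker),
            class = "cis_alignment")
}

#' @export
print.cis_alignment <- function(x, ...) {
  cat("<cis_alignment> marker=", x$marker, ": ", nrow(x$mat), " sequences x ",
      ncol(x$mat), " columns\n", sep = "")
  invisible(x)
}

#' Number of columns / sequences of an alignment
#' @param aln a `cis_alignment`
#' @return integer
#' @export
aln_length <- function(aln) ncol(aln$mat)

#' @rdname aln_length
#' @export
aln_size <- function(aln) nrow(aln$mat)

#' Read an aligned FASTA file
#'
#' Reads a gapped multi-FASTA into a [alignment()] object. Per-sequence
#' metadata is parsed from an `id|species|population|provenance` header
#' convention when present; absent fields default to `"unknown"` (provenance to
#' `"direct"`).
#'
#' @param path FASTA file path.
#' @param marker marker label attached to the alignment.
#' @param log optional audit log.
#' @return a `cis_alignment`.
#' @export
read_aligned_fasta <- function(path, marker = "other", log = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  headers <- names(ss)
  fields <- strsplit(headers, "|", fixed = TRUE)
  get_field <- function(i, default) {
    vapply(fields, function(f) {
      v <- if (length(f) >= i) trimws(f[[i]]) else ""
      if (nzchar(v)) v else default
    }, "")
  }
  res <- stats::setNames(as.character(ss), get_field(1L, ""))
  alignment(res,
            species = get_field(2L, "unknown"),
            population = get_field(3L, "unknown"),
            provenance = get_field(4L, "direct"),
            marker = marker, log = log)
}

#' Write an alignment to FASTA
#'
#' Headers use the `id|species|population|provenance` convention, so that
#' `read_aligned_fasta(write_aligned_fasta(aln))` round-trips ids, residues,
#' order and provenance bit-exactly.
#'
#' @param aln a `cis_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "cis_alignment"))
  headers <- paste(aln$meta$id, aln$meta$species, aln$meta$population,
                   aln$meta$provenance, sep = "|")
  seqs <- apply(aln$mat, 1L, paste, collapse = "")
  ss <- Biostrings::BStringSet(stats::setNames(seqs, headers))
  Biostrings::writeXStringSet(ss, filepath = path, width = 80L)
  invisible(path)
}

#' Read a population metadata table
#'
#' @param path CSV with header columns `population,country,latitude,longitude,species`.
#' @return data frame with one validated record per population row.
#' @export
read_population_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("population", "country", "latitude", "longitude", "species")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L)
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  tab$latitude <- as.numeric(tab$latitude)
  tab$longitude <- as.numeric(tab$longitude)
  if (any(is.na(tab$latitude)) || any(tab$latitude < -90 | tab$latitude > 90))
    stop("value error: latitude outside [-90, 90]", call. = FALSE)
  if (any(is.na(tab$longitude)) || any(tab$longitude < -180 | tab$longitude > 180))
    stop("value error: longitude outside [-180, 180]", call. = FALSE)
  coords <- paste(tab$latitude, tab$longitude)
  for (p in unique(tab$population)) {
    if (length(unique(coords[tab$population == p])) > 1L)
      stop("schema error: population '", p,
           "' appears with differing coordinates", call. = FALSE)
  }
  tab[, required]
}
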