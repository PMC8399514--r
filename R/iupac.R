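#' @name iupac
#' @title IUPAC nucleotide ambiguity utilities
#'
#' @description
#' Internal helpers mapping between IUPAC nucleotide codes and the base sets
#' they denote. Additive polymorphic sites in direct Sanger reads are reported
#' as the IUPAC union of the two superimposed template bases (e.g. C + G = S),
#' so superposition and base subtraction reduce to set union and set difference
#' on these codes.
#'
#' @keywords internal
NULL

# code -> sorted base set, gaps excluded; "-" handled separately throughout
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.IUPAC_CODE <- local({
  keys <- vapply(.IUPAC_SETS, function(b) paste(sort(b), collapse = ""), "")
  stats::setNames(names(.IUPAC_SETS), keys)
})

.VALID_RESIDUES <- c(names(.IUPAC_SETS), "-")

iupac_bases <- function(code) {
  s <- .IUPAC_SETS[[code]]
  if (is.null(s)) stop("not an IUPAC nucleotide code: '", code, "'", call. = FALSE)
  s
}

iupac_union <- function(a, b) {
  key <- paste(sort(unique(c(iupac_bases(a), iupac_bases(b)))), collapse = "")
  unname(.IUPAC_CODE[[key]])
}

#' Is a residue an ambiguity (additive) code?
#' @noRd
is_ambiguous <- function(x) {
  x %in% c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
}

# Vectorised character validity check (uppercase canonical alphabet + gap).
valid_residues <- function(x) x %in% .VALID_RESIDUES
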