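#' @name phasing
#' @title Deconvolution of superimposed ITS paralogs from direct Sanger reads
#'
#' @description
#' A direct Sanger read over two co-amplified, divergent ITS paralogs shows
#' additive polymorphic sites (double peaks, IUPAC ambiguity codes) where the
#' two templates differ, and -- when the templates differ by a length mutation
#' -- sustained ambiguity ("noise") downstream of the indel where the two
#' templates are read out of register. These functions model that read as the
#' position-wise IUPAC union of the two templates, detect the heterozygous
#' signature, and recover the second template by subtracting a clean reference
#' sequence base by base.
NULL

#' Construct a mixed direct-sequencing trace
#'
#' @param read IUPAC nucleotide string in read (degapped) coordinates.
#' @param source_id identifier of the sequenced individual.
#' @param mixing `"balanced"` (the two templates at equivalent copy numbers)
#'   or `"skewed"` (one template underrepresented).
#' @param major optional major-peak base calls (ungapped string, same length
#'   as `read`): at an additive site a real chromatogram still shows which
#'   peak is taller, and for skewed mixtures that major call is what the
#'   predominant-ribotype extraction reads off.
#' @return an object of class `cis_trace`.
#' @export
mixed_trace <- function(read, source_id = "trace", mixing = "balanced",
                        major = NULL) {
  read <- toupper(read)
  ch <- strsplit(read, "", fixed = TRUE)[[1L]]
  if (any(ch == "-")) stop("trace reads are degapped; gap character found",
                           call. = FALSE)
  if (!all(valid_residues(ch)))
    stop("illegal residue in trace read", call. = FALSE)
  if (!mixing %in% c("balanced", "skewed"))
    stop("mixing must be 'balanced' or 'skewed'", call. = FALSE)
  if (!is.null(major) && nchar(major) != nchar(read))
    stop("major-peak calls must match the read length", call. = FALSE)
  structure(list(read = read, source_id = source_id, mixing = mixing,
                 major = major),
            class = "cis_trace")
}

#' Superposition model parameters
#'
#' @param indel_motif the length mutation distinguishing the paralog groups
#'   (default the 6 bp insertion `CGTCCT`).
#' @param snp_range integer interval of SNP counts between paralog pairs
#'   (default 1--5).
#' @param max_offset register offsets searched downstream of the breakpoint,
#'   in both directions (default 10; the documented event is 6 bp but the
#'   method does not hard-code it).
#' @param support_threshold minimum fraction of post-shift positions the
#'   shifted reference must explain (default 0.9).
#' @param minor_rate probability that the underrepresented template surfaces
#'   as a double peak at a differing position in a skewed mixture
#'   (default 0.1).
#' @return a list of class `cis_superposition_model`.
#' @export
superposition_model <- function(indel_motif = "CGTCCT", snp_range = c(1L, 5L),
                                max_offset = 10L, support_threshold = 0.9,
                                minor_rate = 0.1) {
  if (nchar(indel_motif) == 0L) stop("indel motif must be non-empty", call. = FALSE)
  structure(list(indel_motif = toupper(indel_motif),
                 snp_range = as.integer(snp_range),
                 max_offset = as.integer(max_offset),
                 support_threshold = support_threshold,
                 minor_rate = minor_rate),
            class = "cis_superposition_model")
}

#' Superimpose two templates into a mixed trace
#'
#' Forward model of the direct chromatogram over two co-amplified templates.
#' In a balanced mixture the read at each position is the IUPAC union of the
#' two template bases (over the length of the shorter template, as the
#' chromatogram becomes a strict superposition of the two registers). In a
#' skewed mixture the read shows the dominant template (`t1`), with the minor
#' base surfacing as an additive site only at positions sampled at
#' `minor_rate`.
#'
#' @param t1,t2 ungapped template sequences; `t1` is the dominant template in
#'   skewed mode. Lengths may differ by a length mutation.
#' @param mixing `"balanced"` or `"skewed"`.
#' @param seed integer seed for the skewed-mode sampling (required there for
#'   reproducibility).
#' @param minor_rate minor-detection rate in skewed mode.
#' @param source_id id attached to the trace.
#' @return a [mixed_trace()].
#' @export
superimpose <- function(t1, t2, mixing = "balanced", seed = NULL,
                        minor_rate = 0.1, source_id = "trace") {
  c1 <- strsplit(toupper(t1), "", fixed = TRUE)[[1L]]
  c2 <- strsplit(toupper(t2), "", fixed = TRUE)[[1L]]
  if (any(c1 == "-") || any(c2 == "-"))
    stop("templates must be ungapped", call. = FALSE)
  L <- min(length(c1), length(c2))
  c1 <- c1[seq_len(L)]
  c2 <- c2[seq_len(L)]
  read <- character(L)
  if (mixing == "balanced") {
    same <- c1 == c2
    read[same] <- c1[same]
    read[!same] <- mapply(iupac_union, c1[!same], c2[!same])
  } else if (mixing == "skewed") {
    surface <- if (is.null(seed)) stats::runif(L) < minor_rate else
      with_seed(seed, stats::runif(L) < minor_rate)
    read <- c1
    show <- c1 != c2 & surface
    read[show] <- mapply(iupac_union, c1[show], c2[show])
  } else stop("mixing must be 'balanced' or 'skewed'", call. = FALSE)
  mixed_trace(paste(read, collapse = ""), source_id = source_id,
              mixing = mixing,
              major = if (mixing == "skewed") paste(c1, collapse = "") else NULL)
}

#' Detect the heterozygous signature in a direct read
#'
#' A read is called heterozygous when it contains a sustained run of ambiguity
#' codes: some window of `window` read positions holding at least `min_run`
#' ambiguities (the out-of-register "noise" downstream of a length mutation
#' between the two templates). The breakpoint is the first ambiguous position
#' opening such a window. Isolated additive sites alone do not trigger a
#' heterozygote call -- such reads define typed sequence variants carrying
#' ambiguity states, not phasing candidates -- and are reported in
#' `additive_sites`.
#'
#' @param trace a [mixed_trace()].
#' @param window window length in read positions (default 20).
#' @param min_run minimum ambiguities within one window (default 4).
#' @return list with `is_heterozygous`, `additive_sites` (isolated ambiguity
#'   positions upstream of the breakpoint, or all ambiguities for
#'   non-heterozygous reads), `breakpoint` (read position, `NA` when absent)
#'   and `n_ambiguities`.
#' @export
detect_heterozygote <- function(trace, window = 20L, min_run = 4L) {
  stopifnot(inherits(trace, "cis_trace"))
  if (window < min_run)
    stop("parameter error: window must be >= min_run", call. = FALSE)
  ch <- strsplit(trace$read, "", fixed = TRUE)[[1L]]
  amb <- which(is_ambiguous(ch))
  breakpoint <- NA_integer_
  for (a in amb) {
    if (sum(amb >= a & amb <= a + window - 1L) >= min_run) {
      breakpoint <- a
      break
    }
  }
  is_het <- !is.na(breakpoint)
  list(is_heterozygous = is_het,
       additive_sites = if (is_het) amb[amb < breakpoint] else amb,
       breakpoint = breakpoint,
       n_ambiguities = length(amb))
}

# subtract a reference base from one read character
.subtract_base <- function(read_ch, ref_ch) {
  if (!is_ambiguous(read_ch)) return(read_ch)
  rem <- setdiff(iupac_bases(read_ch), ref_ch)
  if (length(rem) == 0L) return(ref_ch)
  key <- paste(sort(rem), collapse = "")
  unname(.IUPAC_CODE[[key]])
}

#' Recover the second template by reference base subtraction
#'
#' Upstream of the breakpoint the second template is read off directly: at
#' each additive site it is the member of the ambiguity set that differs from
#' the reference; elsewhere it equals the read. Downstream of the breakpoint
#' the reference register may have shifted by the length mutation, so
#' candidate offsets up to `model$max_offset` in both directions are scored by
#' the fraction of positions whose read ambiguity set contains the shifted
#' reference base; the smallest-magnitude offset whose support reaches the
#' model's threshold (positive direction first at equal magnitude) is adopted
#' and subtraction continues in that register -- the minimal register shift
#' explaining the tail, which keeps a slightly divergent reference from
#' hijacking the register via a spuriously perfect larger shift. For
#' a balanced, noise-free trace built by [superimpose()] from templates
#' `R1`/`R2`, subtraction with reference `R1` returns `R2` exactly over the
#' resolvable window (the read length), and symmetrically for `R2`.
#'
#' Skewed traces cannot be fully deconvoluted; there the predominant template
#' is extracted (`mode = "dominant_only"`) and no second ribotype is returned.
#'
#' @param trace a [mixed_trace()].
#' @param reference ungapped reference sequence, at least as long as the read.
#' @param model a [superposition_model()].
#' @param window,min_run passed to [detect_heterozygote()] for breakpoint
#'   location.
#' @return list of class `cis_phasing` with `ribotype_1` (the reference used),
#'   `ribotype_2` (recovered sequence, `NULL` in dominant-only mode),
#'   `dominant` (dominant-template read, dominant-only mode), `breakpoint`,
#'   `offset`, `resolved_through` (last resolved read position) and `mode`.
#' @export
subtract_reference <- function(trace, reference, model = superposition_model(),
                               window = 20L, min_run = 4L) {
  stopifnot(inherits(trace, "cis_trace"))
  read <- strsplit(trace$read, "", fixed = TRUE)[[1L]]
  ref <- strsplit(toupper(reference), "", fixed = TRUE)[[1L]]
  if (any(ref == "-")) stop("reference must be ungapped", call. = FALSE)
  L <- length(read)
  if (length(ref) < L)
    stop("reference shorter than trace read", call. = FALSE)

  if (trace$mixing == "skewed") {
    # the predominant template follows the major peak calls when available;
    # otherwise ambiguities resolve toward the reference base
    dom <- if (!is.null(trace$major))
      strsplit(trace$major, "", fixed = TRUE)[[1L]]
    else vapply(seq_len(L), function(k) {
      if (!is_ambiguous(read[k])) read[k]
      else if (ref[k] %in% iupac_bases(read[k])) ref[k]
      else iupac_bases(read[k])[1L]
    }, "")
    return(structure(list(ribotype_1 = toupper(reference), ribotype_2 = NULL,
                          dominant = paste(dom, collapse = ""),
                          breakpoint = NA_integer_, offset = NA_integer_,
                          resolved_through = L, read_length = L,
                          mode = "dominant_only"),
                     class = "cis_phasing"))
  }

  det <- detect_heterozygote(trace, window = window, min_run = min_run)
  bp <- det$breakpoint
  r2 <- character(L)
  head_end <- if (is.na(bp)) L else bp - 1L
  for (k in seq_len(head_end)) r2[k] <- .subtract_base(read[k], ref[k])
  offset <- 0L
  resolved <- L
  if (!is.na(bp)) {
    cand <- c(0L, as.vector(rbind(seq_len(model$max_offset),
                                  -seq_len(model$max_offset))))
    score <- vapply(cand, function(d) {
      ks <- bp:L
      ks <- ks[ks + d >= 1L & ks + d <= length(ref)]
      if (length(ks) == 0L) return(0)
      mean(vapply(ks, function(k)
        ref[k + d] %in% iupac_bases(read[k]), logical(1)))
    }, numeric(1))
    qualifying <- which(score >= model$support_threshold)
    best <- if (length(qualifying) > 0L) qualifying[1L] else which.max(score)
    if (score[best] < model$support_threshold) {
      warning("unresolvable tail: no reference offset reaches the support ",
              "threshold; result truncated at the breakpoint")
      resolved <- bp - 1L
      r2 <- r2[seq_len(resolved)]
    } else {
      offset <- cand[best]
      for (k in bp:L) {
        rk <- k + offset
        r2[k] <- if (rk >= 1L && rk <= length(ref))
          .subtract_base(read[k], ref[rk]) else read[k]
      }
    }
  }
  structure(list(ribotype_1 = toupper(reference),
                 ribotype_2 = paste(r2, collapse = ""),
                 dominant = NULL,
                 breakpoint = bp, offset = offset,
                 resolved_through = resolved, read_length = L,
                 mode = "both_recovered"),
            class = "cis_phasing")
}

#' @export
print.cis_phasing <- function(x, ...) {
  cat("<cis_phasing> mode=", x$mode, "; breakpoint=", x$breakpoint,
      "; resolved_through=", x$resolved_through, "\n", sep = "")
  invisible(x)
}

# does (reference, r2) re-superimpose to the observed read exactly?
.phasing_consistent <- function(trace, res) {
  if (res$mode != "both_recovered") return(FALSE)
  read <- strsplit(trace$read, "", fixed = TRUE)[[1L]]
  ref <- strsplit(res$ribotype_1, "", fixed = TRUE)[[1L]]
  r2 <- strsplit(res$ribotype_2, "", fixed = TRUE)[[1L]]
  if (length(r2) < length(read)) return(FALSE)
  for (k in seq_along(read)) {
    rk <- if (!is.na(res$breakpoint) && k >= res$breakpoint) k + res$offset else k
    if (rk < 1L || rk > length(ref)) return(FALSE)
    if (is_ambiguous(ref[rk]) || is_ambiguous(r2[k])) return(FALSE)
    hat <- if (ref[rk] == r2[k]) ref[rk] else iupac_union(ref[rk], r2[k])
    if (hat != read[k]) return(FALSE)
  }
  TRUE
}

#' Phase one individual against geographically ranked references
#'
#' Clean sequences of geographically neighbouring accessions are tried as
#' references in ascending distance. Among equidistant candidates the longer
#' reference is preferred (an insertion-bearing reference maximises the
#' resolvable window of the recovered allele), then id order; tie decisions
#' are recorded. The first reference whose subtraction is consistent with the
#' trace -- re-superimposing the reference and the recovered ribotype
#' reproduces the read exactly -- is accepted. Skewed traces accept the
#' nearest reference and return the dominant template only.
#'
#' @param trace a [mixed_trace()].
#' @param candidates data frame with columns `id`, `sequence`, `distance`
#'   (any nonnegative geographic distance measure).
#' @param model a [superposition_model()].
#' @param log optional audit log.
#' @return a `cis_phasing` result with `reference_id` attached.
#' @export
phase_individual <- function(trace, candidates, model = superposition_model(),
                             log = NULL) {
  stopifnot(inherits(trace, "cis_trace"))
  if (is.null(candidates) || nrow(candidates) == 0L)
    stop("phasing failed: no candidate references", call. = FALSE)
  ord <- order(candidates$distance, -nchar(candidates$sequence), candidates$id)
  candidates <- candidates[ord, , drop = FALSE]
  if (nrow(candidates) > 1L &&
      candidates$distance[1L] == candidates$distance[2L])
    log_note(log, "tied reference distances for ", trace$source_id,
             "; trying '", candidates$id[1L], "' first by id order")
  for (i in seq_len(nrow(candidates))) {
    if (nchar(candidates$sequence[i]) < nchar(trace$read)) next
    res <- withCallingHandlers(
      subtract_reference(trace, candidates$sequence[i], model = model),
      warning = function(w) invokeRestart("muffleWarning"))
    if (trace$mixing == "skewed" || .phasing_consistent(trace, res)) {
      res$reference_id <- candidates$id[i]
      log_note(log, "phased ", trace$source_id, " with reference '",
               candidates$id[i], "' (distance ", candidates$distance[i], ")")
      return(res)
    }
  }
  stop("phasing failed: no candidate reference consistent with trace '",
       trace$source_id, "'", call. = FALSE)
}
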