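#' @name pipeline
#' @title End-to-end typing pipeline
NULL

.default_params <- function() {
  list(min_main_count = 10L,
       homopolymer_base = "T",
       homopolymer_min_run = 4L,
       exclude_homopolymer = TRUE,
       phasing_window = 20L,
       phasing_min_run = 4L,
       indel_motif = "CGTCCT",
       max_offset = 10L,
       support_threshold = 0.9,
       minor_rate = 0.1,
       msn_metric = "provesti",
       em_chlorotype = "A",
       em_ribotype = "A",
       wm_chlorotypes = c("C", "D", "E"))
}

# Re-insert a recovered (ungapped) allele into alignment coordinates.
#
# The register is decided from the phasing result: no breakpoint means the
# two templates had equal length, so the allele fills a gap pattern with
# exactly its residue count; a breakpoint with a reference no longer than the
# read means the recovered allele carries the insertion, so it is the prefix
# of a longer gap pattern. Candidate patterns are the distinct gap masks of
# the existing alignment (plus the gapless mask). Residue positions beyond
# the resolvable window are filled from the column majority state and the
# fill is logged; such positions are invariant in practice, downstream of
# every tabulated variable column.
regap_recovered <- function(seq, res, aln, log = NULL) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  masks <- unique(as.data.frame(aln$mat == "-"))
  masks <- rbind(masks, rep(FALSE, ncol(aln$mat)))
  masks <- unique(masks)
  counts <- ncol(aln$mat) - rowSums(masks)

  longer <- !is.null(res) && !is.na(res$breakpoint) &&
    nchar(res$ribotype_1) <= res$read_length
  target <- if (longer) {
    bigger <- sort(counts[counts > n])
    if (length(bigger) > 0L) bigger[1L] else n
  } else n
  cand <- which(counts == target)
  if (length(cand) == 0L)
    stop("no alignment gap pattern fits a recovered allele of length ", n,
         call. = FALSE)
  mask <- as.logical(masks[cand[1L], ])

  out <- rep("-", length(mask))
  res_pos <- which(!mask)
  out[res_pos[seq_len(n)]] <- ch
  if (length(res_pos) > n) {
    fill_pos <- res_pos[(n + 1L):length(res_pos)]
    for (p in fill_pos) {
      col <- aln$mat[, p]
      col <- col[col != "-"]
      out[p] <- if (length(col) == 0L) "N" else
        names(sort(table(col), decreasing = TRUE))[1L]
    }
    log_note(log, "filled ", length(fill_pos),
             " positions beyond the resolvable window from column majority")
  }
  paste(out, collapse = "")
}

.read_trace_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  fields <- strsplit(names(ss), "|", fixed = TRUE)
  get_field <- function(i, default) vapply(fields, function(f) {
    v <- if (length(f) >= i) trimws(f[[i]]) else ""
    if (nzchar(v)) v else default
  }, "")
  data.frame(id = get_field(1L, ""), species = get_field(2L, "unknown"),
             population = get_field(3L, "unknown"),
             mixing = get_field(4L, "balanced"),
             read = as.character(ss), stringsAsFactors = FALSE)
}

#' Run the full typing pipeline
#'
#' Executes, for every configured marker, variable-site extraction, type
#' definition and main-type designation; for ITS, additionally heterozygote
#' detection and phasing of direct reads against geographically ranked clean
#' references (both recovered alleles re-enter the alignment with
#' heterozygote provenance before final typing); then network construction,
#' per-population composition, clade calls and KML export. Any stage failure
#' aborts with a stage-named error; outputs already written are retained. The
#' run is deterministic given the config: two runs produce byte-identical
#' outputs.
#'
#' @param config a YAML file path or list with elements `markers` (list of
#'   `list(name=, alignment=, reads=)` entries), `metadata` (population CSV
#'   path), optional `params` (overriding [.default_params()] entries) and
#'   `seed`.
#' @param out_dir optional output directory; when given, catalogs, condensed
#'   matrices, the phasing report, networks (GraphML + DOT), composition
#'   tables, KML maps and the run log are written there.
#' @return list with `catalogs`, `networks`, `composition`, `phasing_report`,
#'   `log` (character vector) and `params`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  params <- utils::modifyList(.default_params(), config$params %||% list())
  log <- new_log()
  if (!is.null(config$seed)) set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(fname, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    writer(file.path(out_dir, fname))
  }

  pops <- stage("metadata", read_population_table(config$metadata))

  markers <- config$markers
  names(markers) <- vapply(markers, function(m) m$name, "")
  alignments <- list()
  for (m in names(markers)) {
    alignments[[m]] <- stage(paste0("read:", m),
      read_aligned_fasta(markers[[m]]$alignment, marker = m, log = log))
  }

  model <- superposition_model(indel_motif = params$indel_motif,
                               max_offset = params$max_offset,
                               support_threshold = params$support_threshold,
                               minor_rate = params$minor_rate)

  # --- ITS phasing -------------------------------------------------------
  phasing_report <- NULL
  if ("ITS" %in% names(markers) && !is.null(markers$ITS$reads)) {
    phased <- stage("phasing", {
      aln <- alignments$ITS
      reads <- .read_trace_fasta(markers$ITS$reads)
      clean_deg <- apply(aln$mat, 1L, function(r) paste(r[r != "-"], collapse = ""))
      ref_pop <- aln$meta$population
      coords <- function(p) {
        i <- match(p, pops$population)
        c(pops$longitude[i], pops$latitude[i])
      }
      add_ids <- character(0); add_seqs <- character(0)
      add_pop <- character(0); add_sp <- character(0); add_prov <- character(0)
      report <- list()
      for (i in seq_len(nrow(reads))) {
        tr <- mixed_trace(reads$read[i], source_id = reads$id[i],
                          mixing = reads$mixing[i])
        det <- detect_heterozygote(tr, window = params$phasing_window,
                                   min_run = params$phasing_min_run)
        if (!det$is_heterozygous) {
          row <- regap_recovered(tr$read, NULL, aln, log = log)
          add_ids <- c(add_ids, reads$id[i]); add_seqs <- c(add_seqs, row)
          add_pop <- c(add_pop, reads$population[i])
          add_sp <- c(add_sp, reads$species[i]); add_prov <- c(add_prov, "direct")
          report[[i]] <- data.frame(id = reads$id[i], heterozygous = FALSE,
                                    breakpoint = NA_integer_, mode = "clean",
                                    reference = NA_character_,
                                    additive_sites = length(det$additive_sites))
          next
        }
        here <- coords(reads$population[i])
        dists <- vapply(ref_pop, function(p) {
          there <- coords(p)
          if (anyNA(there) || anyNA(here)) Inf else
            geosphere::distGeo(here, there)
        }, numeric(1))
        keep <- default_individual_of(rownames(aln$mat)) != reads$id[i]
        cand <- data.frame(id = rownames(aln$mat)[keep],
                           sequence = unname(clean_deg[keep]),
                           distance = unname(dists[keep]),
                           stringsAsFactors = FALSE)
        res <- phase_individual(tr, cand, model = model, log = log)
        if (res$mode == "dominant_only") {
          row <- regap_recovered(res$dominant, NULL, aln, log = log)
          add_ids <- c(add_ids, paste0(reads$id[i], "_dom"))
          add_seqs <- c(add_seqs, row)
          add_pop <- c(add_pop, reads$population[i])
          add_sp <- c(add_sp, reads$species[i])
          add_prov <- c(add_prov, "dominant_only")
        } else {
          row1 <- paste(aln$mat[res$reference_id, ], collapse = "")
          row2 <- regap_recovered(res$ribotype_2, res, aln, log = log)
          add_ids <- c(add_ids, paste0(reads$id[i], c("_p1", "_p2")))
          add_seqs <- c(add_seqs, c(row1, row2))
          add_pop <- c(add_pop, rep(reads$population[i], 2L))
          add_sp <- c(add_sp, rep(reads$species[i], 2L))
          add_prov <- c(add_prov, rep("extracted_from_heterozygote", 2L))
        }
        report[[i]] <- data.frame(id = reads$id[i], heterozygous = TRUE,
                                  breakpoint = det$breakpoint, mode = res$mode,
                                  reference = res$reference_id %||% NA_character_,
                                  additive_sites = length(det$additive_sites))
      }
      all_res <- c(stats::setNames(apply(aln$mat, 1L, paste, collapse = ""),
                                   rownames(aln$mat)),
                   stats::setNames(add_seqs, add_ids))
      alignments$ITS <- alignment(
        all_res,
        species = c(aln$meta$species, add_sp),
        population = c(aln$meta$population, add_pop),
        provenance = c(aln$meta$provenance, add_prov),
        marker = "ITS", log = log)
      do.call(rbind, report)
    })
    phasing_report <- phased
    emit("phasing_report.tsv", function(f)
      utils::write.table(phased, f, sep = "\t", quote = FALSE, row.names = FALSE))
  } else if ("ITS" %in% names(markers)) {
    log_note(log, "no ITS reads configured; phasing skipped")
  } else {
    log_note(log, "no ITS marker configured; chloroplast-only run, phasing skipped")
  }

  # --- typing ------------------------------------------------------------
  catalogs <- list()
  for (m in names(markers)) {
    catalogs[[m]] <- stage(paste0("typing:", m), {
      cm <- condense_alignment(alignments[[m]],
                               base = params$homopolymer_base,
                               min_run = params$homopolymer_min_run,
                               exclude_homopolymer = params$exclude_homopolymer,
                               log = log)
      emit(paste0(gsub("[^A-Za-z0-9]", "", m), "_condensed.tsv"),
           function(f) export_condensed(cm, f))
      cat <- designate_mains(define_types(cm, log = log),
                             min_main_count = params$min_main_count)
      emit(paste0(gsub("[^A-Za-z0-9]", "", m), "_types.tsv"),
           function(f) export_catalog(cat, f))
      cat
    })
  }

  # --- networks ----------------------------------------------------------
  networks <- list()
  for (m in names(catalogs)) {
    if (n_types(catalogs[[m]]) < 2L) next
    networks[[m]] <- stage(paste0("network:", m), {
      cat <- catalogs[[m]]
      net <- build_msn(pairwise_matrix(cat, metric = params$msn_metric),
                       sizes = rowSums(cat$counts), cat = cat)
      emit(paste0(gsub("[^A-Za-z0-9]", "", m), ".graphml"),
           function(f) export_network(net, f, "graphml"))
      emit(paste0(gsub("[^A-Za-z0-9]", "", m), ".dot"),
           function(f) export_network(net, f, "dot"))
      net
    })
  }

  # --- composition and maps ---------------------------------------------
  chloro_name <- setdiff(names(catalogs), "ITS")
  comp <- stage("composition", {
    main <- compose_population_table(
      if (length(chloro_name) > 0L) catalogs[[chloro_name[1L]]] else NULL,
      catalogs[["ITS"]],
      pops,
      em_chlorotype = params$em_chlorotype,
      em_ribotype = params$em_ribotype,
      wm_chlorotypes = params$wm_chlorotypes)
    for (m in chloro_name[-1L]) {
      extra <- compose_population_table(catalogs[[m]], NULL, pops)
      main$composition <- rbind(main$composition, extra$composition)
    }
    main
  })
  emit("composition.tsv", function(f)
    utils::write.table(comp$composition, f, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  if (!is.null(comp$clades))
    emit("clades.csv", function(f)
      utils::write.csv(comp$clades, f, row.names = FALSE))
  for (m in names(catalogs)) {
    emit(paste0(gsub("[^A-Za-z0-9]", "", m), ".kml"), function(f)
      export_kml(comp, pops, m, f))
  }

  log_note(log, "parameters: ", paste(names(params), vapply(params, function(p)
    paste(p, collapse = "/"), ""), sep = "=", collapse = "; "))
  emit("run_log.txt", function(f) writeLines(log$entries, f))

  list(catalogs = catalogs, networks = networks, composition = comp,
       phasing_report = phasing_report, log = log$entries, params = params)
}
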