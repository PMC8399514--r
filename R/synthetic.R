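#' Simulation specification for synthetic marker datasets
#'
#' Defines the study conditions the generator emulates: equal-length marker
#' alignments (defaults 427 / 899 / 699 columns for the two chloroplast
#' spacers and ITS), populations of two sequenced individuals arranged in
#' geographic regions, a ubiquitous ribotype co-occurring in every region
#' with one regionally distributed ribotype, paralog pairs differing by 1--5
#' SNPs plus a 6 bp insertion (`CGTCCT`) in the last third of the sequence,
#' and a heterozygote fraction of 0.27 of sequenced individuals. The
#' skewed-mix fraction defaults to 0: the default dataset models the
#' equivalent-copy-number mixtures that base subtraction fully resolves;
#' skewed (underrepresented-paralog) mixtures are generated only on request.
#'
#' @param marker_lengths named integer vector of alignment lengths.
#' @param n_regions number of geographic regions (each with its own regional
#'   ribotype and chlorotype).
#' @param populations_per_region,individuals_per_population sampling design
#'   (default 4 populations of 2 individuals per region).
#' @param variants_per_main rare one-SNP variants derived from each regional
#'   ribotype, each carried by one homozygous individual (default 1).
#' @param snp_range SNPs between the ubiquitous and a regional ribotype.
#' @param indel_motif insertion carried by all regional ribotypes.
#' @param het_fraction probability that an individual is an ITS heterozygote.
#' @param skewed_fraction fraction of heterozygotes with skewed mixing.
#' @param minor_rate minor-detection rate for skewed mixtures.
#' @param seed integer seed; all generation is a pure function of the spec.
#' @return a list of class `cis_simspec`.
#' @export
simulation_spec <- function(marker_lengths = c("trnL-trnF" = 427L,
                                               "rpl32-trnL" = 899L,
                                               "ITS" = 699L),
                            n_regions = 3L,
                            populations_per_region = 4L,
                            individuals_per_population = 2L,
                            variants_per_main = 1L,
                            snp_range = c(1L, 5L),
                            indel_motif = "CGTCCT",
                            het_fraction = 0.27,
                            skewed_fraction = 0,
                            minor_rate = 0.1,
                            seed = 1L) {
  stopifnot(het_fraction >= 0, het_fraction <= 1,
            skewed_fraction >= 0, skewed_fraction <= 1,
            all(marker_lengths >= nchar(indel_motif) * 3L))
  structure(list(marker_lengths = marker_lengths, n_regions = n_regions,
                 populations_per_region = populations_per_region,
                 individuals_per_population = individuals_per_population,
                 variants_per_main = variants_per_main,
                 snp_range = as.integer(snp_range),
                 indel_motif = toupper(indel_motif),
                 het_fraction = het_fraction,
                 skewed_fraction = skewed_fraction,
                 minor_rate = minor_rate,
                 seed = as.integer(seed)),
            class = "cis_simspec")
}

.random_seq <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

# apply k SNPs at given positions (each to a different random base)
.apply_snps <- function(ch, pos) {
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  ch
}

#' Generate one synthetic paralog pair and its mixed trace
#'
#' `R2` equals `R1` with `k` SNPs (`k` uniform on the spec's SNP range) and,
#' with probability `indel_prob`, the indel motif inserted in the last third
#' of the sequence; the trace is their balanced superposition.
#'
#' @param spec a [simulation_spec()].
#' @param seed seed for this pair.
#' @param indel_prob probability of the insertion (default 0.5).
#' @return list with `R1`, `R2`, `trace` (a [mixed_trace()]) and `truth`
#'   (`k`, SNP read positions, `has_indel`, `insert_pos`).
#' @export
generate_trace_pair <- function(spec = simulation_spec(), seed = 1L,
                                indel_prob = 0.5) {
  L <- unname(spec$marker_lengths[["ITS"]]) - nchar(spec$indel_motif)
  with_seed(seed, {
    r1 <- .random_seq(L)
    k <- sample(seq(spec$snp_range[1L], spec$snp_range[2L]), 1L)
    snp_pos <- sort(sample.int(L, k))
    r2 <- .apply_snps(r1, snp_pos)
    has_indel <- stats::runif(1L) < indel_prob
    insert_pos <- NA_integer_
    if (has_indel) {
      insert_pos <- sample(seq(ceiling(2L * L / 3L), L), 1L)
      motif <- strsplit(spec$indel_motif, "", fixed = TRUE)[[1L]]
      r2 <- append(r2, motif, after = insert_pos - 1L)
    }
    R1 <- paste(r1, collapse = "")
    R2 <- paste(r2, collapse = "")
    list(R1 = R1, R2 = R2,
         trace = superimpose(R1, R2, mixing = "balanced"),
         truth = list(k = k, snp_pos = snp_pos, has_indel = has_indel,
                      insert_pos = insert_pos))
  })
}

#' Generate a full synthetic dataset with known truth
#'
#' Emulates the structure of a two-species phylogeographic marker survey:
#' `n_regions` geographic blocks of populations; one ubiquitous ITS ribotype
#' (`A`, insertion-free) present everywhere; per region one regional ribotype
#' (insertion-bearing, 1--5 SNPs from the ubiquitous one) and one regional
#' chlorotype per chloroplast marker. Each individual is, with probability
#' `het_fraction`, an ITS heterozygote carrying the ubiquitous plus the
#' regional ribotype (its direct read is their superposition, balanced unless
#' sampled into the skewed fraction); homozygotes carry one of the two
#' cleanly. Regional ribotype variants (one extra SNP) replace the regional
#' type in single homozygous carriers.
#'
#' @param spec a [simulation_spec()].
#' @return list with `alignments` (clean `cis_alignment` per marker; mixed
#'   ITS reads are *not* aligned), `traces` (list of [mixed_trace()] per
#'   heterozygote), `populations` (metadata data frame), `individuals`
#'   (truth: per-individual types, heterozygosity, mixing) and
#'   `ribotype_seqs` (named ungapped truth sequences).
#' @export
generate_dataset <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "cis_simspec"))
  with_seed(spec$seed, .generate_dataset_impl(spec))
}

.generate_dataset_impl <- function(spec) {
  motif <- strsplit(spec$indel_motif, "", fixed = TRUE)[[1L]]
  L_its <- unname(spec$marker_lengths[["ITS"]])
  L0 <- L_its - length(motif)
  nR <- spec$n_regions

  # --- ribotype truth sequences (ungapped) and alignment rows (gapped)
  base <- .random_seq(L0)
  insert_pos <- sample(seq(ceiling(2L * L0 / 3L), L0), 1L)
  repeat {
    snp_sets <- lapply(seq_len(nR), function(r) {
      k <- sample(seq(spec$snp_range[1L], spec$snp_range[2L]), 1L)
      sort(sample.int(L0, k))
    })
    regional <- lapply(snp_sets, function(pos) {
      ch <- .apply_snps(base, pos)
      append(ch, motif, after = insert_pos - 1L)
    })
    seqs <- vapply(regional, paste, "", collapse = "")
    if (!anyDuplicated(seqs) && !any(seqs == paste(base, collapse = "")))
      break
  }
  ribo_seqs <- c(A = paste(base, collapse = ""),
                 stats::setNames(vapply(regional, paste, "", collapse = ""),
                                 paste0("R", seq_len(nR))))
  # regional variants: one extra SNP on top of each regional type
  variant_seqs <- character(0)
  if (spec$variants_per_main > 0L) {
    for (r in seq_len(nR)) {
      for (v in seq_len(spec$variants_per_main)) {
        repeat {
          ch <- strsplit(ribo_seqs[[paste0("R", r)]], "", fixed = TRUE)[[1L]]
          ch <- .apply_snps(ch, sample.int(L0, 1L))
          s <- paste(ch, collapse = "")
          if (!s %in% c(ribo_seqs, variant_seqs)) break
        }
        variant_seqs[[paste0("R", r, "v", v)]] <- s
      }
    }
  }
  all_ribo <- c(ribo_seqs, variant_seqs)

  # gapped alignment row for a ribotype: insertion-free types carry gaps at
  # the motif columns
  gap_cols <- insert_pos:(insert_pos + length(motif) - 1L)
  regap <- function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    if (length(ch) == L_its) return(paste(ch, collapse = ""))
    paste(c(ch[seq_len(insert_pos - 1L)], rep("-", length(motif)),
            ch[insert_pos:length(ch)]), collapse = "")
  }

  # --- chlorotype truth per chloroplast marker: one type per region
  cp_markers <- setdiff(names(spec$marker_lengths), "ITS")
  chloro <- lapply(cp_markers, function(m) {
    Lm <- unname(spec$marker_lengths[[m]])
    bm <- .random_seq(Lm)
    types <- list(paste(bm, collapse = ""))
    for (r in seq_len(nR - 1L)) {
      repeat {
        ch <- .apply_snps(bm, sample.int(Lm, r))
        s <- paste(ch, collapse = "")
        if (!s %in% unlist(types)) break
      }
      types[[r + 1L]] <- s
    }
    stats::setNames(unlist(types), paste0("CT", seq_len(nR)))
  })
  names(chloro) <- cp_markers

  # --- populations with geographic structure
  n_pop <- nR * spec$populations_per_region
  region_of_pop <- rep(seq_len(nR), each = spec$populations_per_region)
  lon_centre <- seq(-5, 30, length.out = nR)
  pops <- data.frame(
    population = sprintf("R%dP%d", region_of_pop,
                         rep(seq_len(spec$populations_per_region), nR)),
    country = paste0("region", region_of_pop),
    latitude = round(38 + stats::runif(n_pop, -1.5, 1.5), 4L),
    longitude = round(lon_centre[region_of_pop] + stats::runif(n_pop, -1.5, 1.5), 4L),
    species = "cre",
    stringsAsFactors = FALSE
  )

  # --- individuals
  inds <- list()
  for (p in seq_len(n_pop)) {
    for (j in seq_len(spec$individuals_per_population)) {
      r <- region_of_pop[p]
      id <- sprintf("%s_i%d", pops$population[p], j)
      het <- stats::runif(1L) < spec$het_fraction
      skewed <- het && stats::runif(1L) < spec$skewed_fraction
      ribo <- if (het) c("A", paste0("R", r))
              else if (stats::runif(1L) < 0.5) "A" else paste0("R", r)
      inds[[length(inds) + 1L]] <- data.frame(
        id = id, population = pops$population[p], species = "cre",
        region = r, heterozygous = het,
        mixing = if (!het) NA_character_ else if (skewed) "skewed" else "balanced",
        ribotypes = paste(ribo, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  individuals <- do.call(rbind, inds)

  # substitute regional variants into single homozygous regional carriers
  if (spec$variants_per_main > 0L) {
    for (r in seq_len(nR)) {
      hom <- which(!individuals$heterozygous &
                     individuals$ribotypes == paste0("R", r))
      nv <- min(spec$variants_per_main, max(0L, length(hom) - 1L))
      if (nv > 0L) {
        pick <- hom[seq_len(nv)]
        individuals$ribotypes[pick] <- paste0("R", r, "v", seq_len(nv))
      }
    }
  }
  for (m in cp_markers)
    individuals[[paste0("chlorotype_", m)]] <-
      paste0("CT", individuals$region)

  # --- assemble alignments and traces
  traces <- list()
  its_ids <- character(0); its_seqs <- character(0); its_pop <- character(0)
  for (i in seq_len(nrow(individuals))) {
    ind <- individuals[i, ]
    rt <- strsplit(ind$ribotypes, ",", fixed = TRUE)[[1L]]
    if (ind$heterozygous) {
      tr <- superimpose(all_ribo[[rt[1L]]], all_ribo[[rt[2L]]],
                        mixing = ind$mixing,
                        seed = if (ind$mixing == "skewed")
                          spec$seed + 7919L * i else NULL,
                        minor_rate = spec$minor_rate, source_id = ind$id)
      traces[[ind$id]] <- tr
    } else {
      its_ids <- c(its_ids, ind$id)
      its_seqs <- c(its_seqs, regap(all_ribo[[rt]]))
      its_pop <- c(its_pop, ind$population)
    }
  }
  alignments <- list()
  alignments[["ITS"]] <- alignment(stats::setNames(its_seqs, its_ids),
                                   species = "cre", population = its_pop,
                                   marker = "ITS")
  for (m in cp_markers) {
    seqs <- chloro[[m]][paste0("CT", individuals$region)]
    alignments[[m]] <- alignment(stats::setNames(seqs, individuals$id),
                                 species = "cre",
                                 population = individuals$population,
                                 marker = m)
  }

  list(spec = spec, alignments = alignments, traces = traces,
       populations = pops, individuals = individuals,
       ribotype_seqs = all_ribo, chlorotype_seqs = chloro,
       insert_pos = insert_pos)
}

#' Write a synthetic dataset to disk as a runnable pipeline input
#'
#' Emits aligned FASTA per marker, an ungapped FASTA of heterozygote direct
#' reads, the population metadata CSV and a pipeline YAML config.
#'
#' @param ds a [generate_dataset()] result.
#' @param dir output directory.
#' @return the config file path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  markers <- list()
  for (m in names(ds$alignments)) {
    f <- file.path(dir, paste0(gsub("[^A-Za-z0-9]", "", m), ".fasta"))
    write_aligned_fasta(ds$alignments[[m]], f)
    markers[[m]] <- list(name = m, alignment = f)
  }
  if (length(ds$traces) > 0L) {
    reads <- vapply(ds$traces, function(tr) tr$read, "")
    pop <- ds$individuals$population[match(names(ds$traces), ds$individuals$id)]
    mix <- vapply(ds$traces, function(tr) tr$mixing, "")
    headers <- paste(names(ds$traces), "cre", pop, mix, sep = "|")
    f <- file.path(dir, "its_reads.fasta")
    Biostrings::writeXStringSet(
      Biostrings::BStringSet(stats::setNames(reads, headers)), f, width = 80L)
    markers[["ITS"]]$reads <- f
  }
  meta <- file.path(dir, "populations.csv")
  utils::write.csv(ds$populations, meta, row.names = FALSE, quote = FALSE)
  cfg <- list(markers = unname(markers), metadata = meta,
              seed = ds$spec$seed, params = list())
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
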