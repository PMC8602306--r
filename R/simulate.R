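# Synthetic-data generators. Every generator is a pure function of its
# arguments and a seed; per-sample child seeds are drawn once from the master
# seed (sample.int after set.seed(seed)) so samples are independent yet the
# whole run is reproducible.

#' Screen simulation configuration
#'
#' Defaults mirror the regime of a genome-wide FACS-sorted positive-selection
#' screen scaled to desk size: ~10 sgRNAs per gene, a reporter-positive sort
#' capturing ~0.5% of stained cells, staining coverage >800x the library
#' size, and sequencing depth giving ~200x read coverage of the library.
#'
#' @param n_genes number of genes in the simulated library.
#' @param sgrnas_per_gene sgRNAs designed per gene.
#' @param n_true_regulators number of planted regulator genes.
#' @param enrichment_factor relative sampling weight of a true-regulator
#'   sgRNA cell in the reporter-positive sort (1 = no signal).
#' @param sorted_fraction fraction of stained cells captured by the sort,
#'   in (0, 1).
#' @param baseline_dispersion gamma variance of the latent per-sgRNA
#'   abundance (negative-binomial overdispersion of baseline counts).
#' @param reads_per_sample sequencing reads per sample.
#' @param n_experiments number of immunostaining experiments.
#' @param replicates_per_experiment replicates per experiment and condition.
#' @param cells_per_replicate stained cells per replicate; default
#'   830 x library size, matching a >800-fold staining coverage.
#' @param seed master integer seed.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 1000, sgrnas_per_gene = 10,
                       n_true_regulators = 20, enrichment_factor = 10,
                       sorted_fraction = 0.005, baseline_dispersion = 0.3,
                       reads_per_sample = 2e6, n_experiments = 2,
                       replicates_per_experiment = 2,
                       cells_per_replicate = NULL, seed = 1) {
  cfg <- list(n_genes = n_genes, sgrnas_per_gene = sgrnas_per_gene,
              n_true_regulators = n_true_regulators,
              enrichment_factor = enrichment_factor,
              sorted_fraction = sorted_fraction,
              baseline_dispersion = baseline_dispersion,
              reads_per_sample = reads_per_sample,
              n_experiments = n_experiments,
              replicates_per_experiment = replicates_per_experiment,
              cells_per_replicate = cells_per_replicate, seed = seed)
  for (f in c("n_genes", "sgrnas_per_gene", "reads_per_sample",
              "n_experiments", "replicates_per_experiment"))
    if (length(cfg[[f]]) != 1 || cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]]))
      stop("sim_config: ", f, " must be a positive integer", call. = FALSE)
  if (cfg$n_true_regulators < 0 || cfg$n_true_regulators != round(cfg$n_true_regulators))
    stop("sim_config: n_true_regulators must be a non-negative integer",
         call. = FALSE)
  if (cfg$n_true_regulators > cfg$n_genes)
    stop("sim_config: n_true_regulators exceeds n_genes", call. = FALSE)
  if (cfg$enrichment_factor <= 0)
    stop("sim_config: enrichment_factor must be > 0", call. = FALSE)
  if (cfg$sorted_fraction <= 0 || cfg$sorted_fraction >= 1)
    stop("sim_config: sorted_fraction must lie in (0, 1)", call. = FALSE)
  if (cfg$baseline_dispersion <= 0)
    stop("sim_config: baseline_dispersion must be > 0", call. = FALSE)
  if (!is.null(cfg$cells_per_replicate) && cfg$cells_per_replicate <= 0)
    stop("sim_config: cells_per_replicate must be > 0", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an sgRNA library
#'
#' Generates `n_genes * sgrnas_per_gene` records with pairwise-distinct
#' random 20-nt spacers, ~10 sgRNAs per gene in the genome-wide regime.
#'
#' @param n_genes number of genes (>= 1).
#' @param sgrnas_per_gene sgRNAs per gene (>= 1).
#' @param seed integer seed; the output is deterministic given the seed.
#' @return An [sgrna_library()].
#' @examples
#' lib <- simulate_library(n_genes = 5, sgrnas_per_gene = 3, seed = 1)
#' @export
simulate_library <- function(n_genes, sgrnas_per_gene, seed = 1) {
  if (n_genes < 1 || n_genes != round(n_genes))
    stop("n_genes must be a positive integer", call. = FALSE)
  if (sgrnas_per_gene < 1 || sgrnas_per_gene != round(sgrnas_per_gene))
    stop("sgrnas_per_gene must be a positive integer", call. = FALSE)
  set.seed(seed)
  n <- n_genes * sgrnas_per_gene
  genes <- sprintf("G%05d", seq_len(n_genes))
  gene_col <- rep(genes, each = sgrnas_per_gene)
  sg_id <- paste0(gene_col, "_sg", rep(seq_len(sgrnas_per_gene), n_genes))
  spacers <- random_spacers(n)
  sgrna_library(sg_id, spacers, gene_col)
}

random_spacers <- function(n) {
  draw <- function(k) {
    cols <- replicate(20, sample(c("A", "C", "G", "T"), k, replace = TRUE),
                      simplify = FALSE)
    do.call(paste0, cols)
  }
  spacers <- draw(n)
  while (anyDuplicated(spacers)) {
    idx <- which(duplicated(spacers))
    spacers[idx] <- draw(length(idx))
  }
  spacers
}

#' Simulate FACS-sorted screen counts with planted regulators
#'
#' Baseline per-sgRNA abundances are gamma-distributed (mean 1, variance
#' `baseline_dispersion`), so sequencing the unsorted pool is a
#' gamma-multinomial draw whose marginals are negative-binomial-like.
#' Reporter-positive samples pass through a sorting bottleneck of
#' `sorted_fraction * cells_per_replicate` cells drawn multinomially with
#' per-sgRNA weight `abundance * enrichment_factor` for sgRNAs of planted
#' regulator genes (weight `abundance` otherwise), then are sequenced to
#' `reads_per_sample` reads. Reporter-negative samples pass through the same
#' bottleneck without enrichment weighting.
#'
#' @param library an [sgrna_library()].
#' @param config a [sim_config()].
#' @return A list with elements `counts` (a [count_matrix()], one column per
#'   (condition, experiment, replicate)) and `truth` (class `"sim_truth"`:
#'   planted `regulator_genes`, `enrichment_factor`, `seed`; the latent
#'   per-sgRNA abundances are attached as attribute `"abundance"` for
#'   diagnostics).
#' @export
simulate_screen_counts <- function(library, config = sim_config()) {
  validate_sgrna_library(library)
  stopifnot(inherits(config, "sim_config"))
  L <- nrow(library)
  genes <- unique(library$gene)
  if (config$n_true_regulators > length(genes))
    stop("n_true_regulators exceeds the number of library genes",
         call. = FALSE)
  cells <- config$cells_per_replicate
  if (is.null(cells)) cells <- 830 * L
  n_sorted_cells <- max(1L, round(config$sorted_fraction * cells))

  set.seed(config$seed)
  regulators <- sort(sample(genes, config$n_true_regulators))
  abundance <- stats::rgamma(L, shape = 1 / config$baseline_dispersion,
                             rate = 1 / config$baseline_dispersion)
  is_reg <- library$gene %in% regulators
  w_pos <- abundance * ifelse(is_reg, config$enrichment_factor, 1)

  grid <- expand.grid(replicate = seq_len(config$replicates_per_experiment),
                      condition = c("unsorted", "pos", "neg"),
                      experiment = seq_len(config$n_experiments),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("condition", "experiment", "replicate")]
  grid$sample_id <- sprintf("%s_e%d_r%d", grid$condition, grid$experiment,
                            grid$replicate)
  child_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))

  counts <- matrix(0, nrow = L, ncol = nrow(grid),
                   dimnames = list(library$sgrna_id, grid$sample_id))
  for (i in seq_len(nrow(grid))) {
    set.seed(child_seeds[i])
    counts[, i] <- switch(
      grid$condition[i],
      unsorted = stats::rmultinom(1, config$reads_per_sample, abundance),
      pos = {
        sorted <- stats::rmultinom(1, n_sorted_cells, w_pos)[, 1]
        stats::rmultinom(1, config$reads_per_sample, sorted)
      },
      neg = {
        sorted <- stats::rmultinom(1, n_sorted_cells, abundance)[, 1]
        stats::rmultinom(1, config$reads_per_sample, sorted)
      })
  }
  sheet <- sample_sheet(grid$sample_id, grid$condition,
                        paste0("exp", grid$experiment), grid$replicate)
  truth <- structure(list(regulator_genes = regulators,
                          enrichment_factor = config$enrichment_factor,
                          seed = config$seed),
                     class = "sim_truth", abundance = abundance)
  list(counts = count_matrix(counts, sheet), truth = truth)
}

#' Write the planted-truth file as JSON
#' @param truth a `"sim_truth"` object from [simulate_screen_counts()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth)[c("regulator_genes",
                                        "enrichment_factor", "seed")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# fixed "vector" flanks surrounding the spacer in the simulated amplicon
AMPLICON_FLANK5 <- "TTGTGGAAAGGACGAAACACCG"
AMPLICON_FLANK3 <- "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGC"

#' Simulate amplicon sequencing reads for given sgRNA counts
#'
#' Each read embeds its sgRNA's 20-nt spacer between fixed vector flanks and
#' is truncated to `read_length`; quality strings are constant. Exactly
#' `sum(counts)` reads are emitted per sample, in seeded shuffled order.
#'
#' @param library an [sgrna_library()].
#' @param counts either a named numeric vector (one sample; names are sgRNA
#'   ids) or a [count_matrix()] (one FASTQ per sample).
#' @param read_length read length; must be at least `nchar(flank5) + 20` so
#'   the full spacer is contained in every read.
#' @param dir output directory for FASTQ files (required for a
#'   [count_matrix()]); when `counts` is a vector and `dir` is `NULL` the
#'   read sequences are returned as a character vector instead.
#' @param seed integer seed for read shuffling.
#' @param flank5,flank3 fixed flanking vector sequences.
#' @return A character vector of read sequences (vector input, `dir = NULL`)
#'   or the paths of the written FASTQ files.
#' @export
simulate_amplicon_reads <- function(library, counts, read_length = 75,
                                    dir = NULL, seed = 1,
                                    flank5 = AMPLICON_FLANK5,
                                    flank3 = AMPLICON_FLANK3) {
  validate_sgrna_library(library)
  min_len <- nchar(flank5) + 20
  if (read_length < min_len)
    stop("read_length must be >= ", min_len,
         " (5' flank plus the 20-nt spacer)", call. = FALSE)
  if (inherits(counts, "count_matrix")) {
    if (is.null(dir))
      stop("dir is required when counts is a count_matrix", call. = FALSE)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    set.seed(seed)
    child <- sample.int(.Machine$integer.max - 1L, ncol(counts$counts))
    paths <- character(ncol(counts$counts))
    for (j in seq_len(ncol(counts$counts))) {
      cvec <- counts$counts[, j]
      names(cvec) <- rownames(counts$counts)
      paths[j] <- file.path(dir, paste0(colnames(counts$counts)[j], ".fastq"))
      reads <- amplicon_read_seqs(library, cvec, read_length, child[j],
                                  flank5, flank3)
      write_fastq(reads, paths[j],
                  prefix = paste0(colnames(counts$counts)[j], "_read"))
    }
    return(invisible(paths))
  }
  cvec <- counts
  unknown <- setdiff(names(cvec)[cvec > 0], library$sgrna_id)
  if (length(unknown) > 0)
    stop("unknown sgRNA id(s) in counts: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  reads <- amplicon_read_seqs(library, cvec, read_length, seed, flank5,
                              flank3)
  if (is.null(dir)) return(reads)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "sample.fastq")
  write_fastq(reads, path)
  invisible(path)
}

amplicon_read_seqs <- function(library, cvec, read_length, seed, flank5,
                               flank3) {
  cvec <- cvec[names(cvec) %in% library$sgrna_id & cvec > 0]
  if (length(cvec) == 0) return(character(0))
  spacer <- library$spacer[match(names(cvec), library$sgrna_id)]
  tail_needed <- read_length - nchar(flank5) - 20
  tail3 <- substr(strrep(flank3, ceiling(tail_needed / nchar(flank3)) + 1),
                  1, tail_needed)
  templates <- paste0(flank5, spacer, tail3)
  reads <- rep(templates, times = cvec)
  set.seed(seed)
  reads[sample.int(length(reads))]
}

write_fastq <- function(reads, path, prefix = "read") {
  if (length(reads) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  qual <- strrep("I", nchar(reads))
  rec <- as.vector(rbind(paste0("@", prefix, seq_along(reads)), reads,
                         "+", qual))
  writeLines(rec, path)
  invisible(path)
}

#' Simulate a two-sample CpG methylome with planted hypomethylation
#'
#' The control sample draws beta values from Beta distributions centered high
#' (mean ~0.85) inside maternal DMRs, low (mean ~0.15) inside paternal DMRs,
#' and from a bimodal high/low mixture in the background. CpG positions are
#' placed every `cpg_spacing` bp inside each DMR. The treated sample re-uses
#' the control draws, with CpGs inside `hypo_targets` shifted down by
#' `hypo_delta` and clamped to [0, 1] — a matched-pair design that isolates
#' the downstream aggregation from generator noise.
#'
#' @param dmrs a [dmr_set()] with non-overlapping intervals per chromosome.
#' @param n_background_cpgs number of CpGs outside every DMR.
#' @param hypo_targets character vector of DMR names to demethylate.
#' @param hypo_delta planted methylation loss in [0, 1].
#' @param seed integer seed.
#' @param cpg_spacing distance in bp between successive CpGs within a DMR.
#' @return A list with CpG tables `control` and `treated` plus `truth`
#'   (`hypo_targets`, `hypo_delta`).
#' @export
simulate_methylome <- function(dmrs, n_background_cpgs = 500,
                               hypo_targets = character(0), hypo_delta = 0,
                               seed = 1, cpg_spacing = 10) {
  validate_dmr_set(dmrs)
  if (hypo_delta < 0 || hypo_delta > 1)
    stop("hypo_delta must lie in [0, 1]", call. = FALSE)
  bad_target <- setdiff(hypo_targets, dmrs$name)
  if (length(bad_target) > 0)
    stop("hypo_targets not in DMR set: ",
         paste(bad_target, collapse = ", "), call. = FALSE)
  for (ch in unique(dmrs$chrom)) {
    d <- dmrs[dmrs$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stop("overlapping DMR intervals on ", ch, call. = FALSE)
  }
  set.seed(seed)
  pos_list <- lapply(seq_len(nrow(dmrs)), function(i)
    seq(dmrs$start[i], dmrs$end[i] - 1, by = cpg_spacing))
  dmr_chrom <- rep(dmrs$chrom, lengths(pos_list))
  dmr_name <- rep(dmrs$name, lengths(pos_list))
  dmr_origin <- rep(dmrs$origin, lengths(pos_list))
  dmr_pos <- unlist(pos_list)

  # background CpGs: random positions on the DMR chromosomes, outside DMRs
  bg_chrom <- sample(unique(dmrs$chrom), n_background_cpgs, replace = TRUE)
  span <- max(dmrs$end) + 10000L
  bg_pos <- sample.int(span * 5L, n_background_cpgs, replace = FALSE) + span
  n_dmr <- length(dmr_pos)
  beta_dmr <- ifelse(dmr_origin == "maternal",
                     stats::rbeta(n_dmr, 17, 3), stats::rbeta(n_dmr, 3, 17))
  hi <- stats::runif(n_background_cpgs) < 0.5
  beta_bg <- ifelse(hi, stats::rbeta(n_background_cpgs, 17, 3),
                    stats::rbeta(n_background_cpgs, 2, 18))
  coverage <- stats::rpois(n_dmr + n_background_cpgs, 30) + 1L

  control <- data.frame(chrom = c(dmr_chrom, bg_chrom),
                        start = c(dmr_pos, bg_pos),
                        end = c(dmr_pos, bg_pos) + 1L,
                        beta = c(beta_dmr, beta_bg),
                        coverage = coverage, stringsAsFactors = FALSE)
  treated <- control
  shift <- c(dmr_name %in% hypo_targets, rep(FALSE, n_background_cpgs))
  treated$beta[shift] <- pmin(1, pmax(0, treated$beta[shift] - hypo_delta))
  list(control = validate_cpg_table(control),
       treated = validate_cpg_table(treated),
       truth = list(hypo_targets = hypo_targets, hypo_delta = hypo_delta))
}

#' Simulate a gene expression table (TPM)
#'
#' Each gene is independently "expressed" with probability
#' `expressed_fraction`; expressed genes draw log-normal TPM truncated above
#' 1, the rest draw uniform TPM in [0, 1).
#'
#' @param genes character vector of gene ids.
#' @param expressed_fraction probability in [0, 1] that a gene is expressed.
#' @param seed integer seed.
#' @param meanlog,sdlog log-normal parameters for expressed genes.
#' @return A `data.frame` with columns `gene` and `tpm`.
#' @export
simulate_expression <- function(genes, expressed_fraction = 0.9, seed = 1,
                                meanlog = 2, sdlog = 1.2) {
  if (expressed_fraction < 0 || expressed_fraction > 1)
    stop("expressed_fraction must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  n <- length(genes)
  expressed <- stats::runif(n) < expressed_fraction
  tpm <- stats::runif(n, 0, 1 - 1e-9)
  k <- sum(expressed)
  if (k > 0) {
    draw <- stats::rlnorm(k, meanlog, sdlog)
    while (any(draw <= 1))
      draw[draw <= 1] <- stats::rlnorm(sum(draw <= 1), meanlog, sdlog)
    tpm[expressed] <- draw
  }
  data.frame(gene = genes, tpm = tpm, stringsAsFactors = FALSE)
}
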