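# CpG-to-DMR aggregation and the imprinted-methylation analysis: per-DMR
# mean beta values, informative-DMR filters (maternal >= 0.6, paternal
# <= 0.4 in the control), delta methylation between treatments, a global
# paired one-tailed t-test, and the demethylation-response classification
# of paternally expressed genes.

cpg_granges <- function(cpg) {
  GenomicRanges::GRanges(cpg$chrom,
                         IRanges::IRanges(start = cpg$start + 1L, width = 1L))
}

dmr_granges <- function(dmrs) {
  GenomicRanges::GRanges(dmrs$chrom,
                         IRanges::IRanges(start = dmrs$start + 1L,
                                          end = dmrs$end))
}

#' Assign CpGs to DMRs
#'
#' A CpG at 0-based position `s` belongs to the DMR `[a, b)` iff
#' `a <= s < b` on the same chromosome; CpGs outside every DMR map to
#' `"background"`. DMRs must not overlap, so membership is unique.
#'
#' @param cpg a CpG table (see [read_cpg_table()]).
#' @param dmrs a [dmr_set()].
#' @return Character vector of DMR names (or `"background"`), one per CpG
#'   row.
#' @export
assign_cpgs <- function(cpg, dmrs) {
  cpg <- validate_cpg_table(cpg)
  validate_dmr_set(dmrs)
  # disjoint chromosome sets are legitimate (all CpGs -> background), so
  # the no-common-seqlevels warning is noise here
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(cpg_granges(cpg), dmr_granges(dmrs)))
  member <- rep("background", nrow(cpg))
  member[S4Vectors::queryHits(hits)] <- dmrs$name[S4Vectors::subjectHits(hits)]
  member
}

#' Per-DMR mean methylation
#'
#' Unweighted mean beta over the member CpGs of each DMR (a
#' coverage-weighted variant is available via `coverage_weighted = TRUE`).
#' DMRs with fewer than `min_cpgs` member CpGs are flagged missing
#' (`mean_beta = NA`).
#'
#' @param cpg a CpG table for one sample, or a named list of CpG tables
#'   (one per sample).
#' @param dmrs a [dmr_set()].
#' @param min_cpgs minimum member CpGs for a defined mean (default 3).
#' @param coverage_weighted weight CpG betas by coverage.
#' @return A `data.frame` with columns `dmr`, `sample`, `mean_beta`,
#'   `n_cpgs`, `missing`.
#' @export
dmr_mean_beta <- function(cpg, dmrs, min_cpgs = 3,
                          coverage_weighted = FALSE) {
  if (min_cpgs < 1) stop("min_cpgs must be >= 1", call. = FALSE)
  validate_dmr_set(dmrs)
  if (is.data.frame(cpg)) cpg <- list(sample = cpg)
  if (is.null(names(cpg)))
    names(cpg) <- paste0("sample", seq_along(cpg))
  out <- lapply(names(cpg), function(sm) {
    tab <- validate_cpg_table(cpg[[sm]])
    member <- assign_cpgs(tab, dmrs)
    res <- lapply(dmrs$name, function(d) {
      sel <- member == d
      n <- sum(sel)
      mb <- if (n >= min_cpgs) {
        if (coverage_weighted)
          stats::weighted.mean(tab$beta[sel], tab$coverage[sel])
        else mean(tab$beta[sel])
      } else NA_real_
      data.frame(dmr = d, sample = sm, mean_beta = mb, n_cpgs = n,
                 missing = n < min_cpgs, stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Retain informative imprinted DMRs
#'
#' Drops maternal DMRs whose control mean methylation is below 0.6 and
#' paternal DMRs whose control mean is above 0.4; exact boundary values are
#' retained (the drop rule is strict). DMRs without a control mean are
#' excluded with a message.
#'
#' @param dmr_means_control a [dmr_mean_beta()] table for the control
#'   sample.
#' @param dmrs the [dmr_set()] to filter.
#' @param maternal_min retain maternal DMRs with control mean `>=` this
#'   (default 0.6).
#' @param paternal_max retain paternal DMRs with control mean `<=` this
#'   (default 0.4).
#' @return The retained subset of `dmrs` (still a [dmr_set()]).
#' @export
filter_informative_dmrs <- function(dmr_means_control, dmrs,
                                    maternal_min = 0.6, paternal_max = 0.4) {
  validate_dmr_set(dmrs)
  i <- match(dmrs$name, dmr_means_control$dmr)
  mb <- dmr_means_control$mean_beta[i]
  undefined <- is.na(mb)
  if (any(undefined))
    message("filter_informative_dmrs: ", sum(undefined),
            " DMR(s) without a control mean were excluded: ",
            paste(utils::head(dmrs$name[undefined], 5), collapse = ", "))
  keep <- !undefined &
    ((dmrs$origin == "maternal" & mb >= maternal_min) |
       (dmrs$origin == "paternal" & mb <= paternal_max))
  out <- dmrs[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dmr_set", "data.frame")
  out
}

#' Delta methylation between treated and control samples
#'
#' `delta = treated mean beta - control mean beta` per DMR, in `[-1, 1]`;
#' missing on either side propagates to a missing delta.
#'
#' @param dmr_means_treated,dmr_means_control [dmr_mean_beta()] tables over
#'   the same DMR set.
#' @return A `data.frame` with columns `dmr`, `control_mean`,
#'   `treated_mean`, `delta`.
#' @export
delta_methylation <- function(dmr_means_treated, dmr_means_control) {
  if (!setequal(dmr_means_treated$dmr, dmr_means_control$dmr))
    stop("treated and control tables must cover the same DMR set",
         call. = FALSE)
  i <- match(dmr_means_control$dmr, dmr_means_treated$dmr)
  out <- data.frame(dmr = dmr_means_control$dmr,
                    control_mean = dmr_means_control$mean_beta,
                    treated_mean = dmr_means_treated$mean_beta[i],
                    stringsAsFactors = FALSE)
  out$delta <- out$treated_mean - out$control_mean
  rownames(out) <- NULL
  out
}

#' Paired one-tailed t-test
#'
#' One-tailed paired t-test for a stated direction; used both for the
#' global-hypomethylation contrast (treated beta < control beta across
#' paired CpGs) and for expression fold-change contrasts across replicates.
#'
#' @param values_a,values_b paired numeric vectors of equal length >= 2.
#' @param direction `"less"` tests mean(a - b) < 0, `"greater"` the
#'   opposite.
#' @return The one-tailed p-value, with the t statistic and df attached as
#'   attributes.
#' @export
paired_onetailed_test <- function(values_a, values_b,
                                  direction = c("less", "greater")) {
  direction <- match.arg(direction)
  if (length(values_a) != length(values_b))
    stop("paired vectors must have equal length", call. = FALSE)
  if (length(values_a) < 2)
    stop("need at least 2 pairs", call. = FALSE)
  d <- values_a - values_b
  if (all(d == 0))
    stop("degenerate input: all pairwise differences are zero",
         call. = FALSE)
  stderr_d <- stats::sd(d) / sqrt(length(d))
  if (stderr_d < 10 * .Machine$double.eps * abs(mean(d))) {
    # constant non-zero shift: the t statistic diverges and the one-tailed
    # p collapses to 0 (stated direction) or 1 (opposite direction)
    t_stat <- sign(mean(d)) * Inf
    p <- stats::pt(t_stat, df = length(d) - 1,
                   lower.tail = direction == "less")
    attr(p, "statistic") <- t_stat
    attr(p, "df") <- length(d) - 1
    return(p)
  }
  ht <- stats::t.test(values_a, values_b, paired = TRUE,
                      alternative = direction)
  p <- ht$p.value
  attr(p, "statistic") <- unname(ht$statistic)
  attr(p, "df") <- unname(ht$parameter)
  p
}

#' Global methylation contrast between two CpG tables
#'
#' Pairs beta values per CpG (matched on chromosome and position; CpGs
#' absent from either sample are dropped) and runs
#' [paired_onetailed_test()].
#'
#' @param cpg_treated,cpg_control CpG tables.
#' @param direction tested direction for treated vs control (default
#'   `"less"`: global hypomethylation).
#' @return The one-tailed p-value with the number of paired CpGs attached
#'   as attribute `"n_pairs"`.
#' @export
global_methylation_test <- function(cpg_treated, cpg_control,
                                    direction = "less") {
  cpg_treated <- validate_cpg_table(cpg_treated)
  cpg_control <- validate_cpg_table(cpg_control)
  key_t <- paste(cpg_treated$chrom, cpg_treated$start)
  key_c <- paste(cpg_control$chrom, cpg_control$start)
  common <- intersect(key_t, key_c)
  if (length(common) < 2)
    stop("fewer than 2 CpGs shared between samples", call. = FALSE)
  a <- cpg_treated$beta[match(common, key_t)]
  b <- cpg_control$beta[match(common, key_c)]
  p <- paired_onetailed_test(a, b, direction)
  attr(p, "n_pairs") <- length(common)
  p
}

#' Classify the demethylation response of paternally expressed genes
#'
#' A locus is "demethylated" iff its DMR delta beta is at or below
#' `demeth_delta_cut`, and "activated" iff its expression fold change
#' (demethylated vs control) is at or above `activation_fc_cut`. Categories:
#' `demethylated_activated`, `demethylated_silent`, and
#' `methylation_retained` (not demethylated, regardless of expression).
#' The cut-offs are configurable defaults, not literature constants.
#'
#' @param delta_beta numeric vector in `[-1, 1]`.
#' @param expr_fc positive expression fold changes (treated / control TPM).
#' @param demeth_delta_cut delta threshold at or below which a DMR counts
#'   as demethylated (default -0.2).
#' @param activation_fc_cut fold-change threshold at or above which a gene
#'   counts as activated (default 2).
#' @return Factor with levels `demethylated_activated`,
#'   `demethylated_silent`, `methylation_retained`; thresholds attached as
#'   attribute `"thresholds"`.
#' @export
classify_peg_response <- function(delta_beta, expr_fc,
                                  demeth_delta_cut = -0.2,
                                  activation_fc_cut = 2) {
  if (any(expr_fc <= 0, na.rm = TRUE))
    stop("expr_fc must be > 0", call. = FALSE)
  if (length(delta_beta) != length(expr_fc))
    stop("delta_beta and expr_fc must have equal length", call. = FALSE)
  demeth <- delta_beta <= demeth_delta_cut
  active <- expr_fc >= activation_fc_cut
  cat_chr <- ifelse(!demeth, "methylation_retained",
                    ifelse(active, "demethylated_activated",
                           "demethylated_silent"))
  out <- factor(cat_chr, levels = c("demethylated_activated",
                                    "demethylated_silent",
                                    "methylation_retained"))
  attr(out, "thresholds") <- c(demeth_delta_cut = demeth_delta_cut,
                               activation_fc_cut = activation_fc_cut)
  out
}

#' Per-gene demethylation-response table
#'
#' Joins each retained DMR's delta methylation to its associated genes and
#' classifies every (DMR, gene) pair with [classify_peg_response()].
#'
#' @param delta a [delta_methylation()] table.
#' @param dmrs the [dmr_set()] providing `genes` per DMR.
#' @param expr_fc named numeric vector: expression fold change
#'   (demethylated vs control) per gene.
#' @param demeth_delta_cut,activation_fc_cut see [classify_peg_response()].
#' @return A `data.frame` with columns `gene`, `dmr`, `delta_beta`,
#'   `expr_fc`, `category`; rows with a missing delta or absent expression
#'   fold change are dropped with a message.
#' @export
peg_response_table <- function(delta, dmrs, expr_fc,
                               demeth_delta_cut = -0.2,
                               activation_fc_cut = 2) {
  validate_dmr_set(dmrs)
  gene_lists <- strsplit(dmrs$genes, ",", fixed = TRUE)
  gene_lists <- lapply(gene_lists, function(g) g[nzchar(g)])
  long <- data.frame(dmr = rep(dmrs$name, lengths(gene_lists)),
                     gene = unlist(gene_lists), stringsAsFactors = FALSE)
  long$delta_beta <- delta$delta[match(long$dmr, delta$dmr)]
  long$expr_fc <- expr_fc[long$gene]
  drop <- is.na(long$delta_beta) | is.na(long$expr_fc)
  if (any(drop))
    message("peg_response_table: dropped ", sum(drop),
            " gene(s) with missing delta or expression fold change")
  long <- long[!drop, , drop = FALSE]
  long$category <- classify_peg_response(long$delta_beta, long$expr_fc,
                                         demeth_delta_cut,
                                         activation_fc_cut)
  rownames(long) <- NULL
  out <- long[, c("gene", "dmr", "delta_beta", "expr_fc", "category")]
  attr(out, "thresholds") <- c(demeth_delta_cut = demeth_delta_cut,
                               activation_fc_cut = activation_fc_cut)
  out
}
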