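# Gene-level enrichment statistics for the FACS-sorted screen:
# reads-per-million normalization with a pseudocount, per-experiment
# per-sgRNA log2 fold changes (sorted vs unsorted), Tukey-hinge outlier
# trimming, median gene scores centered on the library median, a two-sample
# two-sided Kolmogorov-Smirnov enrichment p-value per gene, and the
# four-filter candidate-calling rule.

#' Normalize sgRNA counts to reads per million with a pseudocount
#'
#' `norm = (count + c) / (colsum + c * L) * 1e6`, where `colsum` is the raw
#' column sum and `L` the number of sgRNAs. Every normalized entry is
#' strictly positive for `c > 0`, so downstream log fold changes are finite.
#'
#' @param x a [count_matrix()].
#' @param pseudocount pseudocount `c` (default 0.5).
#' @return A list of class `"norm_counts"` with elements `norm` (numeric
#'   matrix), `samples` (the sample sheet) and `pseudocount`.
#' @export
normalize_counts <- function(x, pseudocount = 0.5) {
  stopifnot(inherits(x, "count_matrix"))
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  colsum <- colSums(x$counts)
  zero <- which(colsum == 0)
  if (length(zero) > 0)
    stop("all-zero count column(s): ",
         paste(colnames(x$counts)[zero], collapse = ", "), call. = FALSE)
  L <- nrow(x$counts)
  norm <- sweep(x$counts + pseudocount, 2, colsum + pseudocount * L, "/") * 1e6
  structure(list(norm = norm, samples = x$samples, pseudocount = pseudocount),
            class = "norm_counts")
}

#' Per-sgRNA log2 fold change, sorted vs unsorted, within one experiment
#'
#' For every sgRNA, `log2(mean over sorted replicates / mean over unsorted
#' replicates)` of the normalized values, using only the samples of the
#' given experiment. Positive values mean enrichment in the sorted
#' population.
#'
#' @param normalized a [normalize_counts()] result.
#' @param sorted_condition `"pos"` (reporter-positive sort) or `"neg"`.
#' @param experiment experiment id (as in the sample sheet).
#' @return A `data.frame` with columns `sgrna_id`, `experiment`, `log2fc`.
#' @export
sgrna_log2fc <- function(normalized, sorted_condition = c("pos", "neg"),
                         experiment) {
  stopifnot(inherits(normalized, "norm_counts"))
  sorted_condition <- match.arg(sorted_condition)
  sheet <- normalized$samples
  in_exp <- sheet$experiment == experiment
  s_ids <- sheet$sample_id[in_exp & sheet$condition == sorted_condition]
  u_ids <- sheet$sample_id[in_exp & sheet$condition == "unsorted"]
  if (length(s_ids) == 0)
    stop("experiment '", experiment, "' has no '", sorted_condition,
         "' samples", call. = FALSE)
  if (length(u_ids) == 0)
    stop("experiment '", experiment, "' has no 'unsorted' samples",
         call. = FALSE)
  s_mean <- rowMeans(normalized$norm[, s_ids, drop = FALSE])
  u_mean <- rowMeans(normalized$norm[, u_ids, drop = FALSE])
  data.frame(sgrna_id = rownames(normalized$norm),
             experiment = experiment,
             log2fc = log2(s_mean / u_mean),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-sgRNA log2 fold changes for all experiments
#' @param normalized a [normalize_counts()] result.
#' @param sorted_condition `"pos"` or `"neg"`.
#' @return Row-bound [sgrna_log2fc()] tables over every experiment that has
#'   both the sorted condition and unsorted samples.
#' @export
sgrna_log2fc_all <- function(normalized, sorted_condition = c("pos", "neg")) {
  sorted_condition <- match.arg(sorted_condition)
  exps <- unique(normalized$samples$experiment[
    normalized$samples$condition == sorted_condition])
  do.call(rbind, lapply(exps, function(e)
    sgrna_log2fc(normalized, sorted_condition, e)))
}

#' Tukey-hinge outlier removal
#'
#' Computes the lower and upper hinges (median-of-halves convention, as in
#' the classic five-number summary) and discards values outside
#' `[H1 - 1.5*(H2-H1), H2 + 1.5*(H2-H1)]`. The retained values keep their
#' input order; a constant vector is returned unchanged. Never empties its
#' input: the hinges always bracket the median.
#'
#' @param values numeric vector with at least one finite value.
#' @return The retained values, in input order.
#' @export
remove_outliers <- function(values) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  s <- sort(values)
  n <- length(s)
  h <- (floor((n + 3) / 2)) / 2
  lower <- (s[floor(h)] + s[ceiling(h)]) / 2
  upper <- (s[n + 1 - floor(h)] + s[n + 1 - ceiling(h)]) / 2
  iqr <- upper - lower
  keep <- values >= lower - 1.5 * iqr & values <= upper + 1.5 * iqr
  values[keep]
}

#' Two-sample two-sided Kolmogorov-Smirnov enrichment test
#'
#' Compares a gene's pooled sgRNA log2 fold changes against the background
#' distribution. The D statistic is the maximum ECDF gap over the union of
#' observed points (ties allowed). The p-value is computed from the exact
#' permutation distribution when `n * m <= exact_limit`, and from the
#' asymptotic Kolmogorov distribution otherwise.
#'
#' @param gene_values numeric vector, the gene's fold-change values.
#' @param background_values numeric vector, the background fold changes.
#' @param exact_limit use the exact null distribution when the product of
#'   the two sample sizes is at most this (default 10000).
#' @return The two-sided p-value, with the D statistic attached as
#'   attribute `"statistic"`.
#' @export
gene_ks_test <- function(gene_values, background_values,
                         exact_limit = 10000) {
  if (length(gene_values) == 0 || length(background_values) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  n <- length(gene_values); m <- length(background_values)
  D <- ks_statistic(gene_values, background_values)
  p <- if (as.double(n) * m <= exact_limit) {
    stats::psmirnov(D, sizes = c(n, m),
                    z = sort(c(gene_values, background_values)),
                    two.sided = TRUE, exact = TRUE, lower.tail = FALSE)
  } else {
    # Stephens (1970) finite-sample correction of the asymptotic statistic;
    # the plain Kolmogorov limit is noticeably conservative at n ~ 20
    ne <- sqrt(n * m / (n + m))
    kolmogorov_sf(D * (ne + 0.12 + 0.11 / ne))
  }
  p <- min(1, max(0, p))
  attr(p, "statistic") <- D
  p
}

ks_statistic <- function(x, y) {
  # step ECDFs evaluated at the union of observed points; ties allowed
  pts <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(pts)
  Fy <- stats::ecdf(y)(pts)
  max(abs(Fx - Fy))
}

# survival function of the Kolmogorov distribution:
# Q(t) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 t^2)
kolmogorov_sf <- function(t) {
  if (t < 1e-3) return(1)
  k <- seq_len(101)
  terms <- (-1)^(k - 1) * exp(-2 * k^2 * t^2)
  min(1, max(0, 2 * sum(terms)))
}

#' Aggregate per-sgRNA fold changes to robust per-gene scores
#'
#' Pools each gene's fold-change values across experiments, removes Tukey
#' outliers ([remove_outliers()]), and takes the median as the gene's raw
#' score. Because most genes drift negative under positive selection, scores
#' are then centered: the global offset is the median over genes of the raw
#' medians, and `centered_log2fc = raw_median_log2fc - offset`, so the
#' median centered score is 0. Each gene also gets a two-sided two-sample
#' KS p-value of its pooled values against the background of all values
#' (the gene's own included by default), plus a Benjamini-Hochberg FDR
#' column for reference (not used by the default candidate filter).
#'
#' @param fold_changes row-bound [sgrna_log2fc()] tables (all experiments).
#' @param library an [sgrna_library()]; every fold-change record must map to
#'   a library sgRNA.
#' @param exclude_self exclude the gene's own values from the KS background.
#' @param exact_limit passed to [gene_ks_test()].
#' @return A `data.frame` of class `"gene_scores"` with columns `gene`,
#'   `n_sgrna_values` (values surviving outlier removal),
#'   `raw_median_log2fc`, `centered_log2fc`, `ks_p`, `bh_fdr`,
#'   `low_confidence` (fewer than 3 surviving values); the realized global
#'   offset is attached as attribute `"global_offset"`.
#' @export
gene_scores <- function(fold_changes, library, exclude_self = FALSE,
                        exact_limit = 10000) {
  validate_sgrna_library(library)
  gene <- library$gene[match(fold_changes$sgrna_id, library$sgrna_id)]
  if (anyNA(gene))
    stop("fold-change record(s) with sgRNA id not in library: ",
         paste(utils::head(unique(
           fold_changes$sgrna_id[is.na(gene)]), 5), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(fold_changes$log2fc)))
    stop("non-finite log2 fold changes; normalize with a positive pseudocount",
         call. = FALSE)
  vals_by_gene <- split(fold_changes$log2fc, gene)
  all_genes <- unique(library$gene)
  uncovered <- setdiff(all_genes, names(vals_by_gene))
  if (length(uncovered) > 0)
    message("gene_scores: ", length(uncovered),
            " gene(s) with no fold-change values were excluded")
  background <- fold_changes$log2fc
  res <- lapply(names(vals_by_gene), function(g) {
    vals <- vals_by_gene[[g]]
    kept <- remove_outliers(vals)
    bg <- if (exclude_self) background[gene != g] else background
    p <- gene_ks_test(vals, bg, exact_limit = exact_limit)
    c(n = length(kept), raw = stats::median(kept), p = as.numeric(p))
  })
  res <- do.call(rbind, res)
  offset <- stats::median(res[, "raw"])
  out <- data.frame(gene = names(vals_by_gene),
                    n_sgrna_values = as.integer(res[, "n"]),
                    raw_median_log2fc = res[, "raw"],
                    centered_log2fc = res[, "raw"] - offset,
                    ks_p = res[, "p"],
                    bh_fdr = stats::p.adjust(res[, "p"], method = "BH"),
                    low_confidence = res[, "n"] < 3,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "global_offset") <- offset
  attr(out, "excluded_genes") <- uncovered
  class(out) <- c("gene_scores", "data.frame")
  out
}

#' Candidate-calling configuration
#'
#' The default thresholds reproduce the four-filter rule of the screen:
#' centered log2 FC > 1.4, KS p < 0.05, TPM > 1 in the reference expression
#' sample, and discard of genes with centered log2 FC > 0.5 and p < 0.05 in
#' the reporter-negative sort.
#'
#' @param fc_threshold_centered positive-sort centered log2 FC cut (> keeps).
#' @param p_threshold positive-sort KS p cut (< keeps), in (0, 1).
#' @param tpm_threshold expression gate (TPM > keeps).
#' @param neg_fc_threshold negative-sort centered log2 FC cut for discard.
#' @param neg_p_threshold negative-sort KS p cut for discard, in (0, 1).
#' @param neg_on_centered apply the negative-sort cut on the centered scale
#'   (default) or on the raw scale.
#' @return A validated list of class `"candidate_config"`.
#' @export
candidate_config <- function(fc_threshold_centered = 1.4, p_threshold = 0.05,
                             tpm_threshold = 1, neg_fc_threshold = 0.5,
                             neg_p_threshold = 0.05, neg_on_centered = TRUE) {
  cfg <- list(fc_threshold_centered = fc_threshold_centered,
              p_threshold = p_threshold, tpm_threshold = tpm_threshold,
              neg_fc_threshold = neg_fc_threshold,
              neg_p_threshold = neg_p_threshold,
              neg_on_centered = isTRUE(neg_on_centered))
  for (f in c("fc_threshold_centered", "tpm_threshold", "neg_fc_threshold"))
    if (!is.finite(cfg[[f]]))
      stop("candidate_config: ", f, " must be finite", call. = FALSE)
  for (f in c("p_threshold", "neg_p_threshold"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stop("candidate_config: ", f, " must lie in (0, 1)", call. = FALSE)
  class(cfg) <- "candidate_config"
  cfg
}

#' Call candidate genes with the four-filter rule
#'
#' A gene is a candidate iff (1) its positive-sort centered log2 FC exceeds
#' `fc_threshold_centered`, (2) its positive-sort KS p is below
#' `p_threshold`, (3) its TPM exceeds `tpm_threshold` in the reference
#' expression sample, and (4) it is NOT enriched in the reporter-negative
#' sort (negative-sort centered log2 FC > `neg_fc_threshold` AND negative
#' p < `neg_p_threshold` means discard). Genes absent from the expression
#' table get TPM 0 (and a message).
#'
#' @param pos_scores [gene_scores()] for the reporter-positive sort.
#' @param neg_scores [gene_scores()] for the reporter-negative sort (same
#'   library); `NULL` disables filter 4.
#' @param expression a `data.frame` with columns `gene` and a TPM column
#'   (first numeric column is used), or a named numeric vector of TPM.
#' @param config a [candidate_config()].
#' @return A `data.frame` of class `"candidate_calls"` sorted by descending
#'   centered log2 FC with all filter values and per-filter logicals
#'   attached; candidates carry `candidate = TRUE`.
#' @export
call_candidates <- function(pos_scores, neg_scores, expression,
                            config = candidate_config()) {
  stopifnot(inherits(config, "candidate_config"))
  tpm <- expression_vector(expression)
  out <- data.frame(gene = pos_scores$gene,
                    n_sgrna_values = pos_scores$n_sgrna_values,
                    raw_median_log2fc = pos_scores$raw_median_log2fc,
                    centered_log2fc = pos_scores$centered_log2fc,
                    ks_p = pos_scores$ks_p,
                    stringsAsFactors = FALSE)
  missing_expr <- setdiff(out$gene, names(tpm))
  if (length(missing_expr) > 0)
    message("call_candidates: ", length(missing_expr),
            " gene(s) missing from expression table, TPM set to 0")
  out$tpm <- ifelse(out$gene %in% names(tpm), tpm[out$gene], 0)
  if (!is.null(neg_scores)) {
    i <- match(out$gene, neg_scores$gene)
    out$neg_log2fc <- if (config$neg_on_centered)
      neg_scores$centered_log2fc[i] else neg_scores$raw_median_log2fc[i]
    out$neg_ks_p <- neg_scores$ks_p[i]
  } else {
    out$neg_log2fc <- NA_real_
    out$neg_ks_p <- NA_real_
  }
  out$pass_fc <- out$centered_log2fc > config$fc_threshold_centered
  out$pass_p <- out$ks_p < config$p_threshold
  out$pass_tpm <- out$tpm > config$tpm_threshold
  neg_enriched <- !is.na(out$neg_log2fc) &
    out$neg_log2fc > config$neg_fc_threshold &
    out$neg_ks_p < config$neg_p_threshold
  out$pass_neg <- !neg_enriched
  out$candidate <- out$pass_fc & out$pass_p & out$pass_tpm & out$pass_neg
  out <- out[order(-out$centered_log2fc, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("candidate_calls", "data.frame")
  out
}

expression_vector <- function(expression) {
  if (is.numeric(expression) && !is.null(names(expression)))
    return(expression)
  if (is.data.frame(expression)) {
    if (!"gene" %in% names(expression))
      stop("expression table needs a 'gene' column", call. = FALSE)
    num <- names(expression)[vapply(expression, is.numeric, logical(1))]
    if (length(num) == 0)
      stop("expression table has no numeric TPM column", call. = FALSE)
    return(stats::setNames(expression[[num[1]]], expression$gene))
  }
  stop("expression must be a data.frame or a named numeric vector",
       call. = FALSE)
}

#' Fisher's exact enrichment of candidates in an annotation set
#'
#' Builds the 2x2 candidate-by-annotated table over the gene universe and
#' returns the two-sided Fisher exact p-value together with the sample odds
#' ratio `(a*d)/(b*c)` (reported as `Inf` or 0 when a margin cell is zero).
#'
#' @param candidates character vector of candidate genes (subset of the
#'   universe).
#' @param annotation character vector of annotated genes (intersected with
#'   the universe).
#' @param universe character vector: all genes eligible for calling.
#' @return A list with `odds_ratio`, `p_value` and the 2x2 `table`.
#' @export
annotation_enrichment <- function(candidates, annotation, universe) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  candidates <- intersect(unique(candidates), universe)
  annotation <- intersect(unique(annotation), universe)
  a <- length(intersect(candidates, annotation))
  b <- length(setdiff(candidates, annotation))
  cc <- length(setdiff(annotation, candidates))
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, cc, b, d), nrow = 2,
                dimnames = list(candidate = c("yes", "no"),
                                annotated = c("yes", "no")))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  or <- if (b == 0 || cc == 0) {
    if (a == 0 || d == 0) NaN else Inf
  } else if (a == 0 || d == 0) 0 else (a * d) / (b * cc)
  list(odds_ratio = or, p_value = p, table = tab)
}
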