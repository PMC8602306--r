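#' Fit the gene-level enrichment model of a FACS-sorted CRISPR screen
#'
#' The one-stop estimator: normalizes the counts to reads per million with a
#' pseudocount, computes per-sgRNA log2 fold changes of the reporter-positive
#' (and, when present, reporter-negative) sort against the unsorted control
#' within each immunostaining experiment, pools the values per gene, trims
#' Tukey outliers, takes the median, centers the medians on the library
#' median, and attaches a two-sample two-sided Kolmogorov-Smirnov p-value
#' per gene.
#'
#' @param counts a [count_matrix()] with conditions `unsorted`, `pos` and
#'   optionally `neg`.
#' @param library the [sgrna_library()] the counts were quantified against.
#' @param pseudocount pseudocount for [normalize_counts()].
#' @param exclude_self,exact_limit passed to [gene_scores()].
#' @return An object of class `"screen_fit"`: a list with the normalized
#'   matrix, per-sgRNA fold-change tables (`fc_pos`, `fc_neg`), per-gene
#'   score tables (`scores_pos`, `scores_neg`), the realized global
#'   centering offsets, and the QC table. Use [coef()], [summary()],
#'   [plot()] and [candidates()] on it.
#' @examples
#' lib <- simulate_library(50, 4, seed = 2)
#' sim <- simulate_screen_counts(lib, sim_config(
#'   n_genes = 50, sgrnas_per_gene = 4, n_true_regulators = 3,
#'   reads_per_sample = 5e4, cells_per_replicate = 5e5, seed = 2))
#' fit <- screen_fit(sim$counts, lib)
#' head(coef(fit))
#' @export
screen_fit <- function(counts, library, pseudocount = 0.5,
                       exclude_self = FALSE, exact_limit = 10000) {
  stopifnot(inherits(counts, "count_matrix"))
  validate_sgrna_library(library)
  extra <- setdiff(rownames(counts$counts), library$sgrna_id)
  if (length(extra) > 0)
    stop("count rows not in library: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  qc <- screen_qc(counts, library)
  normalized <- normalize_counts(counts, pseudocount)
  fc_pos <- sgrna_log2fc_all(normalized, "pos")
  scores_pos <- gene_scores(fc_pos, library, exclude_self = exclude_self,
                            exact_limit = exact_limit)
  has_neg <- "neg" %in% counts$samples$condition
  fc_neg <- if (has_neg) sgrna_log2fc_all(normalized, "neg") else NULL
  scores_neg <- if (has_neg)
    gene_scores(fc_neg, library, exclude_self = exclude_self,
                exact_limit = exact_limit) else NULL
  structure(list(library = library, qc = qc, normalized = normalized,
                 fc_pos = fc_pos, fc_neg = fc_neg,
                 scores_pos = scores_pos, scores_neg = scores_neg,
                 global_offset_pos = attr(scores_pos, "global_offset"),
                 global_offset_neg = if (has_neg)
                   attr(scores_neg, "global_offset") else NA_real_,
                 pseudocount = pseudocount, call = match.call()),
            class = "screen_fit")
}

#' @export
print.screen_fit <- function(x, ...) {
  cat("FACS-sorted CRISPR screen fit\n")
  cat("  library: ", nrow(x$library), " sgRNAs, ",
      length(unique(x$library$gene)), " genes\n", sep = "")
  cat("  samples: ", ncol(x$normalized$norm), " (",
      paste(names(table(x$normalized$samples$condition)),
            table(x$normalized$samples$condition),
            sep = "=", collapse = ", "), ")\n", sep = "")
  cat(sprintf("  global centering offset (pos sort): %.4f\n",
              x$global_offset_pos))
  if (!is.na(x$global_offset_neg))
    cat(sprintf("  global centering offset (neg sort): %.4f\n",
                x$global_offset_neg))
  invisible(x)
}

#' Centered per-gene log2 fold changes of the fitted screen
#' @param object a [screen_fit()] object.
#' @param ... unused.
#' @return Named numeric vector of positive-sort centered log2 FC per gene.
#' @export
coef.screen_fit <- function(object, ...) {
  stats::setNames(object$scores_pos$centered_log2fc, object$scores_pos$gene)
}

#' Candidate genes of a fitted screen
#' @param object a fitted model.
#' @param ... passed to methods.
#' @return See methods.
#' @export
candidates <- function(object, ...) UseMethod("candidates")

#' @describeIn candidates apply the four-filter candidate rule to a
#'   [screen_fit()].
#' @param expression expression table or named TPM vector (see
#'   [call_candidates()]).
#' @param config a [candidate_config()].
#' @export
candidates.screen_fit <- function(object, expression,
                                  config = candidate_config(), ...) {
  call_candidates(object$scores_pos, object$scores_neg, expression, config)
}

#' @export
summary.screen_fit <- function(object, expression = NULL,
                               config = candidate_config(), ...) {
  calls <- if (!is.null(expression))
    candidates(object, expression, config) else NULL
  structure(list(fit = object, calls = calls, config = config),
            class = "summary.screen_fit")
}

#' @export
print.summary.screen_fit <- function(x, ...) {
  print(x$fit)
  sp <- x$fit$scores_pos
  cat(sprintf("  gene scores: n=%d, centered log2FC range [%.2f, %.2f]\n",
              nrow(sp), min(sp$centered_log2fc), max(sp$centered_log2fc)))
  cat(sprintf("  genes with KS p < %.3g: %d\n", x$config$p_threshold,
              sum(sp$ks_p < x$config$p_threshold)))
  if (!is.null(x$calls)) {
    cat("  candidates (all four filters):", sum(x$calls$candidate), "\n")
    if (any(x$calls$candidate))
      print(utils::head(
        x$calls[x$calls$candidate,
                c("gene", "centered_log2fc", "ks_p", "tpm")], 10),
        row.names = FALSE)
  }
  invisible(x)
}

#' Volcano plot of a fitted screen
#'
#' Centered per-gene log2 fold change against -log10 KS p-value, with genes
#' passing the FC and p cuts highlighted.
#'
#' @param x a [screen_fit()] object.
#' @param config a [candidate_config()] supplying the highlight cuts.
#' @param ... further arguments to [plot()].
#' @return Invisibly, the plotted data frame.
#' @export
plot.screen_fit <- function(x, config = candidate_config(), ...) {
  sp <- x$scores_pos
  hot <- sp$centered_log2fc > config$fc_threshold_centered &
    sp$ks_p < config$p_threshold
  graphics::plot(sp$centered_log2fc, -log10(pmax(sp$ks_p, 1e-300)),
                 xlab = "centered log2 fold change (sorted vs unsorted)",
                 ylab = "-log10 KS p-value",
                 col = ifelse(hot, "red3", "grey50"),
                 pch = 16, cex = 0.6, ...)
  graphics::abline(v = config$fc_threshold_centered, lty = 2)
  graphics::abline(h = -log10(config$p_threshold), lty = 2)
  invisible(data.frame(gene = sp$gene, centered_log2fc = sp$centered_log2fc,
                       minus_log10_p = -log10(pmax(sp$ks_p, 1e-300)),
                       highlighted = hot))
}

#' Residual dispersion of per-sgRNA fold changes around their gene medians
#' @param object a [screen_fit()] object.
#' @param ... unused.
#' @return Numeric vector: each positive-sort sgRNA fold change minus its
#'   gene's raw median score.
#' @export
residuals.screen_fit <- function(object, ...) {
  g <- object$library$gene[match(object$fc_pos$sgrna_id,
                                 object$library$sgrna_id)]
  med <- stats::setNames(object$scores_pos$raw_median_log2fc,
                         object$scores_pos$gene)
  object$fc_pos$log2fc - med[g]
}
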