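# End-to-end orchestration: validate inputs up front, run the stages, write
# every stage output plus a machine-readable manifest (input hashes,
# thresholds, realized offsets, package version) under one run directory.

#' Screen pipeline configuration
#'
#' @param counts,samples,library paths to the counts TSV, sample sheet TSV
#'   and library TSV.
#' @param expression path to the expression TSV (TPM; first sample column
#'   is the reference).
#' @param annotation optional path to an annotation gene list (one gene per
#'   line) for Fisher enrichment of the candidates.
#' @param outdir output directory (created if absent).
#' @param pseudocount normalization pseudocount.
#' @param config a [candidate_config()].
#' @return A validated list of class `"screen_run_config"`.
#' @export
screen_run_config <- function(counts, samples, library, expression,
                              annotation = NULL, outdir,
                              pseudocount = 0.5,
                              config = candidate_config()) {
  paths <- c(counts = counts, samples = samples, library = library,
             expression = expression)
  if (!is.null(annotation)) paths <- c(paths, annotation = annotation)
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files) > 0)
    stop("input file(s) not found: ",
         paste(names(missing_files), "=", missing_files, collapse = ", "),
         call. = FALSE)
  stopifnot(inherits(config, "candidate_config"))
  structure(list(counts = counts, samples = samples, library = library,
                 expression = expression, annotation = annotation,
                 outdir = outdir, pseudocount = pseudocount,
                 config = config),
            class = "screen_run_config")
}

#' Run the full screen hit-calling pipeline
#'
#' read inputs -> QC -> normalize -> per-experiment fold changes -> gene
#' scores (positive and negative sorts) -> candidate calling -> optional
#' annotation enrichment. Writes `qc.json`, `gene_scores_pos.tsv`,
#' `gene_scores_neg.tsv`, `candidates.tsv`, `volcano.tsv`,
#' `enrichment.json` (when an annotation list is given) and
#' `manifest.json` to the output directory. Deterministic: re-running with
#' the same inputs reproduces the outputs byte for byte.
#'
#' @param run_config a [screen_run_config()].
#' @return Invisibly, a list with the fitted object, candidate calls,
#'   enrichment result and the manifest.
#' @export
run_screen_pipeline <- function(run_config) {
  stopifnot(inherits(run_config, "screen_run_config"))
  outdir <- run_config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  library_tab <- read_library(run_config$library)
  samples <- read_sample_sheet(run_config$samples)
  counts <- read_counts(run_config$counts, samples, library_tab)
  expression <- read_expression(run_config$expression)
  fit <- screen_fit(counts, library_tab,
                    pseudocount = run_config$pseudocount)
  calls <- candidates(fit, expression, run_config$config)
  write_qc_json(fit$qc, file.path(outdir, "qc.json"))
  write_tsv(as.data.frame(fit$scores_pos),
            file.path(outdir, "gene_scores_pos.tsv"))
  if (!is.null(fit$scores_neg))
    write_tsv(as.data.frame(fit$scores_neg),
              file.path(outdir, "gene_scores_neg.tsv"))
  write_tsv(as.data.frame(calls), file.path(outdir, "candidates.tsv"))
  volcano <- data.frame(gene = fit$scores_pos$gene,
                        centered_log2fc = fit$scores_pos$centered_log2fc,
                        minus_log10_p = -log10(pmax(fit$scores_pos$ks_p,
                                                    1e-300)))
  write_tsv(volcano, file.path(outdir, "volcano.tsv"))
  enrichment <- NULL
  if (!is.null(run_config$annotation)) {
    ann <- readLines(run_config$annotation)
    ann <- ann[nzchar(ann) & !startsWith(ann, "#")]
    enrichment <- annotation_enrichment(calls$gene[calls$candidate], ann,
                                        unique(library_tab$gene))
    jsonlite::write_json(list(odds_ratio = enrichment$odds_ratio,
                              p_value = enrichment$p_value,
                              table = as.vector(enrichment$table)),
                         file.path(outdir, "enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- run_manifest(
    run_config,
    inputs = c(counts = run_config$counts, samples = run_config$samples,
               library = run_config$library,
               expression = run_config$expression,
               annotation = run_config$annotation),
    extra = list(global_offset_pos = fit$global_offset_pos,
                 global_offset_neg = fit$global_offset_neg,
                 n_candidates = sum(calls$candidate),
                 n_zero_filled = attr(counts, "n_zero_filled")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(fit = fit, candidates = calls, enrichment = enrichment,
                 manifest = manifest))
}

run_manifest <- function(run_config, inputs, extra = list()) {
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  hashes <- as.list(tools::md5sum(unlist(inputs)))
  names(hashes) <- names(inputs)
  cfg <- run_config$config
  thresholds <- if (inherits(cfg, "candidate_config")) unclass(cfg) else cfg
  c(list(package = "pegscreen",
         version = as.character(utils::packageVersion("pegscreen")),
         inputs = hashes, thresholds = thresholds),
    extra)
}

#' Methylation pipeline configuration
#'
#' @param cpg_control,cpg_treated paths to the per-sample CpG tables.
#' @param dmrs path to the DMR definition file.
#' @param expr_fc optional path to a TSV with columns `gene`, `fc`
#'   (expression fold change, demethylated vs control) for the response
#'   classification.
#' @param outdir output directory.
#' @param min_cpgs minimum CpGs per DMR for a defined mean.
#' @param demeth_delta_cut,activation_fc_cut response-classification
#'   thresholds.
#' @param coverage_weighted coverage-weighted DMR means.
#' @return A validated list of class `"meth_run_config"`.
#' @export
meth_run_config <- function(cpg_control, cpg_treated, dmrs, expr_fc = NULL,
                            outdir, min_cpgs = 3, demeth_delta_cut = -0.2,
                            activation_fc_cut = 2,
                            coverage_weighted = FALSE) {
  paths <- c(cpg_control = cpg_control, cpg_treated = cpg_treated,
             dmrs = dmrs)
  if (!is.null(expr_fc)) paths <- c(paths, expr_fc = expr_fc)
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files) > 0)
    stop("input file(s) not found: ",
         paste(names(missing_files), "=", missing_files, collapse = ", "),
         call. = FALSE)
  structure(list(cpg_control = cpg_control, cpg_treated = cpg_treated,
                 dmrs = dmrs, expr_fc = expr_fc, outdir = outdir,
                 min_cpgs = min_cpgs, demeth_delta_cut = demeth_delta_cut,
                 activation_fc_cut = activation_fc_cut,
                 coverage_weighted = coverage_weighted),
            class = "meth_run_config")
}

#' Run the imprinted-DMR methylation pipeline
#'
#' aggregate CpGs to DMR means (control and treated) -> retain informative
#' DMRs -> delta methylation -> global paired one-tailed hypomethylation
#' test -> optional response classification of associated genes. Writes
#' `dmr_means.tsv`, `informative_dmrs.tsv`, `delta.tsv`,
#' `peg_response.tsv` (when expression fold changes are given),
#' `meth_tests.json` and `manifest.json`.
#'
#' @param run_config a [meth_run_config()].
#' @return Invisibly, a list with the DMR means, retained DMRs, delta
#'   table, global test p-value, response table and manifest.
#' @export
run_methylation_pipeline <- function(run_config) {
  stopifnot(inherits(run_config, "meth_run_config"))
  outdir <- run_config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  control <- read_cpg_table(run_config$cpg_control)
  treated <- read_cpg_table(run_config$cpg_treated)
  dmrs <- read_dmrs(run_config$dmrs)
  means <- dmr_mean_beta(list(control = control, treated = treated), dmrs,
                         min_cpgs = run_config$min_cpgs,
                         coverage_weighted = run_config$coverage_weighted)
  means_c <- means[means$sample == "control", , drop = FALSE]
  means_t <- means[means$sample == "treated", , drop = FALSE]
  informative <- filter_informative_dmrs(means_c, dmrs)
  keep <- means_c$dmr %in% informative$name
  delta <- delta_methylation(means_t[keep, , drop = FALSE],
                             means_c[keep, , drop = FALSE])
  global_p <- global_methylation_test(treated, control, direction = "less")
  response <- NULL
  if (!is.null(run_config$expr_fc)) {
    fc_tab <- read_tsv_checked(run_config$expr_fc, c("gene", "fc"),
                               "expression fold changes")
    response <- peg_response_table(
      delta, informative, stats::setNames(fc_tab$fc, fc_tab$gene),
      demeth_delta_cut = run_config$demeth_delta_cut,
      activation_fc_cut = run_config$activation_fc_cut)
    write_tsv(response, file.path(outdir, "peg_response.tsv"))
  }
  write_tsv(means, file.path(outdir, "dmr_means.tsv"))
  write_tsv(as.data.frame(informative),
            file.path(outdir, "informative_dmrs.tsv"))
  write_tsv(delta, file.path(outdir, "delta.tsv"))
  jsonlite::write_json(
    list(global_hypomethylation = list(
      p_value = as.numeric(global_p),
      t_statistic = attr(global_p, "statistic"),
      df = attr(global_p, "df"),
      n_paired_cpgs = attr(global_p, "n_pairs"),
      direction = "treated < control")),
    file.path(outdir, "meth_tests.json"), auto_unbox = TRUE, digits = NA)
  manifest <- run_manifest(
    list(config = list(min_cpgs = run_config$min_cpgs,
                       demeth_delta_cut = run_config$demeth_delta_cut,
                       activation_fc_cut = run_config$activation_fc_cut,
                       coverage_weighted = run_config$coverage_weighted)),
    inputs = c(cpg_control = run_config$cpg_control,
               cpg_treated = run_config$cpg_treated,
               dmrs = run_config$dmrs, expr_fc = run_config$expr_fc),
    extra = list(n_informative_dmrs = nrow(informative)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(dmr_means = means, informative = informative,
                 delta = delta, global_p = global_p, response = response,
                 manifest = manifest))
}

#' Render a human-readable run report
#'
#' Summarizes the artifacts of a completed screen or methylation run
#' directory into one plain-text document. Contains no values that are not
#' present in the stage outputs; regeneration is idempotent.
#'
#' @param outdir a run directory written by [run_screen_pipeline()] or
#'   [run_methylation_pipeline()].
#' @param path output report path (default `report.txt` inside `outdir`).
#' @return `path`, invisibly.
#' @export
render_report <- function(outdir, path = file.path(outdir, "report.txt")) {
  manifest_path <- file.path(outdir, "manifest.json")
  if (!file.exists(manifest_path))
    stop("incomplete run: missing manifest.json in ", outdir, call. = FALSE)
  manifest <- jsonlite::read_json(manifest_path)
  lines <- c("pegscreen run report", strrep("=", 20), "",
             paste0("package version: ", manifest$version), "", "Inputs:")
  for (nm in names(manifest$inputs))
    lines <- c(lines, sprintf("  %s  md5=%s", nm, manifest$inputs[[nm]]))
  lines <- c(lines, "", "Thresholds:")
  for (nm in names(manifest$thresholds))
    lines <- c(lines, sprintf("  %s = %s", nm, manifest$thresholds[[nm]]))
  cand_path <- file.path(outdir, "candidates.tsv")
  if (file.exists(cand_path)) {
    calls <- utils::read.delim(cand_path)
    if (!is.null(manifest$global_offset_pos))
      lines <- c(lines, "",
                 sprintf("Realized global centering offset (pos): %.6f",
                         as.numeric(manifest$global_offset_pos)))
    lines <- c(lines, "",
               sprintf("Candidate genes: %d of %d", sum(calls$candidate),
                       nrow(calls)))
    if (sum(calls$candidate) > 0) {
      top <- utils::head(calls[calls$candidate, ], 15)
      lines <- c(lines, "Top candidates (gene, centered log2FC, KS p):",
                 sprintf("  %s  %.3f  %.3g", top$gene, top$centered_log2fc,
                         top$ks_p))
    } else {
      lines <- c(lines, "No gene passed all four filters.")
    }
  }
  enr_path <- file.path(outdir, "enrichment.json")
  if (file.exists(enr_path)) {
    enr <- jsonlite::read_json(enr_path)
    lines <- c(lines, "",
               sprintf("Annotation enrichment: odds ratio %s, p = %s",
                       enr$odds_ratio, enr$p_value))
  }
  delta_path <- file.path(outdir, "delta.tsv")
  if (file.exists(delta_path)) {
    delta <- utils::read.delim(delta_path)
    lines <- c(lines, "",
               sprintf("Informative DMRs with delta methylation: %d",
                       sum(!is.na(delta$delta))),
               sprintf("  mean delta: %.4f",
                       mean(delta$delta, na.rm = TRUE)))
  }
  resp_path <- file.path(outdir, "peg_response.tsv")
  if (file.exists(resp_path)) {
    resp <- utils::read.delim(resp_path)
    tab <- table(resp$category)
    lines <- c(lines, "Demethylation response of associated genes:",
               sprintf("  %s: %d", names(tab), as.integer(tab)))
  }
  writeLines(lines, path)
  invisible(path)
}
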