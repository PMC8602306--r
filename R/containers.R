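#' sgRNA library table
#'
#' Construct and validate the sgRNA-to-gene map that defines the universe for
#' all gene-level statistics. Each record carries a unique sgRNA identifier, a
#' unique 20-nt spacer sequence over \{A,C,G,T\} and a non-empty target gene.
#'
#' @param sgrna_id character vector of unique sgRNA identifiers.
#' @param spacer character vector of unique 20-nt spacers.
#' @param gene character vector of target gene symbols.
#' @return A `data.frame` of class `"sgrna_library"` with columns
#'   `sgrna_id`, `spacer`, `gene`.
#' @examples
#' sgrna_library(c("A_sg1", "A_sg2"),
#'               c("ACGTACGTACGTACGTACGT", "TTTTACGTACGTACGTACGT"),
#'               c("A", "A"))
#' @export
sgrna_library <- function(sgrna_id, spacer, gene) {
  lib <- data.frame(sgrna_id = as.character(sgrna_id),
                    spacer = toupper(as.character(spacer)),
                    gene = as.character(gene),
                    stringsAsFactors = FALSE)
  validate_sgrna_library(lib)
  class(lib) <- c("sgrna_library", "data.frame")
  lib
}

validate_sgrna_library <- function(lib, where = "library") {
  required <- c("sgrna_id", "spacer", "gene")
  missing_cols <- setdiff(required, names(lib))
  if (length(missing_cols) > 0)
    stop(where, ": missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(lib) == 0)
    stop(where, ": empty library", call. = FALSE)
  dup_id <- which(duplicated(lib$sgrna_id))
  if (length(dup_id) > 0)
    stop(where, ": duplicated sgrna_id '", lib$sgrna_id[dup_id[1]],
         "' at row ", dup_id[1], call. = FALSE)
  dup_sp <- which(duplicated(lib$spacer))
  if (length(dup_sp) > 0)
    stop(where, ": duplicated spacer '", lib$spacer[dup_sp[1]],
         "' at row ", dup_sp[1], call. = FALSE)
  bad <- which(!grepl("^[ACGT]{20}$", lib$spacer))
  if (length(bad) > 0)
    stop(where, ": spacer at row ", bad[1],
         " is not a 20-nt A/C/G/T string: '", lib$spacer[bad[1]], "'",
         call. = FALSE)
  empty_gene <- which(is.na(lib$gene) | lib$gene == "")
  if (length(empty_gene) > 0)
    stop(where, ": empty gene at row ", empty_gene[1], call. = FALSE)
  invisible(lib)
}

#' Sample sheet
#'
#' Validate the per-sample metadata used throughout the screen analysis.
#' `condition` must be one of `"unsorted"` (the library before sorting),
#' `"pos"` (reporter-positive sort) or `"neg"` (reporter-negative sort).
#'
#' @param sample_id unique sample identifiers.
#' @param condition one of `"unsorted"`, `"pos"`, `"neg"` per sample.
#' @param experiment immunostaining-experiment identifier per sample.
#' @param replicate replicate identifier per sample.
#' @return A validated `data.frame` of class `"sample_sheet"`.
#' @export
sample_sheet <- function(sample_id, condition, experiment, replicate) {
  sheet <- data.frame(sample_id = as.character(sample_id),
                      condition = as.character(condition),
                      experiment = as.character(experiment),
                      replicate = as.character(replicate),
                      stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

validate_sample_sheet <- function(sheet, where = "sample sheet") {
  required <- c("sample_id", "condition", "experiment", "replicate")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols) > 0)
    stop(where, ": missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dup <- which(duplicated(sheet$sample_id))
  if (length(dup) > 0)
    stop(where, ": duplicated sample_id '", sheet$sample_id[dup[1]], "'",
         call. = FALSE)
  bad <- setdiff(unique(sheet$condition), c("unsorted", "pos", "neg"))
  if (length(bad) > 0)
    stop(where, ": unknown condition(s): ", paste(bad, collapse = ", "),
         " (expected unsorted/pos/neg)", call. = FALSE)
  invisible(sheet)
}

#' sgRNA count matrix with sample metadata
#'
#' Bundle an integer sgRNA-by-sample count matrix with its sample sheet.
#' Counts must be non-negative integers; every matrix column must appear in
#' the sheet exactly once (and vice versa).
#'
#' @param counts integer matrix, rows named by sgRNA id, columns by sample id.
#' @param samples a [sample_sheet()] covering exactly the matrix columns.
#' @return An object of class `"count_matrix"`: a list with elements
#'   `counts` and `samples`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  validate_sample_sheet(samples)
  if (is.null(rownames(counts)))
    stop("count matrix must have sgrna_id rownames", call. = FALSE)
  if (is.null(colnames(counts)))
    stop("count matrix must have sample_id colnames", call. = FALSE)
  if (!setequal(colnames(counts), samples$sample_id) ||
      ncol(counts) != nrow(samples))
    stop("count matrix columns and sample sheet disagree", call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "double"  # avoids integer overflow in column sums
  counts <- counts[, samples$sample_id, drop = FALSE]
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("sgRNA count matrix:", nrow(x$counts), "sgRNAs x",
      ncol(x$counts), "samples\n")
  tab <- table(x$samples$condition)
  cat("conditions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' DMR definition set
#'
#' Validate a table of imprinted differentially methylated regions.
#' Coordinates follow the BED convention: 0-based, half-open `[start, end)`.
#'
#' @param name unique DMR names.
#' @param chrom chromosome per DMR.
#' @param start,end 0-based half-open interval bounds, `start < end`.
#' @param origin parental origin, `"maternal"` or `"paternal"`.
#' @param genes comma-separated associated gene symbols (may be empty).
#' @return A `data.frame` of class `"dmr_set"`.
#' @export
dmr_set <- function(name, chrom, start, end, origin, genes = "") {
  dmrs <- data.frame(name = as.character(name), chrom = as.character(chrom),
                     start = as.integer(start), end = as.integer(end),
                     origin = as.character(origin),
                     genes = as.character(genes), stringsAsFactors = FALSE)
  validate_dmr_set(dmrs)
  class(dmrs) <- c("dmr_set", "data.frame")
  dmrs
}

validate_dmr_set <- function(dmrs, where = "DMR set") {
  required <- c("name", "chrom", "start", "end", "origin", "genes")
  missing_cols <- setdiff(required, names(dmrs))
  if (length(missing_cols) > 0)
    stop(where, ": missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dup <- which(duplicated(dmrs$name))
  if (length(dup) > 0)
    stop(where, ": duplicated DMR name '", dmrs$name[dup[1]], "'",
         call. = FALSE)
  bad <- which(!(dmrs$start < dmrs$end))
  if (length(bad) > 0)
    stop(where, ": start >= end for DMR '", dmrs$name[bad[1]], "'",
         call. = FALSE)
  badorig <- setdiff(unique(dmrs$origin), c("maternal", "paternal"))
  if (length(badorig) > 0)
    stop(where, ": unknown origin(s): ", paste(badorig, collapse = ", "),
         call. = FALSE)
  invisible(dmrs)
}

validate_cpg_table <- function(cpg, where = "CpG table") {
  required <- c("chrom", "start", "end", "beta", "coverage")
  missing_cols <- setdiff(required, names(cpg))
  if (length(missing_cols) > 0)
    stop(where, ": missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(cpg) > 0) {
    if (any(cpg$end != cpg$start + 1))
      stop(where, ": CpG records must have end = start + 1", call. = FALSE)
    if (any(is.na(cpg$beta)) || any(cpg$beta < 0) || any(cpg$beta > 1))
      stop(where, ": beta values must lie in [0, 1]", call. = FALSE)
    if (any(cpg$coverage < 0))
      stop(where, ": coverage must be >= 0", call. = FALSE)
  }
  cpg[order(cpg$chrom, cpg$start), , drop = FALSE]
}
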