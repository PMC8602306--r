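# Readers/writers for the screen's tabular formats. All tables are UTF-8
# TSV with a header, no quoting; lines starting with '#' are ignored.

read_tsv_checked <- function(path, required, where) {
  if (!file.exists(path))
    stop(where, ": file not found: ", path, call. = FALSE)
  x <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                         comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0)
    stop(where, " (", path, "): missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  x
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read and validate an sgRNA library TSV
#'
#' Expects columns `sgrna_id`, `spacer`, `gene`. Duplicated identifiers or
#' spacers and non-ACGT spacers abort with the offending row named.
#'
#' @param path path to a tab-separated library file.
#' @return An [sgrna_library()] object.
#' @export
read_library <- function(path) {
  x <- read_tsv_checked(path, c("sgrna_id", "spacer", "gene"), "library")
  sgrna_library(x$sgrna_id, x$spacer, x$gene)
}

#' Write an sgRNA library TSV
#' @param library an [sgrna_library()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  validate_sgrna_library(library)
  write_tsv(library[, c("sgrna_id", "spacer", "gene")], path)
}

#' Read a sample sheet TSV
#' @param path path to a TSV with columns `sample_id`, `condition`,
#'   `experiment`, `replicate`.
#' @return A [sample_sheet()] object.
#' @export
read_sample_sheet <- function(path) {
  x <- read_tsv_checked(path, c("sample_id", "condition", "experiment",
                                "replicate"), "sample sheet")
  sample_sheet(x$sample_id, x$condition, x$experiment, x$replicate)
}

#' Write a sample sheet TSV
#' @param samples a [sample_sheet()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  validate_sample_sheet(samples)
  write_tsv(samples[, c("sample_id", "condition", "experiment", "replicate")],
            path)
}

#' Read an sgRNA count matrix TSV
#'
#' The file holds an `sgrna_id` column plus one integer column per sample.
#' Samples present in the file but absent from the sheet are an error, as are
#' negative or non-integer counts and sgRNA ids outside the library. Library
#' sgRNAs missing from the file are added with count 0 (sequencing dropout)
#' and reported via a message; the number of zero-filled rows is attached as
#' attribute `n_zero_filled`.
#'
#' @param path counts TSV path.
#' @param samples a [sample_sheet()] (or path to one).
#' @param library an [sgrna_library()] defining the row universe.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, samples, library) {
  if (is.character(samples) && length(samples) == 1)
    samples <- read_sample_sheet(samples)
  validate_sample_sheet(samples)
  validate_sgrna_library(library)
  x <- read_tsv_checked(path, "sgrna_id", "counts")
  sample_cols <- setdiff(names(x), "sgrna_id")
  extra <- setdiff(sample_cols, samples$sample_id)
  if (length(extra) > 0)
    stop("counts (", path, "): sample(s) absent from the sample sheet: ",
         paste(extra, collapse = ", "), call. = FALSE)
  absent <- setdiff(samples$sample_id, sample_cols)
  if (length(absent) > 0)
    stop("counts (", path, "): sample sheet sample(s) missing from file: ",
         paste(absent, collapse = ", "), call. = FALSE)
  unknown <- setdiff(x$sgrna_id, library$sgrna_id)
  if (length(unknown) > 0)
    stop("counts (", path, "): sgRNA id(s) not in library: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  dup <- which(duplicated(x$sgrna_id))
  if (length(dup) > 0)
    stop("counts (", path, "): duplicated sgrna_id '", x$sgrna_id[dup[1]],
         "'", call. = FALSE)
  m <- as.matrix(x[, samples$sample_id, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m)))
    stop("counts (", path, "): non-numeric or missing count values",
         call. = FALSE)
  if (any(m < 0) || any(m != round(m)))
    stop("counts (", path, "): counts must be non-negative integers",
         call. = FALSE)
  rownames(m) <- x$sgrna_id
  missing_sg <- setdiff(library$sgrna_id, x$sgrna_id)
  if (length(missing_sg) > 0) {
    fill <- matrix(0, nrow = length(missing_sg), ncol = ncol(m),
                   dimnames = list(missing_sg, colnames(m)))
    m <- rbind(m, fill)
    message("read_counts: ", length(missing_sg),
            " library sgRNA(s) absent from file, filled with 0")
  }
  m <- m[library$sgrna_id, , drop = FALSE]
  out <- count_matrix(m, samples)
  attr(out, "n_zero_filled") <- length(missing_sg)
  out
}

#' Write an sgRNA count matrix TSV
#' @param x a [count_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(sgrna_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a gene expression table (TPM)
#' @param path TSV with a `gene` column plus one numeric TPM column per
#'   sample.
#' @return A `data.frame` with `gene` first, TPM columns after; TPM >= 0
#'   enforced.
#' @export
read_expression <- function(path) {
  x <- read_tsv_checked(path, "gene", "expression")
  num_cols <- setdiff(names(x), "gene")
  if (length(num_cols) == 0)
    stop("expression (", path, "): no sample columns", call. = FALSE)
  for (cc in num_cols) {
    if (!is.numeric(x[[cc]]) || any(is.na(x[[cc]])) || any(x[[cc]] < 0))
      stop("expression (", path, "): column '", cc,
           "' must be non-negative TPM", call. = FALSE)
  }
  x
}

#' Write a gene expression table
#' @param x data.frame with `gene` plus TPM columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) write_tsv(x, path)

#' Read a per-sample CpG methylation table
#'
#' bedGraph-like TSV with columns `chrom`, `start`, `end`, `beta`,
#' `coverage`; 0-based half-open single-CpG records (`end = start + 1`).
#' Rows are sorted by (chrom, start) after load.
#'
#' @param path input TSV path.
#' @return A validated, sorted `data.frame`.
#' @export
read_cpg_table <- function(path) {
  x <- read_tsv_checked(path, c("chrom", "start", "end", "beta", "coverage"),
                        "CpG table")
  validate_cpg_table(x, where = paste0("CpG table (", path, ")"))
}

#' Write a per-sample CpG methylation table
#' @param x CpG table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cpg_table <- function(x, path) {
  write_tsv(x[, c("chrom", "start", "end", "beta", "coverage")], path)
}

#' Read a DMR definition file
#'
#' BED-like TSV with columns `chrom`, `start`, `end`, `name`, `origin`
#' (maternal/paternal) and `genes` (comma-separated associated genes).
#'
#' @param path input path.
#' @return A [dmr_set()].
#' @export
read_dmrs <- function(path) {
  x <- read_tsv_checked(path, c("chrom", "start", "end", "name", "origin",
                                "genes"), "DMR file")
  x$genes[is.na(x$genes)] <- ""
  dmr_set(x$name, x$chrom, x$start, x$end, x$origin, x$genes)
}

#' Write a DMR definition file
#' @param dmrs a [dmr_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dmrs <- function(dmrs, path) {
  validate_dmr_set(dmrs)
  write_tsv(dmrs[, c("chrom", "start", "end", "name", "origin", "genes")],
            path)
}

#' Screen coverage and representation QC
#'
#' For each sample: total reads, representation (number of library sgRNAs
#' seen at least once), representation fraction, and read-coverage fold
#' (total reads / library size). When `cells_per_replicate` is given, the
#' cell-coverage fold (cells / library size) is reported alongside — e.g.
#' 150 million stained cells against a 181,131-sgRNA library is a >800-fold
#' representation.
#'
#' @param x a [count_matrix()].
#' @param library an [sgrna_library()].
#' @param cells_per_replicate optional positive cell count per replicate.
#' @return A `data.frame` of class `"screen_qc"`, one row per sample, with
#'   the library size and cell-coverage fold as attributes.
#' @export
screen_qc <- function(x, library, cells_per_replicate = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  validate_sgrna_library(library)
  if (!is.null(cells_per_replicate) && cells_per_replicate <= 0)
    stop("cells_per_replicate must be > 0", call. = FALSE)
  L <- nrow(library)
  total <- colSums(x$counts)
  represented <- colSums(x$counts[library$sgrna_id, , drop = FALSE] >= 1)
  qc <- data.frame(sample_id = colnames(x$counts),
                   total_reads = unname(total),
                   representation = unname(represented),
                   representation_fraction = unname(represented) / L,
                   read_coverage_fold = unname(total) / L,
                   stringsAsFactors = FALSE)
  attr(qc, "library_size") <- L
  if (!is.null(cells_per_replicate)) {
    attr(qc, "cells_per_replicate") <- cells_per_replicate
    attr(qc, "cell_coverage_fold") <- cells_per_replicate / L
  }
  class(qc) <- c("screen_qc", "data.frame")
  qc
}

#' @export
print.screen_qc <- function(x, ...) {
  cat("Screen QC (library size ", attr(x, "library_size"), ")\n", sep = "")
  if (!is.null(attr(x, "cell_coverage_fold")))
    cat(sprintf("cell coverage: %.1f-fold (%g cells per replicate)\n",
                attr(x, "cell_coverage_fold"),
                attr(x, "cells_per_replicate")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a QC report as JSON
#' @param qc a [screen_qc()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_qc_json <- function(qc, path) {
  payload <- list(library_size = attr(qc, "library_size"),
                  cells_per_replicate = attr(qc, "cells_per_replicate"),
                  cell_coverage_fold = attr(qc, "cell_coverage_fold"),
                  samples = as.data.frame(qc))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
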