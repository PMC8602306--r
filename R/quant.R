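# Counting sgRNA spacers in amplicon reads. Exact matching slides a 20-nt
# window over every read and hashes it against the library (vectorized per
# offset); one-mismatch rescue uses a 2x10-nt seed split: a Hamming-1 hit
# must match one 10-mer half exactly, so candidate sgRNAs are looked up by
# half and verified on the full spacer.

#' Count sgRNA spacers in amplicon FASTQ reads
#'
#' Each read is assigned to at most one sgRNA: an exact 20-mer spacer match
#' at any offset wins; reads matching two different spacers (chimeras) are
#' unassigned. If no exact match exists and `max_mismatches = 1`, a unique
#' Hamming-distance-1 match is accepted; ambiguous rescues (two or more
#' candidate sgRNAs) stay unassigned, as do reads shorter than 20 nt.
#' Assignment is independent of read order.
#'
#' @param fastq either a character vector of read sequences, a single FASTQ
#'   path, or a named vector/list of FASTQ paths (one per sample; plain or
#'   gzip).
#' @param library an [sgrna_library()].
#' @param max_mismatches 0 or 1.
#' @param rc_scan also scan the reverse complement of each read (off by
#'   default: amplicon orientation is fixed by the primers).
#' @return An object of class `"quant_result"`: list with `counts` (integer
#'   matrix, library sgRNAs x samples), `n_reads_total` and
#'   `n_reads_unassigned` (per sample). Assigned counts plus unassigned
#'   reads always sum to the total.
#' @export
quantify <- function(fastq, library, max_mismatches = 0, rc_scan = FALSE) {
  validate_sgrna_library(library)
  if (!max_mismatches %in% c(0, 1))
    stop("max_mismatches must be 0 or 1", call. = FALSE)
  if (is.list(fastq)) fastq <- unlist(fastq)
  as_paths <- length(fastq) >= 1 && all(file.exists(fastq))
  if (as_paths) {
    samples <- if (!is.null(names(fastq))) names(fastq) else
      sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq))
    read_sets <- lapply(fastq, read_fastq_seqs)
  } else {
    samples <- "sample"
    read_sets <- list(as.character(fastq))
  }
  counts <- matrix(0L, nrow = nrow(library), ncol = length(read_sets),
                   dimnames = list(library$sgrna_id, samples))
  totals <- integer(length(read_sets))
  unassigned <- integer(length(read_sets))
  for (j in seq_along(read_sets)) {
    assn <- assign_reads(read_sets[[j]], library, max_mismatches, rc_scan)
    tab <- tabulate(assn[!is.na(assn)], nbins = nrow(library))
    counts[, j] <- tab
    totals[j] <- length(assn)
    unassigned[j] <- sum(is.na(assn))
  }
  structure(list(counts = counts, n_reads_total = stats::setNames(totals, samples),
                 n_reads_unassigned = stats::setNames(unassigned, samples)),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat("sgRNA quantification:", nrow(x$counts), "sgRNAs,",
      ncol(x$counts), "sample(s)\n")
  for (j in seq_len(ncol(x$counts)))
    cat(sprintf("  %s: %d reads, %d unassigned (%.2f%%)\n",
                colnames(x$counts)[j], x$n_reads_total[j],
                x$n_reads_unassigned[j],
                100 * x$n_reads_unassigned[j] / max(1, x$n_reads_total[j])))
  invisible(x)
}

read_fastq_seqs <- function(path) {
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) stop("unreadable FASTQ file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  toupper(as.character(seqs))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# returns per-read library row index, NA = unassigned
assign_reads <- function(reads, library, max_mismatches, rc_scan) {
  n <- length(reads)
  if (n == 0) return(integer(0))
  reads <- toupper(reads)
  scan_set <- if (rc_scan) c(reads, revcomp(reads)) else reads
  hit <- exact_scan(scan_set, library$spacer)
  if (rc_scan) {
    fwd <- hit$idx[seq_len(n)]; rev <- hit$idx[n + seq_len(n)]
    amb <- hit$ambiguous[seq_len(n)] | hit$ambiguous[n + seq_len(n)] |
      (!is.na(fwd) & !is.na(rev) & fwd != rev)
    idx <- ifelse(is.na(fwd), rev, fwd)
    idx[amb] <- NA_integer_
    ambiguous <- amb
  } else {
    idx <- hit$idx
    ambiguous <- hit$ambiguous
  }
  if (max_mismatches == 1) {
    todo <- which(is.na(idx) & !ambiguous)
    if (length(todo) > 0) {
      half_index <- build_half_index(library$spacer)
      for (i in todo) {
        cand <- mismatch1_candidates(reads[i], library$spacer, half_index)
        if (rc_scan && length(cand) != 1)
          cand <- union(cand, mismatch1_candidates(revcomp(reads[i]),
                                                   library$spacer,
                                                   half_index))
        if (length(cand) == 1) idx[i] <- cand
      }
    }
  }
  idx
}

# vectorized exact 20-mer scan; per read reports the unique matching sgRNA
# index or flags ambiguity when two distinct sgRNAs match
exact_scan <- function(reads, spacers) {
  n <- length(reads)
  idx <- rep(NA_integer_, n)
  ambiguous <- logical(n)
  widths <- nchar(reads)
  max_off <- max(widths) - 19L
  if (max_off < 1) return(list(idx = idx, ambiguous = ambiguous))
  for (off in seq_len(max_off)) {
    live <- which(widths >= off + 19L)
    if (length(live) == 0) next
    m <- match(substr(reads[live], off, off + 19L), spacers)
    found <- which(!is.na(m))
    if (length(found) == 0) next
    r <- live[found]; s <- m[found]
    fresh <- is.na(idx[r])
    idx[r[fresh]] <- s[fresh]
    clash <- !fresh & idx[r] != s
    ambiguous[r[clash]] <- TRUE
  }
  idx[ambiguous] <- NA_integer_
  list(idx = idx, ambiguous = ambiguous)
}

build_half_index <- function(spacers) {
  list(h1 = split(seq_along(spacers), substr(spacers, 1, 10)),
       h2 = split(seq_along(spacers), substr(spacers, 11, 20)))
}

hamming20 <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

mismatch1_candidates <- function(read, spacers, half_index) {
  w <- nchar(read)
  if (w < 20) return(integer(0))
  cand <- integer(0)
  for (off in seq_len(w - 19L)) {
    window <- substr(read, off, off + 19L)
    js <- unique(c(half_index$h1[[substr(window, 1, 10)]],
                   half_index$h2[[substr(window, 11, 20)]]))
    for (j in js)
      if (hamming20(window, spacers[j]) <= 1) cand <- c(cand, j)
  }
  unique(cand)
}

#' Convert quantification results to a count matrix
#' @param x a `"quant_result"`.
#' @param samples a [sample_sheet()] covering the quantified samples.
#' @return A [count_matrix()].
#' @export
quant_to_counts <- function(x, samples) {
  stopifnot(inherits(x, "quant_result"))
  count_matrix(x$counts, samples)
}
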