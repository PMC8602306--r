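# Small fixtures built in code, shared across test files.

toy_library <- function() {
  sgrna_library(
    sgrna_id = c("A_sg1", "A_sg2", "B_sg1", "B_sg2", "C_sg1"),
    spacer = c("ACGTACGTACGTACGTACGT",
               "TGCATGCATGCATGCATGCA",
               "AAAACCCCGGGGTTTTACGT",
               "GATTACAGATTACAGATTAC",
               "CCCGGGAAATTTCCCGGGAA"),
    gene = c("A", "A", "B", "B", "C"))
}

# one experiment, one replicate per condition; counts chosen by hand
toy_counts <- function() {
  lib <- toy_library()
  sheet <- sample_sheet(
    sample_id = c("unsorted_e1_r1", "pos_e1_r1", "neg_e1_r1"),
    condition = c("unsorted", "pos", "neg"),
    experiment = "exp1", replicate = "1")
  m <- matrix(c(100, 100, 100, 100, 100,
                400, 400, 50, 50, 100,
                100, 100, 100, 100, 100),
              nrow = 5, dimnames = list(lib$sgrna_id, sheet$sample_id))
  count_matrix(m, sheet)
}

toy_dmrs <- function() {
  dmr_set(name = c("DMR_A", "DMR_B", "DMR_C"),
          chrom = c("chr1", "chr1", "chr2"),
          start = c(100, 1000, 500),
          end = c(300, 1400, 900),
          origin = c("maternal", "paternal", "maternal"),
          genes = c("PEGA", "GENB", "PEGC1,PEGC2"))
}

toy_cpgs <- function(betas, dmrs = toy_dmrs(), spacing = 10) {
  pos <- unlist(lapply(seq_len(nrow(dmrs)), function(i)
    seq(dmrs$start[i], dmrs$end[i] - 1, by = spacing)))
  chrom <- rep(dmrs$chrom, vapply(seq_len(nrow(dmrs)), function(i)
    length(seq(dmrs$start[i], dmrs$end[i] - 1, by = spacing)), integer(1)))
  stopifnot(length(betas) == length(pos))
  data.frame(chrom = chrom, start = pos, end = pos + 1L, beta = betas,
             coverage = 30L, stringsAsFactors = FALSE)
}

# brute-force enumeration of the exact two-sample two-sided KS p-value:
# every split of the pooled values into groups of sizes (n, m)
ks_exact_oracle <- function(x, y) {
  pool <- c(x, y)
  n <- length(x)
  d_obs <- ks_stat_oracle(x, y)
  splits <- utils::combn(length(pool), n)
  d_all <- apply(splits, 2, function(idx)
    ks_stat_oracle(pool[idx], pool[-idx]))
  mean(d_all >= d_obs - 1e-12)
}

ks_stat_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- colMeans(outer(x, pts, "<="))
  Fy <- colMeans(outer(y, pts, "<="))
  max(abs(Fx - Fy))
}

# the R command the hinge rule mimics, as an independent route
setdiff_outliers_boxplot <- function(x) {
  out <- grDevices::boxplot.stats(x)$out
  x[!x %in% out]
}

# hinge oracle: sort, take fivenum hinges, enumerate retained values
tukey_retain_oracle <- function(v) {
  st <- stats::fivenum(v)
  iqr <- st[4] - st[2]
  v[v >= st[2] - 1.5 * iqr & v <= st[4] + 1.5 * iqr]
}

# two-sided Fisher p as a hypergeometric tail sum over tables with
# probability <= the observed one
fisher_oracle <- function(a, b, cc, d) {
  m <- a + cc; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
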