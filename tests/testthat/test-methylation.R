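# CpG-to-DMR aggregation, informative filters, delta methylation, paired
# one-tailed tests and the response classification.

test_that("CpG membership uses half-open BED semantics", {
  dmrs <- dmr_set("D1", "chr1", 100, 200, "maternal")
  mk <- function(start) data.frame(chrom = "chr1", start = start,
                                   end = start + 1L, beta = 0.5,
                                   coverage = 10L)
  expect_equal(assign_cpgs(mk(100), dmrs), "D1")        # left-closed
  expect_equal(assign_cpgs(mk(199), dmrs), "D1")
  expect_equal(assign_cpgs(mk(200), dmrs), "background") # right-open
  expect_equal(assign_cpgs(mk(99), dmrs), "background")

  # random CpGs against the brute-force interval scan
  dmrs3 <- toy_dmrs()
  set.seed(21)
  cpg <- data.frame(chrom = sample(c("chr1", "chr2"), 50, TRUE),
                    start = sample(0:1500, 50), beta = runif(50),
                    coverage = 20L)
  cpg$end <- cpg$start + 1L
  got <- assign_cpgs(cpg, dmrs3)
  cpg_sorted <- cpg[order(cpg$chrom, cpg$start), ]
  brute <- vapply(seq_len(nrow(cpg_sorted)), function(i) {
    hit <- which(dmrs3$chrom == cpg_sorted$chrom[i] &
                   dmrs3$start <= cpg_sorted$start[i] &
                   cpg_sorted$start[i] < dmrs3$end)
    if (length(hit) == 1) dmrs3$name[hit] else "background"
  }, character(1))
  expect_equal(got, brute)
})

test_that("DMR means are unweighted CpG means with a min-CpG guard", {
  dmrs <- dmr_set(c("D1", "D2"), "chr1", c(0, 100), c(30, 200),
                  c("maternal", "paternal"))
  cpg <- data.frame(chrom = "chr1",
                    start = c(0, 10, 20, 100, 110, 120, 130),
                    beta = c(0.2, 0.4, 0.6, 0.1, 0.2, 0.3, 0.8),
                    coverage = c(10, 10, 10, 5, 5, 5, 100))
  cpg$end <- cpg$start + 1L
  mb <- dmr_mean_beta(cpg, dmrs, min_cpgs = 1)
  expect_equal(mb$mean_beta[mb$dmr == "D1"], 0.4)
  expect_equal(mb$mean_beta[mb$dmr == "D2"], 0.35)
  expect_equal(mb$n_cpgs, c(3L, 4L))
  # coverage weighting is available behind the flag
  mbw <- dmr_mean_beta(cpg, dmrs, min_cpgs = 1, coverage_weighted = TRUE)
  expect_equal(mbw$mean_beta[mbw$dmr == "D2"],
               weighted.mean(c(0.1, 0.2, 0.3, 0.8), c(5, 5, 5, 100)))
  # zero-CpG DMR is flagged missing
  dmrs0 <- dmr_set("EMPTY", "chr9", 0, 100, "maternal")
  mb0 <- dmr_mean_beta(cpg, dmrs0, min_cpgs = 1)
  expect_true(mb0$missing)
  expect_true(is.na(mb0$mean_beta))
  # min_cpgs masks sparse DMRs
  mb3 <- dmr_mean_beta(cpg, dmrs, min_cpgs = 4)
  expect_true(is.na(mb3$mean_beta[mb3$dmr == "D1"]))
  expect_false(is.na(mb3$mean_beta[mb3$dmr == "D2"]))
})

test_that("informative-DMR filter drops by origin with closed boundaries", {
  dmrs <- dmr_set(paste0("D", 1:6), "chr1",
                  start = seq(0, 500, 100), end = seq(50, 550, 100),
                  origin = c("maternal", "maternal", "maternal",
                             "paternal", "paternal", "paternal"))
  means <- data.frame(dmr = paste0("D", 1:6), sample = "control",
                      mean_beta = c(0.55, 0.60, 0.80, 0.45, 0.40, 0.10),
                      n_cpgs = 10L, missing = FALSE)
  kept <- filter_informative_dmrs(means, dmrs)
  # maternal: <0.6 dropped, 0.60 exactly retained; paternal: >0.4 dropped,
  # 0.40 exactly retained
  expect_setequal(kept$name, c("D2", "D3", "D5", "D6"))
  # idempotence
  kept2 <- filter_informative_dmrs(means, kept)
  expect_equal(as.data.frame(kept2), as.data.frame(kept))
  # missing control mean -> excluded with a message
  means$mean_beta[3] <- NA
  expect_message(kept3 <- filter_informative_dmrs(means, dmrs),
                 "without a control mean")
  expect_setequal(kept3$name, c("D2", "D5", "D6"))
})

test_that("delta methylation is treated minus control and bounded", {
  mk_means <- function(beta) data.frame(dmr = c("D1", "D2"), sample = "x",
                                        mean_beta = beta, n_cpgs = 10L,
                                        missing = FALSE)
  d <- delta_methylation(mk_means(c(0.3, NA)), mk_means(c(0.8, 0.5)))
  expect_equal(d$delta[d$dmr == "D1"], -0.5)
  expect_true(is.na(d$delta[d$dmr == "D2"]))
  d0 <- delta_methylation(mk_means(c(0.8, 0.5)), mk_means(c(0.8, 0.5)))
  expect_true(all(d0$delta == 0))
  expect_true(all(abs(d$delta) <= 1, na.rm = TRUE))
  expect_error(delta_methylation(mk_means(c(0.1, 0.2)),
                                 data.frame(dmr = "OTHER", sample = "x",
                                            mean_beta = 1, n_cpgs = 1,
                                            missing = FALSE)),
               "same DMR set")
})

test_that("planted hypomethylation is recovered by the aggregation", {
  # one wide maternal DMR with >= 20 CpGs; grid of planted deltas
  dmrs <- dmr_set("TARGET", "chr1", 0, 250, "maternal", "PEGX")
  for (hd in c(0.1, 0.3, 0.5, 0.7)) {
    sim <- simulate_methylome(dmrs, 50, hypo_targets = "TARGET",
                              hypo_delta = hd, seed = 100 + round(100 * hd))
    means <- dmr_mean_beta(list(control = sim$control,
                                treated = sim$treated), dmrs)
    d <- delta_methylation(means[means$sample == "treated", ],
                           means[means$sample == "control", ])
    expect_lt(abs(d$delta - (-hd)), 0.05)
  }
})

test_that("paired one-tailed t-test matches the closed-form statistic", {
  a <- c(1.2, 0.8, 1.5, 1.1, 0.9)
  b <- c(1.0, 1.0, 1.0, 1.0, 1.0)
  p <- paired_onetailed_test(a, b, "greater")
  d <- a - b
  t_stat <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(attr(p, "statistic"), t_stat)
  expect_equal(as.numeric(p), stats::pt(t_stat, df = 4, lower.tail = FALSE))
  # symmetric differences with t = 0 -> p = 0.5
  p_null <- paired_onetailed_test(c(1, 2, 3, 4), c(2, 1, 4, 3), "less")
  expect_equal(as.numeric(p_null), 0.5)
  # uniform separation -> tiny one-tailed p
  x <- seq(0.1, 1, length.out = 10)
  p_sep <- paired_onetailed_test(x + 0.1, x, "greater")
  expect_lt(as.numeric(p_sep), 0.001)
  expect_error(paired_onetailed_test(c(1, 2), c(1, 2)), "degenerate")
  expect_error(paired_onetailed_test(1, 1), "at least 2")
})

test_that("global methylation test pairs CpGs across samples", {
  dmrs <- toy_dmrs()
  sim <- simulate_methylome(dmrs, 200, hypo_targets = c("DMR_A", "DMR_C"),
                            hypo_delta = 0.4, seed = 17)
  p <- global_methylation_test(sim$treated, sim$control, "less")
  expect_lt(as.numeric(p), 1e-6)
  expect_equal(attr(p, "n_pairs"), nrow(sim$control))
})

test_that("PEG response classification partitions all inputs", {
  expect_equal(as.character(classify_peg_response(-0.5, 8)),
               "demethylated_activated")
  expect_equal(as.character(classify_peg_response(-0.5, 1.1)),
               "demethylated_silent")
  expect_equal(as.character(classify_peg_response(-0.05, 1.0)),
               "methylation_retained")
  # boundary: delta exactly at the cut counts as demethylated; FC exactly
  # at the cut counts as activated
  expect_equal(as.character(classify_peg_response(-0.2, 2)),
               "demethylated_activated")
  # every (delta, FC) combination maps to exactly one category
  grid <- expand.grid(delta = seq(-1, 1, by = 0.1),
                      fc = c(0.1, 0.5, 1, 2, 10))
  cats <- classify_peg_response(grid$delta, grid$fc)
  expect_false(any(is.na(cats)))
  expect_error(classify_peg_response(-0.5, 0), "expr_fc")
})

test_that("peg_response_table joins DMRs to their associated genes", {
  dmrs <- toy_dmrs()
  delta <- data.frame(dmr = dmrs$name, control_mean = c(0.85, 0.15, 0.9),
                      treated_mean = c(0.35, 0.15, 0.85),
                      delta = c(-0.5, 0, -0.05))
  fc <- c(PEGA = 6, PEGC1 = 1.2, PEGC2 = 3, GENB = 1)
  resp <- peg_response_table(delta, dmrs, fc)
  expect_setequal(resp$gene, c("PEGA", "GENB", "PEGC1", "PEGC2"))
  expect_equal(as.character(resp$category[resp$gene == "PEGA"]),
               "demethylated_activated")
  expect_equal(as.character(resp$category[resp$gene == "PEGC1"]),
               "methylation_retained")
  expect_message(
    peg_response_table(delta, dmrs, fc[c("PEGA", "GENB")]),
    "dropped")
})
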