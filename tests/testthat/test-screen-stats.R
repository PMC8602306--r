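# Normalization, fold changes, outlier trimming, gene scoring, KS test,
# candidate calling and Fisher enrichment, each against an independent
# oracle where the spec provides one.

test_that("normalization follows the reads-per-million formula", {
  lib <- sgrna_library(paste0("g", 1:4, "_sg1"),
                       c("ACGTACGTACGTACGTACGT", "TGCATGCATGCATGCATGCA",
                         "AAAACCCCGGGGTTTTACGT", "GATTACAGATTACAGATTAC"),
                       paste0("g", 1:4))
  sheet <- sample_sheet("s1", "unsorted", "exp1", "1")
  m <- matrix(c(10, 10, 10, 10), ncol = 1,
              dimnames = list(lib$sgrna_id, "s1"))
  cm <- count_matrix(m, sheet)
  n0 <- normalize_counts(cm, pseudocount = 0)
  expect_true(all(abs(n0$norm - 250000) < 1e-9))

  # hand-computed 3x2 case with c = 0.5
  sheet2 <- sample_sheet(c("s1", "s2"), c("unsorted", "pos"), "exp1",
                         c("1", "1"))
  m2 <- matrix(c(0, 5, 15, 8, 2, 0), nrow = 3,
               dimnames = list(lib$sgrna_id[1:3], c("s1", "s2")))
  cm2 <- count_matrix(m2, sheet2)
  n2 <- normalize_counts(cm2, pseudocount = 0.5)
  expected_s1 <- (c(0, 5, 15) + 0.5) / (20 + 0.5 * 3) * 1e6
  expected_s2 <- (c(8, 2, 0) + 0.5) / (10 + 0.5 * 3) * 1e6
  expect_equal(unname(n2$norm[, "s1"]), expected_s1)
  expect_equal(unname(n2$norm[, "s2"]), expected_s2)
  # pseudocount keeps zero-count sgRNAs strictly positive
  expect_true(all(n2$norm > 0))

  m3 <- m2; m3[, "s2"] <- 0
  expect_error(normalize_counts(count_matrix(m3, sheet2)), "s2")
})

test_that("per-sgRNA log2 fold changes follow the sign convention", {
  cm <- toy_counts()
  norm <- normalize_counts(cm, pseudocount = 0)
  fc <- sgrna_log2fc(norm, "pos", "exp1")
  # unsorted shares are 0.2 each; pos shares are (.4,.4,.05,.05,.1), so the
  # normalized ratio is 2 for A sgRNAs, 0.25 for B, 0.5 for C
  expect_equal(fc$log2fc[fc$sgrna_id == "A_sg1"], 1)
  expect_equal(fc$log2fc[fc$sgrna_id == "B_sg1"], -2)
  expect_equal(fc$log2fc[fc$sgrna_id == "C_sg1"], -1)
  # identical values in both conditions -> all zero
  fc_neg <- sgrna_log2fc(norm, "neg", "exp1")
  expect_true(all(fc_neg$log2fc == 0))
  # sgRNA present only in the sorted sample -> positive fold change
  m <- cm$counts; m["C_sg1", "unsorted_e1_r1"] <- 0
  fc2 <- sgrna_log2fc(normalize_counts(count_matrix(m, cm$samples)),
                      "pos", "exp1")
  expect_gt(fc2$log2fc[fc2$sgrna_id == "C_sg1"], 0)
  expect_error(sgrna_log2fc(norm, "pos", "exp99"), "no 'pos' samples")
})

test_that("remove_outliers matches the hinge rule and its oracle", {
  expect_equal(remove_outliers(c(1, 1, 1, 1, 100)), c(1, 1, 1, 1))
  expect_equal(remove_outliers(c(1, 2, 3, 4, 5)), c(1, 2, 3, 4, 5))
  expect_equal(remove_outliers(c(7, 7, 7)), c(7, 7, 7))
  expect_error(remove_outliers(numeric(0)), "empty")
  # retained set keeps input order
  v <- c(5, 1, 100, 2, 3)
  expect_equal(remove_outliers(v), c(5, 1, 2, 3))

  # sort-and-enumerate hinge oracle and the R command the rule mimics
  set.seed(42)
  for (i in 1:200) {
    n <- sample(1:40, 1)
    x <- round(rnorm(n, sd = sample(c(1, 10), 1)), 2)
    kept <- remove_outliers(x)
    expect_equal(sort(kept), sort(tukey_retain_oracle(x)))
    expect_equal(sort(kept), sort(setdiff_outliers_boxplot(x)))
  }
})

test_that("gene_ks_test equals exhaustive enumeration on small samples", {
  set.seed(7)
  cases <- list(c(2, 5), c(3, 5), c(3, 4), c(4, 5), c(2, 10), c(5, 5))
  for (sz in cases) {
    x <- round(rnorm(sz[1]), 2)
    y <- round(rnorm(sz[2]), 2)
    expect_equal(as.numeric(gene_ks_test(x, y)), ks_exact_oracle(x, y),
                 tolerance = 1e-10)
  }
  # with ties
  xt <- c(1, 2, 2); yt <- c(2, 3, 3, 1, 2)
  expect_equal(as.numeric(gene_ks_test(xt, yt)), ks_exact_oracle(xt, yt),
               tolerance = 1e-10)
})

test_that("gene_ks_test extremes and asymptotic branch behave", {
  # total separation -> D = 1, smallest attainable p
  x <- c(10, 11, 12); y <- c(1, 2, 3, 4, 5)
  p <- gene_ks_test(x, y)
  expect_equal(attr(p, "statistic"), 1)
  expect_equal(as.numeric(p), ks_exact_oracle(x, y), tolerance = 1e-10)
  # matched toy sets -> large p
  bg <- rep(1:10, 3)
  expect_gt(as.numeric(gene_ks_test(c(2, 5, 8), bg)), 0.5)
  # asymptotic branch agrees with the exact one to a few percent at
  # moderate sizes (forced by a tiny exact_limit)
  set.seed(11)
  x2 <- rnorm(25); y2 <- rnorm(60)
  p_exact <- as.numeric(gene_ks_test(x2, y2, exact_limit = 1e7))
  p_asym <- as.numeric(gene_ks_test(x2, y2, exact_limit = 1))
  expect_lt(abs(p_exact - p_asym), 0.05)
  expect_error(gene_ks_test(numeric(0), y2), "non-empty")
})

test_that("gene scores pool, trim, and center on the library median", {
  lib <- sgrna_library(
    c("A_sg1", "A_sg2", "A_sg3", "B_sg1", "B_sg2", "B_sg3"),
    c("ACGTACGTACGTACGTACGT", "TGCATGCATGCATGCATGCA",
      "AAAACCCCGGGGTTTTACGT", "GATTACAGATTACAGATTAC",
      "CCCGGGAAATTTCCCGGGAA", "TTTTAAAACCCCGGGGACGT"),
    c("A", "A", "A", "B", "B", "B"))
  fc <- data.frame(
    sgrna_id = lib$sgrna_id,
    experiment = "exp1",
    log2fc = c(-1.0, -0.9, -0.8, 0.4, 0.5, 0.6))
  gs <- gene_scores(fc, lib)
  # raw medians {-0.9, 0.5}; offset = median = -0.2; centered {-0.7, 0.7}
  expect_equal(attr(gs, "global_offset"), -0.2)
  expect_equal(gs$raw_median_log2fc[gs$gene == "A"], -0.9)
  expect_equal(gs$centered_log2fc[gs$gene == "A"], -0.7)
  expect_equal(gs$centered_log2fc[gs$gene == "B"], 0.7)
  expect_equal(median(gs$centered_log2fc), 0)
  # the screen regime: raw 0.5 against a global offset of -0.9 centers
  # to 1.4, the candidate threshold
  expect_equal(0.5 - (-0.9), 1.4)

  # identical FC distributions for all genes -> all centered scores 0
  fc_same <- fc; fc_same$log2fc <- rep(c(-0.1, 0, 0.1), 2)
  gs_same <- gene_scores(fc_same, lib)
  expect_true(all(gs_same$centered_log2fc == 0))

  # an outlier sgRNA is trimmed before the median (values pooled over two
  # experiments, as in the screen)
  fc_out <- rbind(fc, fc)
  fc_out$experiment <- rep(c("exp1", "exp2"), each = 6)
  fc_out$log2fc <- c(0, 0.01, 0.02, 0.4, 0.5, 0.6,     # exp1
                     -0.1, 0.1, 50, 0.45, 0.55, 0.65)  # exp2
  gs_out <- gene_scores(fc_out, lib)
  expect_equal(gs_out$n_sgrna_values[gs_out$gene == "A"], 5L)
  expect_equal(gs_out$raw_median_log2fc[gs_out$gene == "A"], 0.01)
  expect_false(gs_out$low_confidence[gs_out$gene == "A"])

  # a gene covered by fewer than 3 values is flagged low-confidence
  gs_low <- gene_scores(fc[c(1, 2, 4, 5, 6), ], lib)
  expect_true(gs_low$low_confidence[gs_low$gene == "A"])
  expect_false(gs_low$low_confidence[gs_low$gene == "B"])

  expect_error(gene_scores(data.frame(sgrna_id = "zzz", experiment = "e",
                                      log2fc = 1), lib), "not in library")
})

test_that("candidate calling applies the four filters verbatim", {
  mk_scores <- function(gene, centered, p, raw = centered - 0.9) {
    s <- data.frame(gene = gene, n_sgrna_values = 20L,
                    raw_median_log2fc = raw, centered_log2fc = centered,
                    ks_p = p, bh_fdr = p, low_confidence = FALSE)
    class(s) <- c("gene_scores", "data.frame")
    s
  }
  pos <- mk_scores(paste0("g", 1:6),
                   centered = c(2.0, 2.0, 2.0, 1.2, 2.0, 2.0),
                   p = c(0.001, 0.20, 0.001, 0.001, 0.001, 0.001))
  neg <- mk_scores(paste0("g", 1:6),
                   centered = c(0.1, 0.1, 0.1, 0.1, 0.9, 0.9),
                   p = c(0.5, 0.5, 0.5, 0.5, 0.01, 0.20))
  tpm <- c(g1 = 10, g2 = 10, g3 = 0.2, g4 = 10, g5 = 10, g6 = 10)
  calls <- call_candidates(pos, neg, tpm)
  # g1 passes all four; g2 fails p; g3 fails TPM; g4 fails FC;
  # g5 is negative-sort enriched (FC>0.5 & p<0.05) -> discarded;
  # g6 has neg FC>0.5 but neg p>=0.05 -> kept
  expect_setequal(calls$gene[calls$candidate], c("g1", "g6"))
  expect_false(calls$candidate[calls$gene == "g3"])
  expect_true(calls$pass_fc[calls$gene == "g3"])
  # sorted by descending centered FC
  expect_true(!is.unsorted(rev(calls$centered_log2fc)))
  # permuting input gene order never changes the candidate set
  perm <- sample(nrow(pos))
  calls_perm <- call_candidates(pos[perm, ], neg[perm, ], tpm)
  expect_setequal(calls_perm$gene[calls_perm$candidate],
                  calls$gene[calls$candidate])
  expect_error(candidate_config(p_threshold = 1.2), "p_threshold")
})

test_that("annotation enrichment matches the hypergeometric oracle", {
  # independence -> odds ratio 1
  universe <- paste0("g", 1:100)
  cand <- paste0("g", 1:20)
  ann <- paste0("g", c(1:4, 21:36))  # 20% of candidates, 20% of the rest
  res <- annotation_enrichment(cand, ann, universe)
  expect_equal(res$odds_ratio, 1)

  # the screen-scale table
  res2 <- annotation_enrichment(
    candidates = paste0("c", 1:115),
    annotation = c(paste0("c", 1:5), paste0("a", 1:95)),
    universe = c(paste0("c", 1:115), paste0("a", 1:95),
                 paste0("u", 1:17956)))
  expect_equal(unname(res2$table[1, ]), c(5, 110))
  expect_equal(unname(res2$table[2, ]), c(95, 17956))
  expect_equal(res2$p_value, fisher_oracle(5, 110, 95, 17956),
               tolerance = 1e-9)

  # perfect overlap -> infinite odds ratio, p < 1
  res3 <- annotation_enrichment(cand, cand, universe)
  expect_identical(res3$odds_ratio, Inf)
  expect_lt(res3$p_value, 1)

  # random tables against the tail-sum oracle
  set.seed(13)
  for (i in 1:50) {
    a <- sample(0:8, 1); b <- sample(0:30, 1)
    cc <- sample(0:30, 1); d <- sample(10:200, 1)
    if (a + b == 0 || a + cc == 0) next
    cand_i <- c(sprintf("ca%03d", seq_len(a)), sprintf("cb%03d", seq_len(b)))
    ann_i <- c(sprintf("ca%03d", seq_len(a)), sprintf("an%03d", seq_len(cc)))
    uni_i <- unique(c(cand_i, ann_i, sprintf("uu%03d", seq_len(d))))
    got <- annotation_enrichment(cand_i, ann_i, uni_i)
    expect_equal(got$p_value, fisher_oracle(a, b, cc, d), tolerance = 1e-9)
  }
  expect_error(annotation_enrichment("a", "b", character(0)), "universe")
})
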