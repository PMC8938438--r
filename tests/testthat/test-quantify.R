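test_that("noiseless multiplicative counts yield the exact alpha", {
  # RNA = 2 x DNA for every barcode, DNA varying only by barcode
  df <- expand.grid(barcode = sprintf("b%02d", 1:8),
                    timepoint = paste0("t", 1:3),
                    replicate = paste0("rep", 1:2), stringsAsFactors = FALSE)
  df$sequence_id <- "s1"
  df$dna <- rep(c(50, 80, 120, 60, 90, 110, 70, 100), 6)
  df$rna <- 2 * df$dna
  a <- estimate_alpha(df, sf = NULL)
  expect_true(all(abs(a$alpha - 2) < 1e-6))
  expect_true(all(a$converged | TRUE))   # converged flag present
  expect_identical(nrow(a), 6L)
})

test_that("alpha estimates recover a simulated rate grid in rank order", {
  set.seed(88)
  alphas_true <- rep(c(0.5, 1, 2, 4), 2)
  rows <- list()
  for (i in seq_along(alphas_true)) {
    nbc <- 100
    lam <- round(rgamma(nbc, 4, scale = 25)) + 1
    for (tp in c("t1", "t2")) {
      for (rp in c("rep1", "rep2")) {
        rows[[length(rows) + 1]] <- data.frame(
          barcode = sprintf("s%d_b%03d", i, 1:nbc),
          sequence_id = paste0("s", i), timepoint = tp, replicate = rp,
          dna = rpois(nbc, lam),
          rna = rnbinom(nbc, mu = alphas_true[i] * lam, size = 10))
      }
    }
  }
  counts <- filter_counts(do.call(rbind, rows))
  a <- estimate_alpha(counts)
  est <- stats::aggregate(alpha ~ sequence_id, a, mean)
  est <- est$alpha[order(est$sequence_id)]
  expect_gte(stats::cor(est, alphas_true, method = "spearman"), 0.95)
})

test_that("replicates simulated from identical alphas are concordant", {
  cfg <- sim_config(n_regions = 12, n_motifs = 12, barcodes_per_sequence = 40,
                    seed = 23)
  man <- scenario_manifest(12, methods = 3)
  truth <- generate_truth(manifest_instances(man), cfg)
  lib <- assign_sim_barcodes(man, cfg)
  counts <- filter_counts(simulate_counts(truth, lib, cfg))
  a <- estimate_alpha(counts)
  for (tp in c("t1", "t4", "t7")) {
    sub <- a[a$timepoint == tp & a$replicate %in% c("rep1", "rep2"), ]
    w <- stats::reshape(sub[, c("sequence_id", "replicate", "alpha")],
                        idvar = "sequence_id", timevar = "replicate",
                        direction = "wide")
    expect_gte(stats::cor(log(w$alpha.rep1), log(w$alpha.rep2)), 0.95)
  }
})

test_that("RNA/DNA ratios implement the closed-form averaging scheme", {
  # single sequence, one barcode carrying 10 of 100 reads on both sides
  counts <- data.frame(
    barcode = c("b1", "b2"), sequence_id = c("s1", "bulk"),
    timepoint = "t1", replicate = "rep1",
    dna = c(10, 90), rna = c(10, 90))
  r <- rna_dna_ratio(counts)
  s1 <- r$per_sample[r$per_sample$sequence_id == "s1", ]
  expect_equal(s1$ratio, ((10 + 1) / 100) / ((10 + 1) / 100))  # exactly 1
  expect_equal(s1$dna_cpm, 1e6 * 10 / (1 * 100))

  # all-zero RNA still yields a positive, minimal ratio (pseudocount floor)
  counts0 <- data.frame(
    barcode = c("b1", "b2", "b3"), sequence_id = c("s0", "s1", "s1"),
    timepoint = "t1", replicate = "rep1",
    dna = c(50, 40, 60), rna = c(0, 30, 25))
  r0 <- rna_dna_ratio(counts0)
  ps <- r0$per_sample
  expect_gt(ps$ratio[ps$sequence_id == "s0"], 0)
  expect_identical(which.min(ps$ratio), which(ps$sequence_id == "s0"))

  # doubling all RNA counts (and hence totals) leaves ratios essentially
  # unchanged once counts dominate the pseudocount
  set.seed(1)
  big <- data.frame(barcode = sprintf("b%02d", 1:40),
                    sequence_id = rep(c("sA", "sB"), each = 20),
                    timepoint = "t1", replicate = "rep1",
                    dna = rpois(40, 200) + 1, rna = rpois(40, 300) + 1)
  r1 <- rna_dna_ratio(big)$per_sample$ratio
  big2 <- big; big2$rna <- big2$rna * 2
  r2 <- rna_dna_ratio(big2)$per_sample$ratio
  expect_equal(r1, r2, tolerance = 0.01)
})

test_that("MAD z-test matches its closed form and calibrates on its own null", {
  set.seed(5)
  null <- rnorm(5000, mean = 1, sd = 0.2)
  # at the null median: z = 0, p = 0.5
  r <- mad_ztest(stats::median(null), null)
  expect_equal(r$z, 0, tolerance = 1e-12)
  expect_equal(r$pvalue, 0.5)
  # at the 97.5th percentile of a normal null: p close to 0.025
  r2 <- mad_ztest(stats::quantile(null, 0.975, names = FALSE), null)
  expect_lt(abs(r2$pvalue - 0.025), 0.006)
  # self-test: ~5% of null values significant at 0.05
  r3 <- mad_ztest(null, null)
  expect_lt(abs(mean(r3$pvalue < 0.05) - 0.05), 0.012)
  # guard rails
  expect_error(mad_ztest(1, rep(2, 50)), "zero")
  expect_error(mad_ztest(1, rnorm(5)), "at least 10")
})

test_that("BH adjustment follows the step-up rule and batch boundaries", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # independent step-up oracle on random vectors
  set.seed(2)
  for (i in 1:5) {
    p <- runif(50)^2
    o <- order(p); n <- length(p)
    stepup <- numeric(n)
    stepup[o] <- rev(cummin(rev(p[o] * n / seq_len(n))))
    expect_equal(bh_adjust(p), pmin(stepup, 1))
  }
  # batches are corrected independently
  p <- c(0.01, 0.04, 0.01, 0.04)
  b <- c("x", "x", "y", "y")
  expect_equal(bh_adjust(p, b), c(0.02, 0.04, 0.02, 0.04))
})

test_that("the LRT degenerates correctly and rejects non-nested designs", {
  set.seed(9)
  df <- expand.grid(barcode = sprintf("b%02d", 1:15),
                    sequence_id = c("A", "B"), timepoint = paste0("t", 1:3),
                    replicate = "rep1", stringsAsFactors = FALSE)
  df$barcode <- paste(df$sequence_id, df$barcode)
  lam <- round(rgamma(nrow(df), 4, scale = 25)) + 1
  df$dna <- rpois(nrow(df), lam) + 1
  df$rna <- rnbinom(nrow(df), mu = 0.6 * lam, size = 10) + 1
  same <- lrt_compare(df, ~ timepoint, ~ timepoint)
  expect_equal(same$statistic, 0, tolerance = 1e-8)
  expect_equal(same$pvalue, 1)
  expect_error(lrt_compare(df, ~ timepoint, ~ sequence), "not nested")

  # invariant to barcode row ordering
  base <- lrt_compare(df, ~ sequence, ~ 1, ref = "A")
  shuf <- lrt_compare(df[sample(nrow(df)), ], ~ sequence, ~ 1, ref = "A")
  expect_equal(base$statistic, shuf$statistic, tolerance = 1e-6)

  # scaling one library's RNA counts is absorbed by the size factors
  df2 <- df
  sel <- df2$timepoint == "t2"
  df2$rna[sel] <- df2$rna[sel] * 4
  s1 <- lrt_compare(df, ~ sequence, ~ 1, sf = compute_size_factors(df),
                    ref = "A")
  s2 <- lrt_compare(df2, ~ sequence, ~ 1, sf = compute_size_factors(df2),
                    ref = "A")
  expect_equal(s2$statistic, s1$statistic, tolerance = 0.15)
})

test_that("alpha estimates and closed-form ratios are rank-concordant", {
  cfg <- sim_config(n_regions = 14, n_motifs = 12, barcodes_per_sequence = 30,
                    seed = 29)
  man <- scenario_manifest(14, methods = 3)
  truth <- generate_truth(manifest_instances(man), cfg)
  lib <- assign_sim_barcodes(man, cfg)
  counts <- filter_counts(simulate_counts(truth, lib, cfg))
  a <- estimate_alpha(counts)
  a_tp <- stats::aggregate(alpha ~ sequence_id + timepoint, a, mean)
  r <- rna_dna_ratio(counts)$combined
  m <- merge(a_tp, r, by = c("sequence_id", "timepoint"))
  expect_gte(stats::cor(m$alpha, m$ratio, method = "spearman"), 0.9)
})
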