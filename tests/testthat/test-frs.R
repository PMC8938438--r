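# Build a minimal mpra_tests object by hand so the filter booleans and
# categorization clauses can be driven directly.
fake_tests <- function(instances, n_tp = 7) {
  tps <- paste0("t", seq_len(n_tp))
  per_tp <- list(); temporal <- list(); mad <- list()
  for (i in seq_len(nrow(instances))) {
    x <- instances[i, ]
    per_tp[[i]] <- data.frame(
      instance_id = x$instance_id, method = x$method, region = x$region,
      seq_id = sprintf("PERT|%s|m%d", x$instance_id, x$method),
      timepoint = tps, statistic = 1,
      pvalue = NA_real_, lfc = x$lfc,
      fdr = c(rep(0.01, x$n_sig_tp), rep(0.5, n_tp - x$n_sig_tp)))
    temporal[[i]] <- data.frame(
      instance_id = x$instance_id, method = x$method, region = x$region,
      comparison = c("PERT_WT", "PERT_SCRAM"), statistic = 1, df = 6,
      pvalue = NA_real_, lfc = x$lfc,
      fdr = c(x$fdr_temporal_pw, x$fdr_temporal_ps))
    mad[[i]] <- data.frame(
      seq_id = sprintf("PERT|%s|m%d", x$instance_id, x$method),
      role = "PERT", method = x$method, instance_id = x$instance_id,
      timepoint = tps, z = 1, pvalue = NA_real_,
      fdr = c(rep(0.01, x$n_mad_pert), rep(0.5, n_tp - x$n_mad_pert)))
  }
  regions <- unique(instances[, c("region", "n_mad_wt", "fdr_temporal_ws")])
  mad_wt <- lapply(seq_len(nrow(regions)), function(j) {
    data.frame(seq_id = paste0("WT|", regions$region[j]), role = "WT",
               method = NA_integer_, instance_id = NA_character_,
               timepoint = tps, z = 1, pvalue = NA_real_,
               fdr = c(rep(0.01, regions$n_mad_wt[j]),
                       rep(0.5, n_tp - regions$n_mad_wt[j])))
  })
  temporal_ws <- lapply(seq_len(nrow(regions)), function(j) {
    data.frame(instance_id = NA_character_, method = NA_integer_,
               region = regions$region[j], comparison = "WT_SCRAM",
               statistic = 1, df = 6, pvalue = NA_real_, lfc = NA_real_,
               fdr = regions$fdr_temporal_ws[j])
  })
  out <- list(per_tp = do.call(rbind, per_tp),
              temporal = rbind(do.call(rbind, temporal),
                               do.call(rbind, temporal_ws)),
              mad = rbind(do.call(rbind, mad), do.call(rbind, mad_wt)),
              n_timepoints = n_tp)
  class(out) <- "mpra_tests"
  out
}

base_instance <- function(...) {
  defaults <- data.frame(
    instance_id = "R1|M1|10-20", method = 3L, region = "R1", lfc = -1,
    n_sig_tp = 3L, fdr_temporal_pw = 0.001, fdr_temporal_ps = 0.001,
    n_mad_pert = 2L, n_mad_wt = 7L, fdr_temporal_ws = 0.001,
    stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) defaults[[nm]] <- mods[[nm]]
  defaults
}

test_that("the four filter booleans follow the printed expressions", {
  # baseline: everything significant -> all filters pass
  fl <- apply_filters(fake_tests(base_instance()))
  expect_true(all(unlist(fl[, c("f1", "f2", "f3", "f4")])))
  expect_true(fl$pass)
  expect_identical(fl$direction, "activating")

  # filter 1 needs at least one significant timepoint
  fl <- apply_filters(fake_tests(base_instance(n_sig_tp = 0L)))
  expect_false(fl$f1); expect_false(fl$pass)

  # filter 2 is the temporal perturbed-vs-wild-type comparison
  fl <- apply_filters(fake_tests(base_instance(fdr_temporal_pw = 0.2)))
  expect_false(fl$f2)

  # filter 3 via the WT clause: WT beats the null at all timepoints even
  # though the perturbed sequence never does
  fl <- apply_filters(fake_tests(base_instance(n_mad_pert = 0L, n_mad_wt = 7L)))
  expect_true(fl$f3)
  # ... but 6 of 7 timepoints is not enough when PERT has none
  fl <- apply_filters(fake_tests(base_instance(n_mad_pert = 0L, n_mad_wt = 6L)))
  expect_false(fl$f3)
  # the PERT clause needs only one timepoint
  fl <- apply_filters(fake_tests(base_instance(n_mad_pert = 1L, n_mad_wt = 0L)))
  expect_true(fl$f3)

  # filter 4 is an OR of the two temporal-vs-control comparisons
  fl <- apply_filters(fake_tests(base_instance(fdr_temporal_ps = 0.9,
                                               fdr_temporal_ws = 0.9)))
  expect_false(fl$f4)
  fl <- apply_filters(fake_tests(base_instance(fdr_temporal_ps = 0.9,
                                               fdr_temporal_ws = 0.01)))
  expect_true(fl$f4)

  # dampening direction from a positive fold change
  fl <- apply_filters(fake_tests(base_instance(lfc = 1)))
  expect_identical(fl$direction, "dampening")
})

test_that("consensus calling requires method 3 plus one fixed-replacement method", {
  fr_row <- function(method, pass, direction, fdr = 0.01,
                     iid = "R1|M1|10-20", windows = "10-20") {
    data.frame(instance_id = iid, method = method, region = "R1",
               motif = "M1", windows = windows, f1 = pass, f2 = pass,
               f3 = pass, f4 = pass, pass = pass, n_sig_up = 0,
               n_sig_down = 3, direction = direction, temporal_fdr = fdr,
               temporal_lfc = -1, stringsAsFactors = FALSE)
  }
  # methods 1 + 2 only: not an FRS
  fr <- rbind(fr_row(1, TRUE, "activating"), fr_row(2, TRUE, "activating"),
              fr_row(3, FALSE, "activating"))
  expect_identical(nrow(consensus_frs(fr)), 0L)
  # methods 3 + 1, concordant downward direction: FRS, activating
  fr <- rbind(fr_row(3, TRUE, "activating"), fr_row(1, TRUE, "activating"),
              fr_row(2, FALSE, "activating"))
  out <- consensus_frs(fr)
  expect_identical(nrow(out), 1L)
  expect_identical(out$direction, "activating")
  expect_identical(out$supporting_methods, "1,3")
  # direction disagreement between the supporting methods: rejected
  fr <- rbind(fr_row(3, TRUE, "activating"), fr_row(1, TRUE, "dampening"))
  expect_identical(nrow(consensus_frs(fr)), 0L)
  # invariance to input row order
  fr <- rbind(fr_row(1, TRUE, "activating"), fr_row(3, TRUE, "activating"))
  expect_identical(consensus_frs(fr), consensus_frs(fr[2:1, ]))

  # duplicate coordinates under different PWMs: lowest temporal FDR wins
  fr <- rbind(fr_row(3, TRUE, "activating", fdr = 0.01, iid = "R1|M1|10-20"),
              fr_row(1, TRUE, "activating", fdr = 0.01, iid = "R1|M1|10-20"),
              fr_row(3, TRUE, "activating", fdr = 0.001, iid = "R1|M2|10-20"),
              fr_row(1, TRUE, "activating", fdr = 0.001, iid = "R1|M2|10-20"))
  fr$motif <- sub(".*\\|(M\\d)\\|.*", "\\1", fr$instance_id)
  out <- consensus_frs(fr)
  expect_identical(nrow(out), 1L)
  expect_identical(out$motif, "M2")
})

test_that("sub-categorization follows the printed control-similarity clauses", {
  # essential: perturbed sequence indistinguishable from controls over time
  tt <- fake_tests(base_instance(fdr_temporal_ps = 0.5, n_mad_pert = 3L))
  frs <- data.frame(instance_id = "R1|M1|10-20", region = "R1", motif = "M1",
                    windows = "10-20", direction = "activating",
                    supporting_methods = "1,3", min_temporal_fdr = 0.001,
                    stringsAsFactors = FALSE)
  expect_identical(categorize(frs, tt)$sub_category, "essential")
  # ... or never beats the null at any timepoint
  tt <- fake_tests(base_instance(fdr_temporal_ps = 0.001, n_mad_pert = 0L))
  expect_identical(categorize(frs, tt)$sub_category, "essential")
  # both clauses false: contributing
  tt <- fake_tests(base_instance(fdr_temporal_ps = 0.001, n_mad_pert = 3L))
  expect_identical(categorize(frs, tt)$sub_category, "contributing")
  # under the AND reading the single-clause cases flip to contributing
  tt <- fake_tests(base_instance(fdr_temporal_ps = 0.5, n_mad_pert = 3L))
  expect_identical(categorize(frs, tt, clause = "and")$sub_category,
                   "contributing")

  # dampening: silencing when the wild type never leaves the control band
  frs$direction <- "dampening"
  tt <- fake_tests(base_instance(lfc = 1, fdr_temporal_ws = 0.5))
  expect_identical(categorize(frs, tt)$sub_category, "silencing")
  tt <- fake_tests(base_instance(lfc = 1, fdr_temporal_ws = 0.001,
                                 n_mad_wt = 7L))
  expect_identical(categorize(frs, tt)$sub_category, "inhibiting")
})

test_that("lowering the FDR threshold never grows the filtered set", {
  set.seed(33)
  insts <- do.call(rbind, lapply(1:12, function(i) {
    base_instance(instance_id = sprintf("R%d|M1|10-20", i),
                  region = sprintf("R%d", i),
                  n_sig_tp = sample(0:7, 1),
                  fdr_temporal_pw = runif(1, 0, 0.2),
                  fdr_temporal_ps = runif(1, 0, 0.2),
                  n_mad_pert = sample(0:7, 1), n_mad_wt = sample(0:7, 1),
                  fdr_temporal_ws = runif(1, 0, 0.2))
  }))
  tt <- fake_tests(insts)
  loose <- apply_filters(tt, fdr = 0.1)
  strict <- apply_filters(tt, fdr = 0.02)
  expect_true(all(strict$instance_id[strict$pass] %in%
                    loose$instance_id[loose$pass]))
})

test_that("activation dynamics fits are exact on linear input and recover noisy slopes", {
  wt <- c(0.4, 0.8, 1.4, 2.2, 3.1, 4.4, 5.0)
  pert <- wt - (0.2 + 0.5 * wt)
  d <- fit_dynamics(wt, pert)
  expect_equal(d$a, 0.2)
  expect_equal(d$b, 0.5)
  expect_equal(d$r_squared, 1)
  expect_error(fit_dynamics(wt[1:2], pert[1:2]), "at least 3")

  set.seed(14)
  hits <- 0
  for (k in 1:40) {
    delta <- 0.3 + 0.4 * wt + rnorm(7, 0, 0.05)
    dd <- fit_dynamics(wt, wt - delta)
    se <- summary(dd$fit)$coefficients["wt_alpha", "Std. Error"]
    hits <- hits + (abs(dd$b - 0.4) <= 2 * se)
  }
  # with 5 residual df the 2-SE band covers ~90% (t distribution), so the
  # empirical coverage over 40 fits should clear 0.8
  expect_gte(hits / 40, 0.8)
})
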