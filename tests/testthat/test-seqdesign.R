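test_that("site perturbation substitutes exactly the hit window", {
  region <- paste(rep(c("A", "C", "G", "T"), 10), collapse = "")
  nonmotif <- c("GGGGGGGGGGGG", "TTTTTTTTTTTT")
  hit <- data.frame(start = 8L, end = 16L, strand = "+")
  out <- perturb_site(region, hit, 1, nonmotif)
  expect_identical(substr(out, 9, 16), "GGGGGGGG")     # prefix, length-matched
  expect_identical(substr(out, 1, 8), substr(region, 1, 8))
  expect_identical(substr(out, 17, 40), substr(region, 17, 40))

  # minus strand: reverse complement of the prefix lands on the + strand
  hitm <- data.frame(start = 8L, end = 16L, strand = "-")
  outm <- perturb_site(region, hitm, 1, nonmotif)
  expect_identical(substr(outm, 9, 16), "CCCCCCCC")

  # methods 1 and 2 differ exactly when the two prefixes differ
  out2 <- perturb_site(region, hit, 2, nonmotif)
  expect_false(out2 == out)
  expect_identical(substr(out2, 9, 16), "TTTTTTTT")

  expect_error(perturb_site(region, hit, 4, nonmotif), "method")
})

test_that("window shuffling conserves the multiset and avoids the identity", {
  region <- paste(rep("A", 30), collapse = "")
  substr(region, 11, 14) <- "ACGT"
  hit <- data.frame(start = 10L, end = 14L, strand = "+")
  for (seed in 1:20) {
    out <- perturb_site(region, hit, 3, seed = seed)
    win <- substr(out, 11, 14)
    expect_identical(sort(strsplit(win, "")[[1]]), c("A", "C", "G", "T"))
    expect_false(win == "ACGT")
    expect_identical(substr(out, 1, 10), substr(region, 1, 10))
    expect_identical(substr(out, 15, 30), substr(region, 15, 30))
  }
})

test_that("library construction follows the per-region and per-instance counting rules", {
  set.seed(3)
  regions <- c("rA", "rB")
  seqs <- stats::setNames(random_dna(2, 171), regions)
  hits <- data.frame(
    region_id = c("rA", "rA", "rB"), motif_id = c("m1", "m2", "m1"),
    start = c(10L, 40L, 60L), end = c(20L, 52L, 70L),
    strand = c("+", "+", "-"), pvalue = 1e-6)
  g <- tripartite_graph(regions, c("m1", "m2"),
                        instances = data.frame(
                          motif = c("m1", "m2", "m1"),
                          region = c("rA", "rA", "rB"),
                          low_confidence = FALSE), tb_min = 1L)
  sel <- perturbMPRA:::new_selection(g, c(TRUE, TRUE), c(TRUE, TRUE),
                                     NA_real_, "manual")
  cfg <- sim_config(n_regions = 2, n_motifs = 2, n_properties = 0, seed = 2)
  nonmotif <- c(paste(rep("G", 12), collapse = ""),
                paste(rep("T", 12), collapse = ""))
  man <- build_library(sel, seqs, hits, nonmotif, cfg)
  # 2 x (1 WT + 1 SCRAM + 3 RAND) + 3 instances x 3 methods = 19
  expect_identical(nrow(man), 19L)
  expect_true(all(nchar(man$sequence) == 171))

  # SCRAM conserves base composition
  for (r in regions) {
    wt <- man$sequence[man$seq_id == paste0("WT|", r)]
    sc <- man$sequence[man$seq_id == paste0("SCRAM|", r)]
    expect_identical(sort(strsplit(wt, "")[[1]]), sort(strsplit(sc, "")[[1]]))
  }

  # RAND differs from WT only inside one 12-bp window
  wt <- man$sequence[man$seq_id == "WT|rA"]
  for (m in 1:3) {
    rnd <- man[man$seq_id == sprintf("RAND|m%d|rA", m), ]
    w <- as.integer(strsplit(rnd$windows, "-")[[1]])
    expect_identical(w[2] - w[1], 12L)
    diff_pos <- which(strsplit(rnd$sequence, "")[[1]] != strsplit(wt, "")[[1]])
    expect_true(all(diff_pos > w[1] & diff_pos <= w[2]))
  }

  # PERT differs from WT exactly within the declared hit window
  p1 <- man[man$category == "PERT" & man$method == 1 &
              man$instance_id == "rA|m1|10-20", ]
  diff_pos <- which(strsplit(p1$sequence, "")[[1]] != strsplit(wt, "")[[1]])
  expect_true(all(diff_pos > 10 & diff_pos <= 20))
  expect_gt(length(diff_pos), 0)

  # a missing hit for a selected instance raises an error naming it
  bad_sel <- perturbMPRA:::new_selection(g, c(TRUE, TRUE), c(TRUE, TRUE),
                                         NA_real_, "manual")
  expect_error(build_library(bad_sel, seqs, hits[-3, ], nonmotif, cfg),
               "rB")
})

test_that("multi-hit instances follow the hit2/hit2diff/discard rules", {
  set.seed(4)
  seqs <- c(rA = random_dna(1, 171))
  g <- tripartite_graph("rA", "m1",
                        instances = data.frame(motif = "m1", region = "rA",
                                               low_confidence = FALSE),
                        tb_min = 1L)
  sel <- perturbMPRA:::new_selection(g, TRUE, TRUE, NA_real_, "manual")
  cfg <- sim_config(n_regions = 1, n_motifs = 1, n_properties = 0, seed = 2)
  nonmotif <- c(paste(rep("G", 12), collapse = ""),
                paste(rep("T", 12), collapse = ""))

  # duplicated +/- pair at identical coordinates: one perturbation, + strand
  hits2 <- data.frame(region_id = "rA", motif_id = "m1",
                      start = c(30L, 30L), end = c(40L, 40L),
                      strand = c("+", "-"), pvalue = 1e-6)
  man2 <- build_library(sel, seqs, hits2, nonmotif, cfg)
  pert <- man2[man2$category == "PERT", ]
  expect_identical(nrow(pert), 3L)
  expect_true(all(pert$design_class == "hit2"))

  # two distinct hits: each single plus the joint perturbation
  hits2d <- data.frame(region_id = "rA", motif_id = "m1",
                       start = c(30L, 80L), end = c(40L, 90L),
                       strand = c("+", "+"), pvalue = 1e-6)
  man2d <- build_library(sel, seqs, hits2d, nonmotif, cfg)
  pert2d <- man2d[man2d$category == "PERT", ]
  expect_identical(nrow(pert2d), 9L)
  expect_true(all(pert2d$design_class == "hit2diff"))
  joint <- pert2d[grepl("+", pert2d$instance_id, fixed = TRUE), ]
  expect_identical(nrow(joint), 3L)

  # three or more hits of the same motif: discarded and logged
  hits3 <- data.frame(region_id = "rA", motif_id = "m1",
                      start = c(10L, 60L, 110L), end = c(20L, 70L, 120L),
                      strand = "+", pvalue = 1e-6)
  man3 <- build_library(sel, seqs, hits3, nonmotif, cfg)
  expect_identical(sum(man3$category == "PERT"), 0L)
  expect_identical(attr(man3, "discarded"), "rA|m1")
})

test_that("non-motif derivation matches an independent re-ranking oracle", {
  set.seed(11)
  pwms <- random_pwms(paste0("M", 1:4), width_range = c(8, 8), seed = 14)
  background <- random_dna(6, 171)
  sequences <- stats::setNames(random_dna(3, 171), c("r1", "r2", "r3"))
  contexts <- data.frame(region_id = c("r1", "r2", "r3"),
                         start = c(20L, 60L, 100L), end = c(30L, 70L, 110L))
  scanner <- make_pwm_scanner(pwms)
  res <- derive_nonmotif_sequences(background, scanner, max_width = 12,
                                   contexts = contexts, sequences = sequences,
                                   n_candidates = 120, seed = 7)
  expect_identical(nchar(res$sequences), c(12L, 12L))

  # oracle: rescore every candidate with direct full-sequence scans
  h1 <- h2 <- numeric(length(res$candidates))
  for (ci in seq_len(nrow(res$contexts))) {
    cx <- res$contexts[ci, ]
    reg <- sequences[[cx$region_id]]
    len <- cx$end - cx$start
    for (k in seq_along(res$candidates)) {
      emb1 <- paste0(substr(reg, cx$start - 2, cx$start),
                     substr(res$candidates[k], 1, len),
                     substr(reg, cx$end + 1, cx$end + 3))
      h1[k] <- h1[k] + nrow(scan_pwm(c(x = emb1), pwms, pval = 1e-4))
      full <- reg
      substr(full, cx$start + 1, cx$end) <- substr(res$candidates[k], 1, len)
      hits <- scan_pwm(c(x = full), pwms, pval = 1e-4)
      h2[k] <- h2[k] + sum(hits$start < cx$end & hits$end > cx$start)
    }
  }
  med_rank <- (rank(h1, ties.method = "min") + rank(h2, ties.method = "min")) / 2
  oracle_top2 <- order(med_rank, seq_along(med_rank))[1:2]
  expect_identical(res$selected, oracle_top2)

  # a candidate with zero hits always outranks one with hits
  zero <- which(res$hit_counts$flank_hits + res$hit_counts$context_hits == 0)
  nonzero <- which(res$hit_counts$flank_hits + res$hit_counts$context_hits > 0)
  if (length(zero) && length(nonzero)) {
    expect_lt(max(res$ranks[zero]), min(res$ranks[nonzero]) + 1e-9)
  }
})

test_that("degenerate poly-A background yields poly-A candidates", {
  pwms <- random_pwms("M1", width_range = c(8, 8), seed = 5)
  background <- rep(paste(rep("A", 50), collapse = ""), 3)
  sequences <- c(r1 = paste(rep("A", 60), collapse = ""))
  contexts <- data.frame(region_id = "r1", start = 20L, end = 30L)
  res <- derive_nonmotif_sequences(background, make_pwm_scanner(pwms),
                                   max_width = 10, contexts = contexts,
                                   sequences = sequences, n_candidates = 10,
                                   seed = 3)
  expect_true(all(res$candidates == paste(rep("A", 10), collapse = "")))
})
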