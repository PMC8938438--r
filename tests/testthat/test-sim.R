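test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_regions = 0), "n_regions")
  expect_error(sim_config(rna_dispersion = 0), "rna_dispersion")
  expect_error(sim_config(region_length = 15, motif_width_range = c(10, 12)))
  cfg <- sim_config()
  expect_identical(cfg$region_length, 171L)
  expect_identical(cfg$barcode_length, 15L)
  expect_identical(cfg$n_timepoints, 7L)
  expect_identical(cfg$n_replicates, 3L)
})

test_that("generated sequences have full region length with planted hits", {
  cfg <- sim_config(n_regions = 15, n_motifs = 12, n_properties = 0,
                    mean_degree_high = 3, seed = 6)
  g <- generate_graph(cfg)
  seqs <- generate_sequences(g, cfg)
  expect_true(all(nchar(seqs$sequences) == 171))
  expect_setequal(names(seqs$sequences), g$regions)
  h <- seqs$hits
  expect_true(all(h$end - h$start >= 8 & h$end - h$start <= 12))
  expect_true(all(h$start >= 0 & h$end <= 171))
  # every instance edge is realized as at least one hit
  expect_true(all(paste(g$instances$motif, g$instances$region) %in%
                    paste(h$motif_id, h$region_id)))
  # planted strand semantics: minus-strand hits carry the reverse complement
  minus <- h[h$strand == "-", ][1, ]
  cons <- seqs$pwms[[minus$motif_id]]$consensus
  window <- substr(seqs$sequences[[minus$region_id]], minus$start + 1,
                   minus$end)
  expect_identical(window, revcomp(cons))
  plus <- h[h$strand == "+", ][1, ]
  expect_identical(substr(seqs$sequences[[plus$region_id]], plus$start + 1,
                          plus$end),
                   seqs$pwms[[plus$motif_id]]$consensus)
})

test_that("rescanning generated sequences recovers planted hits", {
  cfg <- sim_config(n_regions = 15, n_motifs = 12, n_properties = 0,
                    mean_degree_high = 3, seed = 6)
  g <- generate_graph(cfg)
  seqs <- generate_sequences(g, cfg)
  found <- scan_pwm(seqs$sequences, seqs$pwms, pval = 1e-4)
  key_found <- paste(found$region_id, found$motif_id, found$start, found$end)
  key_planted <- with(seqs$hits, paste(region_id, motif_id, start, end))
  expect_gte(mean(key_planted %in% key_found), 0.95)
})

test_that("count simulation is deterministic and preserves the NB mean-variance excess", {
  cfg <- sim_config(n_regions = 12, n_motifs = 12, barcodes_per_sequence = 30,
                    seed = 21)
  man <- scenario_manifest(12, methods = 3)
  truth <- generate_truth(manifest_instances(man), cfg)
  lib <- assign_sim_barcodes(man, cfg)
  c1 <- simulate_counts(truth, lib, cfg)
  c2 <- simulate_counts(truth, lib, cfg)
  expect_identical(c1$dna, c2$dna)
  expect_identical(c1$rna, c2$rna)
  expect_true(all(nchar(lib$barcodes$barcode) == 15))
  expect_false(anyDuplicated(lib$barcodes$barcode) > 0)

  # overdispersion: within one (sequence, sample) stratum, scaled by latent
  sub <- c1[c1$timepoint == "t4" & c1$replicate == "rep1", ]
  wt <- sub[grepl("^WT", sub$sequence_id), ]
  expect_gt(nrow(wt), 300)          # >= 1000 simulated barcodes overall
  ratio <- wt$rna / pmax(wt$dna, 1)
  expect_gt(stats::var(wt$rna), mean(wt$rna))
})

test_that("planted truth respects the category-direction invariants", {
  cfg <- sim_config(n_regions = 40, n_motifs = 12, seed = 12)
  man <- scenario_manifest(40, methods = 3)
  truth <- generate_truth(manifest_instances(man), cfg)
  inst <- truth$instances
  expect_true(all(inst$direction[inst$sub_category %in%
                                   c("essential", "contributing")] == "activating"))
  expect_true(all(inst$direction[inst$sub_category %in%
                                   c("silencing", "inhibiting")] == "dampening"))
  null_rows <- inst$sub_category == "none"
  expect_true(all(truth$effects[null_rows, ] == 0))
  expect_true(all(truth$effects[inst$direction == "activating", ] <= 0))
  expect_true(all(truth$effects[inst$direction == "dampening", ] >= 0))
  # silencing instances live in blocked regions
  blk <- truth$regions$region[truth$regions$archetype == "blocked"]
  expect_true(all(inst$region[inst$sub_category == "silencing"] %in% blk))
})

test_that("association reads expose the planted ambiguity classes", {
  cfg <- sim_config(n_regions = 12, n_motifs = 12, barcodes_per_sequence = 20,
                    ambiguous_fraction = 0, shallow_fraction = 0, seed = 31)
  man <- scenario_manifest(12, methods = 3)
  lib <- assign_sim_barcodes(man, cfg)
  reads <- simulate_association_reads(lib, cfg)
  asg <- assign_barcodes(reads)
  expect_equal(unname(attr(asg, "summary")["frac_assigned"]), 1.0)

  # a shallow barcode (2 UMIs) and a 70% majority barcode are both dropped
  tab <- data.frame(barcode = c("b1", "b2", "b2"),
                    sequence_id = c("sA", "sA", "sB"),
                    umi_count = c(2, 7, 3))
  a <- assign_barcodes(tab)
  expect_identical(a$status[a$barcode == "b1"], "ambiguous")
  expect_identical(a$status[a$barcode == "b2"], "ambiguous")
  expect_equal(a$majority_fraction[a$barcode == "b2"], 0.7)
})
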