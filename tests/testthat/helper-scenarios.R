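# Hand-built library manifests and count scenarios used across test files.

# one WT + SCRAM per region, one single-site instance perturbed by `methods`
scenario_manifest <- function(n_regions, methods = 1:3) {
  regions <- sprintf("R%03d", seq_len(n_regions))
  rows <- list()
  for (r in regions) {
    rows[[length(rows) + 1]] <- data.frame(
      seq_id = paste0("WT|", r), category = "WT", method = NA_integer_,
      region = r, instance_id = NA_character_, pair_id = NA_character_)
    rows[[length(rows) + 1]] <- data.frame(
      seq_id = paste0("SCRAM|", r), category = "SCRAM", method = NA_integer_,
      region = r, instance_id = NA_character_, pair_id = NA_character_)
    iid <- sprintf("%s|M001|10-20", r)
    for (m in methods) {
      rows[[length(rows) + 1]] <- data.frame(
        seq_id = sprintf("PERT|%s|m%d", iid, m), category = "PERT",
        method = m, region = r, instance_id = iid, pair_id = NA_character_)
    }
  }
  do.call(rbind, rows)
}

manifest_instances <- function(man) {
  keep <- man$category == "PERT" & !grepl("+", man$instance_id, fixed = TRUE)
  unique(data.frame(
    instance_id = man$instance_id[keep], region = man$region[keep],
    motif = vapply(strsplit(man$instance_id[keep], "|", fixed = TRUE),
                   `[`, "", 2),
    stringsAsFactors = FALSE))
}

# WT + three PERT variants (two singles and the double) per pair region
pair_bank_manifest <- function(n_pairs, interacting, methods = 1:3) {
  regions <- sprintf("R%03d", seq_len(n_pairs))
  rows <- list(); pairs <- list()
  for (i in seq_len(n_pairs)) {
    r <- regions[i]
    i1 <- sprintf("%s|M001|10-20", r); i2 <- sprintf("%s|M002|40-50", r)
    rows[[length(rows) + 1]] <- data.frame(
      seq_id = paste0("WT|", r), category = "WT", method = NA_integer_,
      region = r, instance_id = NA_character_, pair_id = NA_character_)
    for (m in methods) {
      for (iid in c(i1, i2)) {
        rows[[length(rows) + 1]] <- data.frame(
          seq_id = sprintf("PERT|%s|m%d", iid, m), category = "PERT",
          method = m, region = r, instance_id = iid, pair_id = NA_character_)
      }
      rows[[length(rows) + 1]] <- data.frame(
        seq_id = sprintf("DBL|p%03d|m%d", i, m), category = "DBL", method = m,
        region = r, instance_id = paste(i1, i2, sep = "&"),
        pair_id = sprintf("p%03d", i))
    }
    pairs[[i]] <- data.frame(pair_id = sprintf("p%03d", i), region = r,
                             instance1 = i1, instance2 = i2,
                             interacting = interacting[i],
                             stringsAsFactors = FALSE)
  }
  list(manifest = do.call(rbind, rows), pairs = do.call(rbind, pairs))
}

# run interaction tests over a pair bank for the given methods
bank_pair_tests <- function(counts, man, pairs, sf, methods = 1:3) {
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    for (m in methods) {
      dbl <- man[man$category == "DBL" & man$pair_id == pairs$pair_id[k] &
                   man$method == m, ]
      s1 <- man[man$category == "PERT" &
                  man$instance_id == pairs$instance1[k] & man$method == m, ]
      s2 <- man[man$category == "PERT" &
                  man$instance_id == pairs$instance2[k] & man$method == m, ]
      wt <- man[man$category == "WT" & man$region == pairs$region[k], ]
      sub <- counts[counts$sequence_id %in%
                      c(wt$seq_id, s1$seq_id, s2$seq_id, dbl$seq_id), ]
      sub$pert1 <- sub$sequence_id %in% c(s1$seq_id, dbl$seq_id)
      sub$pert2 <- sub$sequence_id %in% c(s2$seq_id, dbl$seq_id)
      ti <- test_interaction(sub, sf = sf)
      rows[[length(rows) + 1]] <- data.frame(
        pair_id = pairs$pair_id[k], region = pairs$region[k],
        instance1 = pairs$instance1[k], instance2 = pairs$instance2[k],
        windows1 = "10-20", windows2 = "40-50", method = m,
        gamma = ti$gamma, pvalue = ti$pvalue, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# simulate a null pair (log-additive effects) from the count model directly
simulate_additive_pair <- function(nbc = 30, effects = c(-0.7, -0.4),
                                   dispersion = 0.1) {
  eff <- c(WT = 0, P1 = effects[1], P2 = effects[2], P12 = sum(effects))
  base <- exp(seq(0.3, 1.3, length.out = 7)) * 0.4
  df <- expand.grid(barcode = sprintf("b%02d", seq_len(nbc)),
                    sequence_id = names(eff),
                    timepoint = paste0("t", 1:7),
                    replicate = paste0("rep", 1:3), stringsAsFactors = FALSE)
  df$barcode <- paste(df$sequence_id, df$barcode)
  lam_bc <- round(rgamma(4 * nbc, 4, scale = 25 * exp(rnorm(4 * nbc, 0, 0.3)))) + 1
  names(lam_bc) <- unique(df$barcode)
  lam <- lam_bc[df$barcode]
  df$dna <- rpois(nrow(df), lam)
  mu <- base[as.integer(substr(df$timepoint, 2, 2))] *
    exp(eff[df$sequence_id]) * lam
  df$rna <- rnbinom(nrow(df), mu = mu, size = 1 / dispersion)
  df <- df[df$dna > 0 & df$rna > 0, ]
  df$pert1 <- df$sequence_id %in% c("P1", "P12")
  df$pert2 <- df$sequence_id %in% c("P2", "P12")
  df
}

# small random tripartite toys for the enumeration-vs-solver equivalence
random_toy_graph <- function(seed) {
  set.seed(seed)
  nR <- sample(2:4, 1); nT <- sample(2:3, 1)
  regions <- paste0("r", seq_len(nR)); motifs <- paste0("t", seq_len(nT))
  edges <- expand.grid(motif = motifs, region = regions,
                       stringsAsFactors = FALSE)
  edges <- edges[runif(nrow(edges)) < 0.7, ]
  if (!nrow(edges)) edges <- data.frame(motif = motifs[1], region = regions[1])
  edges$low_confidence <- runif(nrow(edges)) < 0.2
  hp <- if (runif(1) < 0.5) motifs[1] else character()
  tripartite_graph(regions, motifs, instances = edges, hand_picked = hp,
                   tb_min = 1L)
}
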