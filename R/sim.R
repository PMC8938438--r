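#' Simulation configuration for the synthetic perturbation-MPRA study
#'
#' Collects every tunable of the synthetic-data generator: graph dimensions,
#' construct geometry (171-bp regions, 15-bp barcodes), the assay layout
#' (seven timepoints at 0-72 h of differentiation, three replicates), the
#' count model (gamma DNA counts, negative-binomial RNA counts), and the
#' planted-effect grid per category. Temporal profiles of planted effects are
#' drawn from a small basis (flat, early-peak, late-peak, transient).
#'
#' @param n_regions,n_motifs,n_properties layer sizes of the design graph.
#' @param region_length construct length in bp.
#' @param barcode_length barcode length in nt.
#' @param timepoints numeric vector of timepoint labels (hours).
#' @param n_replicates biological replicates per timepoint.
#' @param barcodes_per_sequence barcodes assigned to each designed sequence.
#' @param dna_shape,dna_scale gamma parameters of per-barcode DNA counts.
#' @param rna_dispersion negative-binomial dispersion (1/size) of RNA counts.
#' @param scram_alpha baseline transcription rate of scrambled controls.
#' @param activity_range log-scale peak activity of active regions over
#'   baseline (uniform draw).
#' @param effect_grid list with `contributing` and `inhibiting` log-effect
#'   ranges; essential/silencing effects are tied to the region amplitude.
#' @param category_probs named probabilities for instance categories
#'   (essential, contributing, inhibiting, silencing, null).
#' @param motif_width_range motif widths (bp) of the planted PWMs.
#' @param frac_high_degree fraction of motifs given region-degree at least 5.
#' @param mean_degree_high mean extra region-degree of high-degree motifs.
#' @param lowconf_frac fraction of instance edges flagged low-confidence.
#' @param prop_motif_frac,prop_region_frac fraction of motifs/regions each
#'   property connects to (floored at the design bounds 12 and 17).
#' @param ambiguous_fraction,shallow_fraction fractions of association
#'   barcodes made ambiguous (majority below 80%) or shallow (under 3 UMIs).
#' @param umi_mean mean UMI count of a well-covered barcode.
#' @param rand_window width of the random-perturbation control window (bp).
#' @param seed master seed; every stage derives its own stream from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_regions = 30, n_motifs = 20, n_properties = 4,
                       region_length = 171L, barcode_length = 15L,
                       timepoints = c(0, 3, 6, 12, 24, 48, 72),
                       n_replicates = 3L, barcodes_per_sequence = 30L,
                       dna_shape = 4, dna_scale = 25, rna_dispersion = 0.1,
                       scram_alpha = 0.15, activity_range = c(1.5, 2.5),
                       effect_grid = list(contributing = c(0.8, 1.4),
                                          inhibiting = c(0.8, 1.4)),
                       category_probs = c(essential = 0.20, contributing = 0.35,
                                          inhibiting = 0.12, silencing = 0.08,
                                          null = 0.25),
                       motif_width_range = c(8L, 12L),
                       frac_high_degree = 0.8, mean_degree_high = 19,
                       lowconf_frac = 0.1,
                       prop_motif_frac = 0.025, prop_region_frac = 0.04,
                       ambiguous_fraction = 0.1, shallow_fraction = 0.05,
                       umi_mean = 8, rand_window = 12L, seed = 1L) {
  cfg <- as.list(environment())
  cfg$n_timepoints <- length(timepoints)
  stopifnot(n_regions >= 1, n_motifs >= 1, n_properties >= 0,
            n_replicates >= 1, barcodes_per_sequence >= 1,
            rna_dispersion > 0, dna_shape > 0, dna_scale > 0,
            region_length >= motif_width_range[2] + 6,
            barcode_length >= 1, cfg$n_timepoints >= 1)
  cfg$category_probs <- category_probs / sum(category_probs)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("Simulation config: %d regions x %d motifs x %d properties; ",
                     "%d bp constructs, %d nt barcodes, %d timepoints x %d replicates, ",
                     "%d barcodes/sequence; seed %d\n"),
              x$n_regions, x$n_motifs, x$n_properties, x$region_length,
              x$barcode_length, x$n_timepoints, x$n_replicates,
              x$barcodes_per_sequence, x$seed))
  invisible(x)
}

#' Generate a feasible synthetic tripartite design graph
#'
#' Constructs a region/motif/property graph that is feasible by construction
#' for the selection ILP: TF groups hold at most two motifs, every property
#' connects to at least 12 motifs and at least `min(17, n_regions)` regions,
#' at least `frac_high_degree` of motifs reach region-degree 5, and the
#' low-confidence edge share stays well under the selectable budget, so the
#' all-nodes selection satisfies every constraint family. Parameter
#' combinations that violate a design bound raise an error naming the bound.
#'
#' @param config a [sim_config()].
#' @return A [tripartite_graph()].
#' @export
generate_graph <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_properties > 0 && config$n_motifs < 12) {
    stop("infeasible: property coverage bound requires >= 12 motifs, got ",
         config$n_motifs)
  }
  with_seed(substream_seed(config$seed, "graph"), {
    regions <- sprintf("R%04d", seq_len(config$n_regions))
    motifs <- sprintf("M%04d", seq_len(config$n_motifs))
    properties <- if (config$n_properties > 0) {
      sprintf("P%02d", seq_len(config$n_properties))
    } else character()

    n_high <- max(1L, round(config$frac_high_degree * config$n_motifs))
    is_high <- seq_len(config$n_motifs) <= n_high
    deg <- ifelse(is_high,
                  pmin(config$n_regions,
                       5L + stats::rpois(config$n_motifs, config$mean_degree_high)),
                  sample(1:4, config$n_motifs, replace = TRUE))
    deg <- pmin(deg, config$n_regions)
    inst <- do.call(rbind, lapply(seq_len(config$n_motifs), function(i) {
      data.frame(motif = motifs[i],
                 region = sample(regions, deg[i]),
                 stringsAsFactors = FALSE)
    }))
    # top up regions left without any candidate motif instance
    missing <- setdiff(regions, inst$region)
    if (length(missing)) {
      inst <- rbind(inst, data.frame(motif = sample(motifs[is_high],
                                                    length(missing),
                                                    replace = TRUE),
                                     region = missing))
      inst <- unique(inst)
    }
    inst$low_confidence <- stats::runif(nrow(inst)) < config$lowconf_frac

    motif_props <- region_props <- NULL
    if (length(properties)) {
      n_pm <- min(config$n_motifs,
                  max(12L, round(config$prop_motif_frac * config$n_motifs)))
      n_pr <- min(config$n_regions,
                  max(17L, round(config$prop_region_frac * config$n_regions)))
      motif_props <- do.call(rbind, lapply(properties, function(p) {
        data.frame(motif = sample(motifs, n_pm), property = p,
                   stringsAsFactors = FALSE)
      }))
      region_props <- do.call(rbind, lapply(properties, function(p) {
        data.frame(region = sample(regions, n_pr), property = p,
                   stringsAsFactors = FALSE)
      }))
    } else {
      motif_props <- data.frame(motif = character(), property = character())
      region_props <- data.frame(region = character(), property = character())
    }

    # TF groups of size <= 2 so that selecting every motif stays feasible
    n_pairs <- floor(0.2 * config$n_motifs / 2)
    grp <- character(config$n_motifs)
    if (n_pairs > 0) {
      paired <- sample(config$n_motifs, 2 * n_pairs)
      grp[paired] <- rep(sprintf("TF_p%03d", seq_len(n_pairs)), each = 2)
    }
    singles <- which(grp == "")
    grp[singles] <- sprintf("TF_s%04d", seq_along(singles))
    tf_group <- stats::setNames(grp, motifs)
    groups <- unique(grp)
    hand_picked <- sample(groups, min(3L, length(groups)))

    tripartite_graph(regions, motifs, properties, inst,
                     motif_props, region_props, tf_group, hand_picked)
  })
}

basis_profile <- function(kind, timepoints) {
  n <- length(timepoints)
  x <- seq(0, 1, length.out = n)
  switch(kind,
         flat = rep(1, n),
         early = 1 - x * 0.8,
         late = 0.2 + x * 0.8,
         transient = 0.2 + 0.8 * exp(-((x - 0.5) / 0.25)^2))
}

TEMPORAL_BASIS <- c("flat", "early", "late", "transient")

#' Generate region sequences with planted motif hits
#'
#' One random sequence of `region_length` bp per region; every motif-region
#' edge of the graph is realized by planting the motif's PWM consensus at a
#' (preferably non-overlapping) position on a random strand. Hit coordinates
#' are 0-based half-open; on the minus strand the reverse complement of the
#' consensus is inserted on the forward strand.
#'
#' @param graph a [tripartite_graph()].
#' @param config a [sim_config()].
#' @return list with `sequences` (named character), `hits` (data.frame
#'   `region_id`, `motif_id`, `start`, `end`, `strand`, `pvalue`) and `pwms`.
#' @export
generate_sequences <- function(graph, config) {
  pwms <- random_pwms(graph$motifs, config$motif_width_range,
                      seed = substream_seed(config$seed, "pwms"))
  wmax <- max(vapply(pwms, function(p) p$width, integer(1)))
  if (wmax > config$region_length) {
    stop("motif width ", wmax, " exceeds region length ", config$region_length)
  }
  with_seed(substream_seed(config$seed, "sequences"), {
    seqs <- stats::setNames(random_dna(length(graph$regions),
                                       config$region_length), graph$regions)
    hits <- vector("list", nrow(graph$instances))
    occupied <- stats::setNames(vector("list", length(graph$regions)),
                                graph$regions)
    ord <- sample(nrow(graph$instances))   # placement order independent of id
    for (k in ord) {
      r <- graph$instances$region[k]; m <- graph$instances$motif[k]
      pw <- pwms[[m]]
      strand <- sample(c("+", "-"), 1)
      starts <- sample(0:(config$region_length - pw$width))
      occ <- occupied[[r]]
      pick <- NA_integer_
      for (s in starts) {
        clash <- length(occ) && any(s < occ[, 2] & s + pw$width > occ[, 1])
        if (!clash) { pick <- s; break }
      }
      if (is.na(pick)) pick <- starts[1]   # dense region: overlap allowed
      ins <- if (strand == "+") pw$consensus else revcomp(pw$consensus)
      substr(seqs[[r]], pick + 1, pick + pw$width) <- ins
      occupied[[r]] <- rbind(occ, c(pick, pick + pw$width))
      cons_score <- sum(apply(pw$lo, 2, max))
      hits[[k]] <- data.frame(region_id = r, motif_id = m, start = pick,
                              end = pick + pw$width, strand = strand,
                              pvalue = pw$null(cons_score),
                              stringsAsFactors = FALSE)
    }
    hits <- do.call(rbind, hits)
    hits <- hits[order(hits$region_id, hits$start, hits$motif_id), ]
    rownames(hits) <- NULL
    list(sequences = seqs, hits = hits, pwms = pwms)
  })
}

#' Plant ground-truth effects for a set of motif instances
#'
#' Assigns each region an activity archetype (active with a temporal profile
#' from the flat/early/late/transient basis, or blocked at the scrambled
#' baseline) and each motif instance a direction and sub-category consistent
#' with its region: essential and contributing activators and inhibiting
#' dampeners live in active regions; silencing dampeners require a blocked
#' region. Planted per-timepoint log effects are the shift of the perturbed
#' sequence's log transcription rate relative to wild type (negative for
#' activators). Optional pairs receive an interaction coefficient (0 for
#' additive pairs).
#'
#' @param instances data.frame with columns `instance_id`, `region`, `motif`.
#' @param config a [sim_config()].
#' @param pairs optional data.frame with columns `pair_id`, `region`,
#'   `instance1`, `instance2`, and optionally `interacting` (logical) to
#'   force the additive/non-additive split.
#' @return A list of class `ground_truth` with `regions`, `instances`,
#'   `effects` (instances x timepoints matrix of log effects) and `pairs`.
#' @export
generate_truth <- function(instances, config, pairs = NULL) {
  stopifnot(all(c("instance_id", "region", "motif") %in% names(instances)))
  with_seed(substream_seed(config$seed, "truth"), {
    regions <- unique(instances$region)
    tp <- config$timepoints

    p <- config$category_probs
    p_blocked <- p[["silencing"]]
    blocked <- stats::runif(length(regions)) < p_blocked
    names(blocked) <- regions
    # regions enter the assay because they are temporally active, so active
    # regions draw a non-flat profile; blocked regions sit flat at baseline
    active_basis <- setdiff(TEMPORAL_BASIS, "flat")
    reg <- data.frame(
      region = regions,
      archetype = ifelse(blocked, "blocked", "active"),
      basis = ifelse(blocked, "flat",
                     sample(active_basis, length(regions), replace = TRUE)),
      amplitude = ifelse(blocked, 0,
                         stats::runif(length(regions), config$activity_range[1],
                                      config$activity_range[2])),
      stringsAsFactors = FALSE)

    n <- nrow(instances)
    cat_active <- p[c("essential", "contributing", "inhibiting", "null")]
    cat_active <- cat_active / sum(cat_active)
    sub <- character(n)
    for (i in seq_len(n)) {
      sub[i] <- if (blocked[[instances$region[i]]]) {
        sample(c("silencing", "none"), 1, prob = c(0.7, 0.3))
      } else {
        s <- sample(names(cat_active), 1, prob = cat_active)
        if (s == "null") "none" else s
      }
    }
    direction <- c(essential = "activating", contributing = "activating",
                   inhibiting = "dampening", silencing = "dampening",
                   none = "null")[sub]

    eff <- matrix(0, n, length(tp),
                  dimnames = list(instances$instance_id,
                                  paste0("t", seq_along(tp))))
    for (i in seq_len(n)) {
      ri <- reg[reg$region == instances$region[i], ]
      b <- basis_profile(ri$basis, tp)
      eff[i, ] <- switch(sub[i],
        essential = -ri$amplitude * b,
        contributing = {
          d <- stats::runif(1, config$effect_grid$contributing[1],
                            config$effect_grid$contributing[2])
          -pmin(d, 0.7 * ri$amplitude) * b
        },
        inhibiting = stats::runif(1, config$effect_grid$inhibiting[1],
                                  config$effect_grid$inhibiting[2]) * b,
        silencing = stats::runif(1, config$activity_range[1],
                                 config$activity_range[2]) *
          basis_profile(sample(active_basis, 1), tp),
        none = rep(0, length(tp)))
    }

    inst <- data.frame(instances[, c("instance_id", "region", "motif")],
                       direction = unname(direction),
                       sub_category = ifelse(sub == "none", "none", sub),
                       stringsAsFactors = FALSE)

    pair_truth <- NULL
    if (!is.null(pairs) && nrow(pairs)) {
      interacting <- if (!is.null(pairs$interacting)) {
        pairs$interacting
      } else stats::runif(nrow(pairs)) < 0.5
      gamma <- ifelse(interacting,
                      sample(c(-1, 1), nrow(pairs), replace = TRUE) *
                        stats::runif(nrow(pairs), 0.8, 1.5),
                      0)
      pair_truth <- data.frame(pairs[, c("pair_id", "region", "instance1",
                                         "instance2")],
                               gamma = gamma, stringsAsFactors = FALSE)
    }

    out <- list(regions = reg, instances = inst, effects = eff,
                pairs = pair_truth, config = config)
    class(out) <- "ground_truth"
    out
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Planted ground truth: %d regions (%d blocked), %d instances\n",
              nrow(x$regions), sum(x$regions$archetype == "blocked"),
              nrow(x$instances)))
  print(table(x$instances$sub_category))
  if (!is.null(x$pairs)) {
    cat(sprintf("pairs: %d (%d interacting)\n", nrow(x$pairs),
                sum(abs(x$pairs$gamma) > 0)))
  }
  invisible(x)
}

# True per-timepoint alpha for every library sequence, from region profiles
# and planted instance/pair effects.
true_alpha_matrix <- function(truth, manifest) {
  cfg <- truth$config
  tp <- cfg$timepoints
  reg <- truth$regions
  log_wt <- function(region) {
    ri <- reg[reg$region == region, ]
    log(cfg$scram_alpha) + ri$amplitude * basis_profile(ri$basis, tp)
  }
  eff <- truth$effects
  alpha <- matrix(NA_real_, nrow(manifest), length(tp),
                  dimnames = list(manifest$seq_id, paste0("t", seq_along(tp))))
  scram_jitter <- attr(truth, "scram_jitter") %||% 0
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    la <- switch(m$category,
      WT = log_wt(m$region),
      RAND = log_wt(m$region),
      SCRAM = rep(log(cfg$scram_alpha), length(tp)),
      PERT = log_wt(m$region) + eff[m$instance_id, ],
      DBL = {
        pr <- truth$pairs[truth$pairs$pair_id == m$pair_id, ]
        log_wt(m$region) + eff[pr$instance1, ] + eff[pr$instance2, ] + pr$gamma
      })
    alpha[i, ] <- exp(la)
  }
  alpha
}

#' Simulate barcode association reads
#'
#' Emits, per barcode of the library, the UMI-supported assignments an
#' association sequencing run would produce: most barcodes map cleanly to
#' their true sequence; a configurable fraction are made ambiguous (majority
#' fraction below 80%) or shallow (fewer than 3 UMIs).
#'
#' @param library a library manifest with barcode table, as produced by
#'   [assign_sim_barcodes()] (list with `manifest` and `barcodes`).
#' @param config a [sim_config()].
#' @return data.frame with columns `barcode`, `sequence_id`, `umi_count`.
#' @export
simulate_association_reads <- function(library, config) {
  bc <- library$barcodes
  with_seed(substream_seed(config$seed, "association"), {
    n <- nrow(bc)
    type <- sample(c("clean", "ambiguous", "shallow"), n, replace = TRUE,
                   prob = c(1 - config$ambiguous_fraction - config$shallow_fraction,
                            config$ambiguous_fraction, config$shallow_fraction))
    n1 <- 3L + stats::rpois(n, max(config$umi_mean - 3, 1))
    rows <- vector("list", n)
    other <- sample(unique(bc$sequence_id))
    for (i in seq_len(n)) {
      if (type[i] == "shallow") {
        rows[[i]] <- data.frame(barcode = bc$barcode[i],
                                sequence_id = bc$sequence_id[i],
                                umi_count = sample(1:2, 1))
      } else if (type[i] == "ambiguous") {
        n2 <- max(1L, ceiling(n1[i] * 0.4))  # majority <= 0.72 < 0.8
        alt <- other[other != bc$sequence_id[i]][1]
        rows[[i]] <- data.frame(barcode = bc$barcode[i],
                                sequence_id = c(bc$sequence_id[i], alt),
                                umi_count = c(n1[i], n2))
      } else {
        rows[[i]] <- data.frame(barcode = bc$barcode[i],
                                sequence_id = bc$sequence_id[i],
                                umi_count = n1[i])
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Attach random barcodes to a library manifest
#'
#' @param manifest library manifest data.frame (one row per sequence).
#' @param config a [sim_config()].
#' @return list with `manifest` and `barcodes` (data.frame `barcode`,
#'   `sequence_id`).
#' @export
assign_sim_barcodes <- function(manifest, config) {
  with_seed(substream_seed(config$seed, "barcodes"), {
    n <- nrow(manifest) * config$barcodes_per_sequence
    bcs <- unique(random_dna(ceiling(n * 1.05), config$barcode_length))
    while (length(bcs) < n) {
      bcs <- unique(c(bcs, random_dna(n, config$barcode_length)))
    }
    bcs <- bcs[seq_len(n)]
    list(manifest = manifest,
         barcodes = data.frame(
           barcode = bcs,
           sequence_id = rep(manifest$seq_id,
                             each = config$barcodes_per_sequence),
           stringsAsFactors = FALSE))
  })
}

#' Simulate DNA/RNA barcode counts with planted effects
#'
#' Each barcode carries a latent construct abundance drawn once from a
#' rounded gamma (integration copy number; a lognormal per-barcode factor
#' adds heterogeneity and makes the barcode covariate of the DNA model
#' informative). Observed DNA counts are Poisson draws around that latent
#' abundance per sample (sequencing counting noise); RNA counts are
#' negative-binomial with mean `alpha * latent abundance * size factor` —
#' transcription happens from the integrated construct, and the DNA reads
#' are a noisy measurement of it, matching the nested-GLM model downstream.
#' Alpha is the sequence's true per-timepoint transcription rate from the
#' planted truth (perturbed sequences scaled by their planted effect,
#' scrambled controls at a flat baseline). Fully seeded and reproducible.
#'
#' @param truth a [generate_truth()] result.
#' @param library list with `manifest` and `barcodes`
#'   (see [assign_sim_barcodes()]).
#' @param config a [sim_config()].
#' @return A count data.frame (class `mpra_counts`) with columns `barcode`,
#'   `sequence_id`, `timepoint`, `replicate`, `dna`, `rna`; true size factors
#'   are attached as attribute `sim_size_factors`.
#' @export
simulate_counts <- function(truth, library, config) {
  manifest <- library$manifest
  alpha <- true_alpha_matrix(truth, manifest)
  bc <- library$barcodes
  tp_lab <- paste0("t", seq_along(config$timepoints))
  with_seed(substream_seed(config$seed, "counts"), {
    sf <- exp(stats::rnorm(config$n_timepoints * config$n_replicates, 0, 0.15))
    sf_mat <- matrix(sf, config$n_timepoints, config$n_replicates,
                     dimnames = list(tp_lab, paste0("rep", seq_len(config$n_replicates))))
    bc_factor <- exp(stats::rnorm(nrow(bc), 0, 0.3))
    n_samp <- config$n_timepoints * config$n_replicates
    grid <- expand.grid(tp = seq_len(config$n_timepoints),
                        rep = seq_len(config$n_replicates))
    out <- vector("list", n_samp)
    seq_alpha_idx <- match(bc$sequence_id, manifest$seq_id)
    latent <- round(stats::rgamma(nrow(bc), shape = config$dna_shape,
                                  scale = config$dna_scale * bc_factor))
    for (s in seq_len(n_samp)) {
      t_i <- grid$tp[s]; r_i <- grid$rep[s]
      dna <- stats::rpois(nrow(bc), latent)
      mu <- alpha[cbind(seq_alpha_idx, t_i)] * latent * sf_mat[t_i, r_i]
      rna <- stats::rnbinom(nrow(bc), mu = mu, size = 1 / config$rna_dispersion)
      out[[s]] <- data.frame(barcode = bc$barcode,
                             sequence_id = bc$sequence_id,
                             timepoint = tp_lab[t_i],
                             replicate = paste0("rep", r_i),
                             dna = dna, rna = rna,
                             stringsAsFactors = FALSE)
    }
    counts <- do.call(rbind, out)
    rownames(counts) <- NULL
    attr(counts, "sim_size_factors") <- sf_mat
    class(counts) <- c("mpra_counts", "data.frame")
    counts
  })
}
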