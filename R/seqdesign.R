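#' Build a scanner closure from a PWM set
#'
#' The sequence-design operations take a scanner as a pluggable interface: a
#' function `f(seqs, ranges = NULL)` returning the number of motif hits per
#' sequence. This wraps the bundled PWM scanner; any scanner with the same
#' signature can be substituted.
#'
#' @param pwms list of [pwm()] objects.
#' @param pval hit p-value threshold.
#' @return A function `(seqs, ranges) -> named integer vector`.
#' @export
make_pwm_scanner <- function(pwms, pval = 1e-4) {
  force(pwms); force(pval)
  function(seqs, ranges = NULL) count_pwm_hits(seqs, pwms, pval = pval,
                                               ranges = ranges)
}

dinuc_freq <- function(seqs) {
  counts <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  for (s in seqs) {
    v <- seq_to_int(s)
    if (length(v) < 2) next
    tr <- table(factor(v[-length(v)], 1:4), factor(v[-1], 1:4))
    counts <- counts + as.matrix(tr)
  }
  counts
}

sample_markov <- function(n, length, trans, start_prob) {
  vapply(seq_len(n), function(i) {
    v <- integer(length)
    v[1] <- sample(1:4, 1, prob = start_prob)
    for (j in 2:length) v[j] <- sample(1:4, 1, prob = trans[v[j - 1], ])
    paste(DNA_BASES[v], collapse = "")
  }, character(1))
}

#' Derive "non-motif" replacement sequences
#'
#' Generates `n_candidates` dinucleotide-frequency-matched random sequences
#' of the maximal motif length, screens each candidate by embedding its
#' length-matched prefix into real motif-hit contexts under two strategies —
#' (1) between the hit's 3-bp wild-type flanks, (2) substituted into the full
#' region — and counting scanner hits created around the replacement. The
#' two candidates with the lowest median hit-count rank across the two
#' strategies are returned (ties broken by candidate index).
#'
#' @param background character vector of background sequences whose
#'   dinucleotide frequencies the candidates match.
#' @param scanner a scanner closure, e.g. from [make_pwm_scanner()].
#' @param max_width candidate length (the maximal motif width).
#' @param contexts data.frame of hit contexts with columns `region_id`,
#'   `start`, `end` plus a `sequences` named vector passed separately.
#' @param sequences named character vector of region sequences providing the
#'   contexts.
#' @param n_candidates number of candidates to screen.
#' @param max_contexts cap on screened contexts (sampled, seeded).
#' @param seed integer seed.
#' @return list with `sequences` (the two selected candidates), `ranks`,
#'   and the per-candidate hit counts per strategy.
#' @export
derive_nonmotif_sequences <- function(background, scanner, max_width,
                                      contexts, sequences,
                                      n_candidates = 1000, max_contexts = 8,
                                      seed = 1L) {
  stopifnot(length(background) > 0, max_width >= 1, nrow(contexts) > 0)
  with_seed(seed, {
    dn <- dinuc_freq(background)
    trans <- sweep(dn, 1, pmax(rowSums(dn), 1), "/")
    zero <- rowSums(dn) == 0
    trans[zero, ] <- 0.25
    start_prob <- pmax(rowSums(dn), 1e-9) / sum(pmax(rowSums(dn), 1e-9))
    cands <- sample_markov(n_candidates, max_width, trans, start_prob)

    if (nrow(contexts) > max_contexts) {
      contexts <- contexts[sample(nrow(contexts), max_contexts), ]
    }
    hits1 <- hits2 <- numeric(n_candidates)
    for (ci in seq_len(nrow(contexts))) {
      cx <- contexts[ci, ]
      reg <- sequences[[cx$region_id]]
      len <- cx$end - cx$start
      lf <- substr(reg, max(1, cx$start - 2), cx$start)        # 3 bp upstream
      rf <- substr(reg, cx$end + 1, min(nchar(reg), cx$end + 3))
      emb1 <- paste0(lf, substr(cands, 1, len), rf)
      names(emb1) <- sprintf("c%04d", seq_len(n_candidates))
      hits1 <- hits1 + scanner(emb1)
      emb2 <- vapply(cands, function(cd) {
        s <- reg; substr(s, cx$start + 1, cx$end) <- substr(cd, 1, len); s
      }, character(1))
      names(emb2) <- names(emb1)
      rng <- rep(list(c(cx$start, cx$end)), n_candidates)
      names(rng) <- names(emb2)
      hits2 <- hits2 + scanner(emb2, ranges = rng)
    }
    r1 <- rank(hits1, ties.method = "min")
    r2 <- rank(hits2, ties.method = "min")
    med_rank <- (r1 + r2) / 2
    ord <- order(med_rank, seq_len(n_candidates))
    list(sequences = cands[ord[1:2]], selected = ord[1:2],
         candidates = cands, contexts = contexts, ranks = med_rank,
         hit_counts = data.frame(candidate = seq_len(n_candidates),
                                 flank_hits = hits1, context_hits = hits2))
  })
}

#' Perturb one motif site within a region sequence
#'
#' Methods 1 and 2 substitute the length-matched prefix of the first/second
#' non-motif sequence at the hit window; for minus-strand hits the reverse
#' complement of the prefix is inserted so the motif-bearing strand is the
#' one disrupted. Method 3 permutes the wild-type nucleotides within the
#' window (seeded; redrawn up to 100 times if the shuffle reproduces the
#' wild type, then the permutation with maximal Hamming distance is kept).
#'
#' @param region_seq the region's DNA sequence.
#' @param hit one-row data.frame (or list) with `start`, `end` (0-based
#'   half-open) and `strand`.
#' @param method perturbation method, 1, 2 or 3.
#' @param nonmotif_pair character vector of the two non-motif sequences.
#' @param seed integer seed (used by method 3).
#' @return The perturbed sequence (same length as `region_seq`).
#' @export
perturb_site <- function(region_seq, hit, method, nonmotif_pair = NULL,
                         seed = 1L) {
  start <- hit$start; end <- hit$end
  stopifnot(start >= 0, end > start, end <= nchar(region_seq))
  len <- end - start
  if (method %in% c(1, 2)) {
    stopifnot(!is.null(nonmotif_pair), nchar(nonmotif_pair[method]) >= len)
    repl <- substr(nonmotif_pair[method], 1, len)
    if (identical(hit$strand, "-")) repl <- revcomp(repl)
  } else if (method == 3) {
    wt <- substr(region_seq, start + 1, end)
    chars <- strsplit(wt, "")[[1]]
    repl <- with_seed(seed, {
      best <- wt; best_d <- 0L
      for (k in seq_len(100)) {
        cand <- paste(sample(chars), collapse = "")
        d <- sum(strsplit(cand, "")[[1]] != chars)
        if (d > best_d) { best <- cand; best_d <- d }
        if (cand != wt) { best <- cand; break }
      }
      best
    })
    if (repl == wt && length(unique(chars)) > 1) {
      # fall back: swap two differing positions
      i <- which(chars != chars[1])[1]
      chars2 <- chars; chars2[c(1, i)] <- chars2[c(i, 1)]
      repl <- paste(chars2, collapse = "")
    }
  } else stop("method must be 1, 2 or 3")
  out <- region_seq
  substr(out, start + 1, end) <- repl
  out
}

shuffle_seq <- function(s, seed) {
  with_seed(seed, paste(sample(strsplit(s, "")[[1]]), collapse = ""))
}

hit_instance_id <- function(region, motif, start, end) {
  sprintf("%s|%s|%d-%d", region, motif, start, end)
}

#' Build the perturbation oligo library
#'
#' Emits, per selected region: one wild-type (WT) sequence, one full-sequence
#' shuffle (SCRAM), and three random-window controls (RAND; the same
#' `rand_window`-bp window perturbed by each of the three methods). Per
#' selected motif instance: three PERT sequences (one per method). Hit
#' multiplicity follows the design rules: a single hit is perturbed as is
#' (`hit1`); an exactly-duplicated plus/minus strand pair is perturbed once
#' on the plus strand (`hit2`); two distinct hits are perturbed each
#' separately and then jointly (`hit2diff`); motif-region combinations with
#' three or more hits are discarded and logged. Additional double
#' perturbations are built for a configured pair list.
#'
#' @param selection a `design_selection` (its `edges` drive the PERT set).
#' @param sequences named character vector of region sequences.
#' @param hits motif-hit table (`region_id`, `motif_id`, `start`, `end`,
#'   `strand`).
#' @param nonmotif_pair the two non-motif replacement sequences.
#' @param config a [sim_config()] (for the RAND window width and seed).
#' @param pairs optional data.frame (`region`, `instance1`, `instance2`)
#'   naming instance ids to perturb jointly.
#' @return data.frame manifest (class `mpra_library`) with one row per
#'   designed sequence: `seq_id`, `category`, `method`, `region`,
#'   `design_class`, `instance_id`, `pair_id`, `windows`, `sequence`.
#'   Discarded multi-hit combinations are attached as attribute `discarded`.
#' @export
build_library <- function(selection, sequences, hits, nonmotif_pair, config,
                          pairs = NULL) {
  seed0 <- substream_seed(config$seed, "library")
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  discarded <- character(0)

  mk_pert <- function(region, hset, class, tag) {
    wt <- sequences[[region]]
    iid <- hit_instance_id(region, hset$motif_id[1], hset$start[1], hset$end[1])
    if (nrow(hset) > 1) {
      iid <- paste(mapply(hit_instance_id, region, hset$motif_id,
                          hset$start, hset$end), collapse = "+")
    }
    for (m in 1:3) {
      s <- wt
      for (hi in order(hset$start)) {       # overlapping windows left-to-right
        s <- perturb_site(s, hset[hi, ], m, nonmotif_pair,
                          seed = seed0 + m * 131 + hset$start[hi])
      }
      add(seq_id = sprintf("PERT|%s|m%d|%s", tag, m, region),
          category = "PERT", method = m, region = region,
          design_class = class, instance_id = iid, pair_id = NA_character_,
          windows = paste(sprintf("%d-%d", hset$start, hset$end),
                          collapse = ";"),
          sequence = s)
    }
  }

  for (region in selection$regions) {
    wt <- sequences[[region]]
    add(seq_id = paste0("WT|", region), category = "WT", method = NA_integer_,
        region = region, design_class = "control", instance_id = NA_character_,
        pair_id = NA_character_, windows = NA_character_, sequence = wt)
    add(seq_id = paste0("SCRAM|", region), category = "SCRAM",
        method = NA_integer_, region = region, design_class = "control",
        instance_id = NA_character_, pair_id = NA_character_,
        windows = NA_character_,
        sequence = shuffle_seq(wt, seed0 + match(region, selection$regions)))
    w <- config$rand_window
    rstart <- with_seed(seed0 + 7919 + match(region, selection$regions),
                        sample(0:(nchar(wt) - w), 1))
    rhit <- data.frame(start = rstart, end = rstart + w, strand = "+")
    for (m in 1:3) {
      add(seq_id = sprintf("RAND|m%d|%s", m, region), category = "RAND",
          method = m, region = region, design_class = "control",
          instance_id = NA_character_, pair_id = NA_character_,
          windows = sprintf("%d-%d", rstart, rstart + w),
          sequence = perturb_site(wt, rhit, m, nonmotif_pair,
                                  seed = seed0 + m * 17 + rstart))
    }
  }

  for (k in seq_len(nrow(selection$edges))) {
    region <- selection$edges$region[k]; motif <- selection$edges$motif[k]
    h <- hits[hits$region_id == region & hits$motif_id == motif, , drop = FALSE]
    if (nrow(h) == 0) {
      stop("no motif hit recorded for selected instance ", motif, " in ", region)
    }
    if (nrow(h) == 1) {
      mk_pert(region, h, "hit1", hit_instance_id(region, motif, h$start, h$end))
    } else if (nrow(h) == 2) {
      same_site <- h$start[1] == h$start[2] && h$end[1] == h$end[2]
      if (same_site) {
        hp <- h[h$strand == "+", , drop = FALSE]
        if (nrow(hp) == 0) hp <- h[1, , drop = FALSE]
        mk_pert(region, hp[1, , drop = FALSE], "hit2",
                hit_instance_id(region, motif, hp$start[1], hp$end[1]))
      } else {
        for (j in 1:2) {
          mk_pert(region, h[j, , drop = FALSE], "hit2diff",
                  hit_instance_id(region, motif, h$start[j], h$end[j]))
        }
        mk_pert(region, h[order(h$strand != "+", h$start), ], "hit2diff",
                paste0(hit_instance_id(region, motif, h$start[1], h$end[1]),
                       "+both"))
      }
    } else {
      discarded <- c(discarded, paste(region, motif, sep = "|"))
    }
  }

  manifest <- do.call(rbind, rows)

  if (!is.null(pairs) && nrow(pairs)) {
    find_hit <- function(iid) {
      p <- strsplit(iid, "|", fixed = TRUE)[[1]]
      coords <- as.integer(strsplit(p[3], "-", fixed = TRUE)[[1]])
      hits[hits$region_id == p[1] & hits$motif_id == p[2] &
             hits$start == coords[1] & hits$end == coords[2], , drop = FALSE]
    }
    prows <- list()
    for (k in seq_len(nrow(pairs))) {
      h1 <- find_hit(pairs$instance1[k]); h2 <- find_hit(pairs$instance2[k])
      stopifnot(nrow(h1) == 1, nrow(h2) == 1)
      region <- pairs$region[k]
      pid <- if (!is.null(pairs$pair_id)) pairs$pair_id[k] else sprintf("pair%03d", k)
      wt <- sequences[[region]]
      hset <- rbind(h1, h2)
      for (m in 1:3) {
        s <- wt
        for (hi in order(hset$start)) {
          s <- perturb_site(s, hset[hi, ], m, nonmotif_pair,
                            seed = seed0 + m * 131 + hset$start[hi])
        }
        prows[[length(prows) + 1L]] <- data.frame(
          seq_id = sprintf("DBL|%s|m%d|%s", pid, m, region),
          category = "DBL", method = m, region = region,
          design_class = "pair",
          instance_id = paste(pairs$instance1[k], pairs$instance2[k], sep = "&"),
          pair_id = pid,
          windows = paste(sprintf("%d-%d", hset$start, hset$end), collapse = ";"),
          sequence = s, stringsAsFactors = FALSE)
      }
    }
    manifest <- rbind(manifest, do.call(rbind, prows))
  }

  rownames(manifest) <- NULL
  attr(manifest, "discarded") <- discarded
  class(manifest) <- c("mpra_library", "data.frame")
  manifest
}

#' Write a library manifest as FASTA plus TSV
#'
#' FASTA headers carry the structured fields
#' `seq_id|category|method|region|windows`.
#'
#' @param manifest an `mpra_library` manifest.
#' @param fasta,tsv output paths.
#' @return invisibly, the manifest.
#' @export
write_library <- function(manifest, fasta, tsv) {
  ss <- Biostrings::DNAStringSet(manifest$sequence)
  names(ss) <- with(manifest, paste(seq_id, category, method, region, windows,
                                    sep = "|"))
  Biostrings::writeXStringSet(ss, fasta)
  write_tsv(manifest[, setdiff(names(manifest), "sequence")], tsv)
  invisible(manifest)
}
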