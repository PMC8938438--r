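#' Position weight matrix utilities and a minimal motif scanner
#'
#' The scanner computes, for every window of a sequence (both strands), the
#' log-odds score of the window under a PWM relative to a uniform background,
#' and converts scores to exact p-values with the standard dynamic-programming
#' convolution over per-position score distributions. It is deliberately
#' minimal: enough to plant, re-detect and screen motif hits in designed
#' sequences; it is exposed behind a pluggable interface so another scanner
#' can be substituted.
#'
#' @name pwm-scanner
NULL

#' Build a PWM object from a probability matrix
#'
#' @param probs 4 x w matrix of base probabilities (rows A,C,G,T).
#' @param id motif identifier.
#' @param background background base probabilities (default uniform).
#' @return An object of class `pwm` with log-odds matrix, consensus string and
#'   a precomputed exact null score distribution (used for p-values).
#' @export
pwm <- function(probs, id, background = rep(0.25, 4)) {
  stopifnot(is.matrix(probs), nrow(probs) == 4)
  probs <- sweep(probs, 2, colSums(probs), "/")
  lo <- log2(pmax(probs, 1e-4) / background)
  cons <- paste(DNA_BASES[apply(probs, 2, which.max)], collapse = "")
  obj <- list(id = id, probs = probs, lo = lo, width = ncol(probs),
              consensus = cons, background = background)
  obj$null <- pwm_score_null(lo, background)
  class(obj) <- "pwm"
  obj
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$id, "width", x$width, "consensus", x$consensus, "\n")
  invisible(x)
}

# Exact distribution of the log-odds score of a background-drawn window,
# discretized to a fixed grid. Returns a function p(score) = P(S >= score).
pwm_score_null <- function(lo, background, step = 0.02) {
  q <- round(lo / step)
  lo_min <- sum(apply(q, 2, min)); lo_max <- sum(apply(q, 2, max))
  dist <- c(1)                     # point mass at score 0, offset index 1
  off <- 0                         # dist[k] = P(sum = off + k - 1)
  for (j in seq_len(ncol(q))) {
    vals <- q[, j]
    lo_j <- min(vals); hi_j <- max(vals)
    new <- numeric(length(dist) + hi_j - lo_j)
    for (b in 1:4) {
      idx <- seq_along(dist) + (vals[b] - lo_j)
      new[idx] <- new[idx] + dist * background[b]
    }
    dist <- new
    off <- off + lo_j
  }
  surv <- rev(cumsum(rev(dist)))   # P(S >= off + k - 1)
  function(score) {
    k <- ceiling(score / step - 1e-9) - off + 1
    k <- pmin(pmax(k, 1), length(surv) + 1)
    ifelse(k > length(surv), 0, surv[pmin(k, length(surv))])
  }
}

#' Generate a random set of PWMs
#'
#' Consensus-dominated PWMs (default 0.85 weight on the consensus base) with
#' widths sampled from `width_range`; used by the synthetic-data generator.
#'
#' @param ids motif identifiers.
#' @param width_range integer range of motif widths.
#' @param consensus_weight probability mass on the consensus base.
#' @param seed integer seed.
#' @return Named list of `pwm` objects.
#' @export
random_pwms <- function(ids, width_range = c(8L, 12L), consensus_weight = 0.85,
                        seed = 1L) {
  with_seed(seed, {
    out <- lapply(ids, function(id) {
      w <- sample(seq(width_range[1], width_range[2]), 1)
      cons <- sample(1:4, w, replace = TRUE)
      probs <- matrix((1 - consensus_weight) / 3, 4, w)
      probs[cbind(cons, seq_len(w))] <- consensus_weight
      pwm(probs, id)
    })
    names(out) <- ids
    out
  })
}

score_windows <- function(s_int, lo) {
  w <- ncol(lo)
  n <- length(s_int) - w + 1
  if (n < 1) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(w)) sc <- sc + lo[cbind(s_int[j:(j + n - 1)], j)]
  sc
}

#' Scan sequences for PWM hits
#'
#' Both strands are scanned; a window is a hit when its exact log-odds
#' p-value is below `pval`. Coordinates are 0-based half-open on the forward
#' strand.
#'
#' @param seqs named character vector of DNA sequences.
#' @param pwms list of `pwm` objects.
#' @param pval p-value threshold (default `1e-4`).
#' @param ranges optional list (named by sequence) of `c(start, end)` 0-based
#'   half-open windows restricting the scan to windows overlapping the range.
#' @return data.frame with columns `region_id`, `motif_id`, `start`, `end`,
#'   `strand`, `pvalue`, `score`.
#' @export
scan_pwm <- function(seqs, pwms, pval = 1e-4, ranges = NULL) {
  stopifnot(!is.null(names(seqs)))
  res <- vector("list", length(seqs) * length(pwms) * 2)
  k <- 0L
  for (sid in names(seqs)) {
    fw <- seq_to_int(seqs[[sid]])
    rv <- rev(5L - fw)               # reverse complement in integer coding
    L <- length(fw)
    rng <- if (!is.null(ranges)) ranges[[sid]] else NULL
    for (pw in pwms) {
      p_of <- pw$null
      for (strand in c("+", "-")) {
        sc <- score_windows(if (strand == "+") fw else rv, pw$lo)
        if (!length(sc)) next
        starts0 <- if (strand == "+") seq_along(sc) - 1L else L - pw$width + 1L - seq_along(sc) + 1L - 1L
        pv <- p_of(sc)
        keep <- pv < pval
        if (!is.null(rng)) {
          keep <- keep & (starts0 < rng[2]) & (starts0 + pw$width > rng[1])
        }
        if (any(keep)) {
          k <- k + 1L
          res[[k]] <- data.frame(
            region_id = sid, motif_id = pw$id,
            start = starts0[keep], end = starts0[keep] + pw$width,
            strand = strand, pvalue = pv[keep], score = sc[keep],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (k == 0L) {
    return(data.frame(region_id = character(), motif_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      pvalue = numeric(), score = numeric()))
  }
  out <- do.call(rbind, res[seq_len(k)])
  out[order(out$region_id, out$start, out$motif_id), , drop = FALSE]
}

#' Count PWM hits in a set of sequences
#'
#' Convenience wrapper around [scan_pwm()] returning the total number of hits
#' per input sequence (zero included).
#'
#' @inheritParams scan_pwm
#' @return Named integer vector of hit counts.
#' @export
count_pwm_hits <- function(seqs, pwms, pval = 1e-4, ranges = NULL) {
  hits <- scan_pwm(seqs, pwms, pval = pval, ranges = ranges)
  n <- table(factor(hits$region_id, levels = names(seqs)))
  stats::setNames(as.integer(n), names(seqs))
}
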