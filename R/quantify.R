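#' Library size factors (upper-quartile)
#'
#' One DNA and one RNA factor per (timepoint, replicate) library, computed as
#' the upper quartile of the positive counts, rescaled to unit geometric
#' mean. Factors are computed once on the full dataset and reused across all
#' analyses so per-timepoint and temporal models share a common scale.
#'
#' @param counts an `mpra_counts` data.frame.
#' @return data.frame with columns `timepoint`, `replicate`, `dna_sf`,
#'   `rna_sf`.
#' @export
compute_size_factors <- function(counts) {
  libs <- unique(counts[, c("timepoint", "replicate")])
  uq <- function(x) stats::quantile(x[x > 0], 0.75, names = FALSE)
  libs$dna_sf <- NA_real_; libs$rna_sf <- NA_real_
  for (i in seq_len(nrow(libs))) {
    sel <- counts$timepoint == libs$timepoint[i] &
      counts$replicate == libs$replicate[i]
    libs$dna_sf[i] <- uq(counts$dna[sel])
    libs$rna_sf[i] <- uq(counts$rna[sel])
  }
  libs$dna_sf <- libs$dna_sf / exp(mean(log(libs$dna_sf)))
  libs$rna_sf <- libs$rna_sf / exp(mean(log(libs$rna_sf)))
  rownames(libs) <- NULL
  libs
}

merge_sf <- function(df, sf) {
  if (is.null(sf)) {
    df$dna_sf <- 1; df$rna_sf <- 1
    return(df)
  }
  m <- match(paste(df$timepoint, df$replicate),
             paste(sf$timepoint, sf$replicate))
  df$dna_sf <- sf$dna_sf[m]; df$rna_sf <- sf$rna_sf[m]
  df
}

# Keep only model terms whose variables actually vary in the data; preserves
# interaction terms whose components all vary.
drop_constant_terms <- function(formula, data) {
  tl <- attr(stats::terms(formula), "term.labels")
  if (!length(tl)) return(~1)
  varies <- function(v) length(unique(data[[v]])) > 1
  keep <- tl[vapply(tl, function(lab) {
    all(vapply(all.vars(str2lang(lab)), varies, logical(1)))
  }, logical(1))]
  if (length(keep)) stats::reformulate(keep) else ~1
}

# Latent construct abundance from the DNA counts: gamma GLM, log link, with
# the library size factor as a fixed offset. Returns exp(X beta) per row.
fit_dna_latent <- function(df, design = ~ timepoint + replicate + barcode) {
  f <- drop_constant_terms(design, df)
  X <- stats::model.matrix(f, df)
  y <- pmax(df$dna, 0.5)          # gamma likelihood needs positive counts
  off <- log(df$dna_sf)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::Gamma(link = "log"),
                                    offset = off)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(y / df$dna_sf)
  fit$fitted.values / df$dna_sf
}

nb_loglik <- function(y, mu, theta) {
  sum(stats::dnbinom(y, size = theta, mu = pmax(mu, 1e-12), log = TRUE))
}

# Negative-binomial GLM with fixed offset; dispersion by maximum likelihood
# (MASS::glm.nb) unless theta is supplied, with a near-Poisson fallback when
# the dispersion estimate does not converge.
fit_nb <- function(y, X, off, theta = NULL) {
  dat <- data.frame(.y = y)
  converged <- TRUE
  if (is.null(theta)) {
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(.y ~ 0 + X + offset(off), data = dat,
                                    maxit = 100)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      return(list(coef = stats::coef(fit), mu = stats::fitted(fit),
                  theta = fit$theta,
                  loglik = nb_loglik(y, stats::fitted(fit), fit$theta),
                  converged = fit$converged))
    }
    theta <- 1e5
    converged <- FALSE
  }
  fit <- suppressWarnings(stats::glm(.y ~ 0 + X + offset(off), data = dat,
                                     family = MASS::negative.binomial(theta)))
  list(coef = stats::coef(fit), mu = stats::fitted(fit), theta = theta,
       loglik = nb_loglik(y, stats::fitted(fit), theta),
       converged = converged && fit$converged)
}

assert_nested <- function(full, reduced) {
  fl <- attr(stats::terms(full), "term.labels")
  rl <- attr(stats::terms(reduced), "term.labels")
  if (!all(rl %in% fl)) {
    stop("reduced design is not nested in the full design: ",
         paste(setdiff(rl, fl), collapse = ", "))
  }
}

#' Estimate per-sequence transcription rates (alpha)
#'
#' Two nested GLMs per sequence: a gamma model with log link estimates the
#' latent construct abundance from the DNA counts (design
#' `~ timepoint + replicate + barcode`), and a negative-binomial model with
#' log link estimates the transcription rate from the RNA counts, using the
#' latent DNA estimates and the RNA library size factors as fixed offsets
#' (design `~ timepoint + replicate`). Alpha is the exponentiated RNA linear
#' predictor per (timepoint, replicate). Sequences whose dispersion fit does
#' not converge fall back to a ratio-based alpha and are flagged.
#'
#' @param counts an `mpra_counts` data.frame (filtered).
#' @param sf size factors from [compute_size_factors()] (computed from
#'   `counts` when `NULL`).
#' @param dna_design,rna_design model formulas as above.
#' @return data.frame with columns `sequence_id`, `timepoint`, `replicate`,
#'   `alpha`, `loglik`, `converged`.
#' @export
estimate_alpha <- function(counts, sf = NULL,
                           dna_design = ~ timepoint + replicate + barcode,
                           rna_design = ~ timepoint + replicate) {
  if (is.null(sf)) sf <- compute_size_factors(counts)
  out <- lapply(split(seq_len(nrow(counts)), counts$sequence_id), function(ix) {
    df <- merge_sf(counts[ix, ], sf)
    dhat <- fit_dna_latent(df, dna_design)
    f <- drop_constant_terms(rna_design, df)
    X <- stats::model.matrix(f, df)
    off <- log(dhat) + log(df$rna_sf)
    fit <- fit_nb(df$rna, X, off)
    grid <- unique(df[, c("timepoint", "replicate")])
    Xg <- stats::model.matrix(f, grid)
    alpha <- as.numeric(exp(Xg %*% fit$coef))
    if (!fit$converged) {
      ratio <- df$rna / pmax(dhat * df$rna_sf, 1e-12)
      alpha <- vapply(seq_len(nrow(grid)), function(i) {
        mean(ratio[df$timepoint == grid$timepoint[i] &
                     df$replicate == grid$replicate[i]])
      }, numeric(1))
    }
    data.frame(sequence_id = df$sequence_id[1], timepoint = grid$timepoint,
               replicate = grid$replicate, alpha = alpha,
               loglik = fit$loglik, converged = fit$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Likelihood-ratio test between nested RNA designs
#'
#' Fits the latent-DNA/negative-binomial nested GLM pair under a full and a
#' reduced RNA design and compares them with a chi-square likelihood-ratio
#' test (df = difference in design columns). The reduced model is refit at
#' the full model's dispersion so the two likelihoods are nested. Optional
#' per-timepoint offsets (e.g. the temporal coefficients of a joint
#' scrambled-control model, applied as normalization factors) enter the RNA
#' linear predictor as fixed terms.
#'
#' @param counts an `mpra_counts` subset holding every sequence the designs
#'   reference (a `sequence` factor column is derived from `sequence_id`;
#'   set its reference level via `ref`).
#' @param full,reduced RNA design formulas (reduced nested in full).
#' @param sf size factors ([compute_size_factors()]), or `NULL` for unit.
#' @param dna_design DNA model design.
#' @param offsets named numeric vector of per-timepoint offsets added to the
#'   RNA linear predictor, or `NULL`.
#' @param ref reference level for the `sequence` factor.
#' @return list of class `mpra_lrt`: `statistic`, `df`, `pvalue`,
#'   `coefficients`, `converged`, `n_barcodes`.
#' @export
lrt_compare <- function(counts, full, reduced, sf = NULL,
                        dna_design = ~ timepoint + replicate + barcode,
                        offsets = NULL, ref = NULL) {
  assert_nested(full, reduced)
  df <- merge_sf(counts, sf)
  df$sequence <- factor(df$sequence_id)
  if (!is.null(ref) && ref %in% levels(df$sequence)) {
    df$sequence <- stats::relevel(df$sequence, ref)
  }
  dhat <- fit_dna_latent(df, dna_design)
  off <- log(dhat) + log(df$rna_sf)
  if (!is.null(offsets)) off <- off + offsets[as.character(df$timepoint)]
  ff <- drop_constant_terms(full, df)
  fr <- drop_constant_terms(reduced, df)
  Xf <- stats::model.matrix(ff, df)
  Xr <- stats::model.matrix(fr, df)
  fit_f <- fit_nb(df$rna, Xf, off)
  fit_r <- fit_nb(df$rna, Xr, off, theta = fit_f$theta)
  stat <- max(0, 2 * (fit_f$loglik - fit_r$loglik))
  dof <- ncol(Xf) - ncol(Xr)
  p <- if (dof <= 0) 1 else stats::pchisq(stat, dof, lower.tail = FALSE)
  n_bc <- length(unique(df$barcode))
  out <- list(statistic = stat, df = dof, pvalue = p,
              coefficients = fit_f$coef, theta = fit_f$theta,
              converged = fit_f$converged && fit_r$converged,
              n_barcodes = n_bc)
  class(out) <- "mpra_lrt"
  out
}

#' @export
print.mpra_lrt <- function(x, ...) {
  cat(sprintf("LRT: chi-square = %.3f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$pvalue))
  invisible(x)
}

#' MAD-based z-test of activity against scrambled controls
#'
#' Alpha values are MAD-normalized against the null distribution estimated
#' from the scrambled negative controls:
#' `z = (alpha - median(null)) / (1.4826 * MAD(null))`, with a normal tail
#' p-value (one-sided upper tail by default: "more active than the null").
#'
#' @param alphas numeric vector of alpha values to test.
#' @param scram_alphas numeric vector of control alpha values (>= 10).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return data.frame with columns `alpha`, `z`, `pvalue`.
#' @export
mad_ztest <- function(alphas, scram_alphas,
                      alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(scram_alphas) < 10) {
    stop("need at least 10 control alpha values to estimate the null")
  }
  s <- stats::mad(scram_alphas)        # 1.4826 * median absolute deviation
  if (s == 0) {
    stop("MAD of the control alphas is zero; jitter the controls or enlarge the null set")
  }
  z <- (alphas - stats::median(scram_alphas)) / s
  p <- if (alternative == "greater") {
    stats::pnorm(z, lower.tail = FALSE)
  } else 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  data.frame(alpha = alphas, z = z, pvalue = p)
}

#' Benjamini-Hochberg FDR adjustment within batches
#'
#' Standard step-up BH, applied within each correction batch (an analysis,
#' per the batching conventions of the comparative analyses: the
#' per-timepoint comparison is corrected jointly across all timepoints).
#'
#' @param pvals numeric vector of p-values.
#' @param batch optional factor defining correction batches; `NULL` corrects
#'   the whole vector jointly.
#' @return numeric vector of FDR-adjusted values.
#' @export
bh_adjust <- function(pvals, batch = NULL) {
  stopifnot(all(is.na(pvals) | (pvals >= 0 & pvals <= 1)))
  if (is.null(batch)) return(stats::p.adjust(pvals, method = "BH"))
  out <- rep(NA_real_, length(pvals))
  for (b in split(seq_along(pvals), batch)) {
    out[b] <- stats::p.adjust(pvals[b], method = "BH")
  }
  out
}

#' Temporal coefficients of the joint scrambled-control model
#'
#' Fits one negative-binomial model to all scrambled controls
#' (RNA design `~ timepoint`) on top of their latent-DNA offsets and returns
#' the per-timepoint coefficients (first timepoint = 0). These are the
#' normalization factors applied as offsets when testing a sequence's
#' temporal activity against the control behaviour.
#'
#' @param scram_counts `mpra_counts` restricted to scrambled controls.
#' @param sf size factors.
#' @return named numeric vector, one element per timepoint level.
#' @export
scram_temporal_offsets <- function(scram_counts, sf = NULL) {
  df <- merge_sf(scram_counts, sf)
  dhat <- fit_dna_latent(df, ~ timepoint + replicate + barcode)
  tps <- sort(unique(as.character(df$timepoint)))
  X <- stats::model.matrix(~ timepoint, data.frame(timepoint = factor(df$timepoint, tps)))
  fit <- fit_nb(df$rna, X, log(dhat) + log(df$rna_sf))
  co <- c(0, fit$coef[-1])
  names(co) <- tps
  co
}

#' RNA/DNA ratios per sequence (closed-form averaging scheme)
#'
#' Per (timepoint, replicate) library: the per-sequence abundance is the
#' reads-per-million of its barcodes divided by the barcode count, and the
#' per-sequence ratio is the mean over barcodes of the normalized RNA/DNA
#' ratio, with a pseudocount of 1 added to the numerator and denominator
#' counts. Ratios are then divided by the library median and averaged across
#' replicates.
#'
#' @param counts an `mpra_counts` data.frame.
#' @return list with `per_sample` (sequence x timepoint x replicate table of
#'   `dna_cpm`, `rna_cpm`, `ratio`, `ratio_norm`) and `combined` (sequence x
#'   timepoint cross-replicate mean of the normalized ratio).
#' @export
rna_dna_ratio <- function(counts) {
  libs <- unique(counts[, c("timepoint", "replicate")])
  res <- list()
  for (i in seq_len(nrow(libs))) {
    sel <- counts$timepoint == libs$timepoint[i] &
      counts$replicate == libs$replicate[i]
    sub <- counts[sel, ]
    sum_dna <- sum(sub$dna); sum_rna <- sum(sub$rna)
    per_seq <- lapply(split(sub, sub$sequence_id), function(d) {
      nbc <- nrow(d)
      data.frame(sequence_id = d$sequence_id[1],
                 timepoint = libs$timepoint[i], replicate = libs$replicate[i],
                 n_barcodes = nbc,
                 dna_cpm = 1e6 * sum(d$dna) / (nbc * sum_dna),
                 rna_cpm = 1e6 * sum(d$rna) / (nbc * sum_rna),
                 ratio = mean(((d$rna + 1) / sum_rna) / ((d$dna + 1) / sum_dna)),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, per_seq)
    tab$ratio_norm <- tab$ratio / stats::median(tab$ratio)
    res[[i]] <- tab
  }
  per_sample <- do.call(rbind, res)
  rownames(per_sample) <- NULL
  agg <- stats::aggregate(ratio_norm ~ sequence_id + timepoint, per_sample,
                          mean)
  names(agg)[3] <- "ratio"
  list(per_sample = per_sample, combined = agg)
}
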