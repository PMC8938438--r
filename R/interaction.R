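#' Test a motif pair for deviation from log-additive effects
#'
#' Under the billboard model the effects of two perturbations are
#' log-additive: the double perturbation equals the product of the single
#' fold changes. The test fits the RNA negative-binomial GLM over the four
#' variants (wild type, each single perturbation, the double) with binary
#' covariates `pert1` and `pert2` — the full model includes their product,
#' the reduced does not — and compares them with a 1-df likelihood ratio
#' test. The interaction coefficient gamma is reported on the model's
#' natural-log scale.
#'
#' @param counts `mpra_counts` rows for the four variants, with logical
#'   columns `pert1` and `pert2` (the double perturbation has both TRUE).
#' @param sf size factors.
#' @param dna_design DNA model design.
#' @return list with `gamma`, `statistic`, `df`, `pvalue`, `converged`.
#' @export
test_interaction <- function(counts, sf = NULL,
                             dna_design = ~ timepoint + replicate + barcode) {
  stopifnot(all(c("pert1", "pert2") %in% names(counts)))
  combos <- unique(counts[, c("pert1", "pert2")])
  if (nrow(combos) < 4) {
    miss <- setdiff(c("00", "10", "01", "11"),
                    paste0(as.integer(combos$pert1), as.integer(combos$pert2)))
    stop("missing variant(s) for interaction test: pert1/pert2 = ",
         paste(miss, collapse = ", "))
  }
  lrt <- lrt_compare(counts, ~ timepoint + pert1 * pert2,
                     ~ timepoint + pert1 + pert2, sf = sf,
                     dna_design = dna_design)
  cf <- lrt$coefficients
  gi <- grep("pert1.*:.*pert2|pert2.*:.*pert1", names(cf))
  list(gamma = unname(cf[gi][1]), statistic = lrt$statistic, df = lrt$df,
       pvalue = lrt$pvalue, converged = lrt$converged)
}

parse_windows <- function(w) {
  lapply(strsplit(w, ";", fixed = TRUE), function(x) {
    do.call(rbind, lapply(strsplit(x, "-", fixed = TRUE), as.integer))
  })
}

windows_overlap <- function(w1, w2) {
  a <- parse_windows(w1)[[1]]; b <- parse_windows(w2)[[1]]
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a[i, 1] < b[j, 2] && b[j, 1] < a[i, 2]) return(TRUE)
    }
  }
  FALSE
}

#' Classify motif pairs as additive or interacting
#'
#' Applies, in order: exclusion of pairs whose assayed sites overlap
#' (interval intersection of the perturbed windows); a functionality
#' requirement that at least one of the single perturbations passes the
#' four-filter scheme (in method 3 and in method 1 or 2, as for FRS
#' calling); and a consistency requirement that the significance label —
#' `|gamma| > gamma_min` with BH-corrected p below `fdr` — agrees between
#' method 3 and at least one of methods 1 and 2. Surviving pairs are labeled
#' interacting when the consistent label is significant, additive otherwise.
#'
#' @param pair_tests data.frame with one row per (pair, method):
#'   `pair_id`, `region`, `instance1`, `instance2`, `windows1`, `windows2`,
#'   `method`, `gamma`, `pvalue`.
#' @param filter_results output of [apply_filters()] for the single sites.
#' @param gamma_min minimum interaction size (natural-log scale).
#' @param fdr BH threshold.
#' @return data.frame of class `pair_results`: per pair, per-method gamma
#'   and BH p, `label` in additive/interacting/excluded, `exclusion_reason`.
#' @export
classify_pairs <- function(pair_tests, filter_results, gamma_min = 0.5,
                           fdr = 0.05) {
  pt <- as.data.frame(pair_tests)
  pt$bh <- bh_adjust(pt$pvalue, pt$method)
  pt$significant <- abs(pt$gamma) > gamma_min & pt$bh < fdr

  frs_like <- consensus_frs(filter_results)   # instances passing the scheme
  functional <- frs_like$instance_id

  out <- lapply(split(pt, pt$pair_id), function(d) {
    d <- d[order(d$method), ]
    base <- data.frame(pair_id = d$pair_id[1], region = d$region[1],
                       instance1 = d$instance1[1], instance2 = d$instance2[1],
                       gamma_m1 = d$gamma[d$method == 1][1],
                       gamma_m2 = d$gamma[d$method == 2][1],
                       gamma_m3 = d$gamma[d$method == 3][1],
                       bh_m1 = d$bh[d$method == 1][1],
                       bh_m2 = d$bh[d$method == 2][1],
                       bh_m3 = d$bh[d$method == 3][1],
                       stringsAsFactors = FALSE)
    if (windows_overlap(d$windows1[1], d$windows2[1])) {
      base$label <- "excluded"; base$exclusion_reason <- "overlap"
      return(base)
    }
    if (!any(c(d$instance1[1], d$instance2[1]) %in% functional)) {
      base$label <- "excluded"; base$exclusion_reason <- "non-functional"
      return(base)
    }
    s3 <- d$significant[d$method == 3][1]
    s1 <- d$significant[d$method == 1][1]
    s2 <- d$significant[d$method == 2][1]
    consistent <- isTRUE(s3 == s1) || isTRUE(s3 == s2)
    if (!consistent) {
      base$label <- "excluded"; base$exclusion_reason <- "inconsistent"
      return(base)
    }
    base$label <- if (isTRUE(s3)) "interacting" else "additive"
    base$exclusion_reason <- NA_character_
    base
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("pair_results", "data.frame")
  out
}
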