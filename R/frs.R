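parse_instance <- function(instance_id) {
  parts <- strsplit(instance_id, "|", fixed = TRUE)
  data.frame(region = vapply(parts, `[`, "", 1),
             motif = vapply(parts, `[`, "", 2),
             windows = vapply(parts, `[`, "", 3),
             stringsAsFactors = FALSE)
}

#' Run the full battery of per-sequence comparisons
#'
#' For every single-site perturbed sequence this computes, per perturbation
#' method: the per-timepoint perturbed-vs-wild-type LRT (FDR corrected
#' jointly across all timepoints within a method), the temporal
#' perturbed-vs-wild-type LRT (interaction design), the temporal tests of
#' the perturbed and wild-type sequences against the scrambled-control
#' behaviour (joint control model coefficients applied as offsets), and the
#' per-timepoint MAD z-tests against the scrambled alpha null (FDR within
#' timepoint). Alpha estimates for all sequences are returned alongside.
#'
#' @param counts filtered `mpra_counts`.
#' @param manifest the `mpra_library` manifest.
#' @param sf size factors (computed from `counts` when `NULL`).
#' @param include_rand also test RAND controls against wild type.
#' @return A list of class `mpra_tests` with elements `alphas`, `alpha_tp`,
#'   `mad`, `per_tp`, `temporal`, `scram_offsets`, `n_timepoints`.
#' @export
run_mpra_tests <- function(counts, manifest, sf = NULL, include_rand = FALSE) {
  if (is.null(sf)) sf <- compute_size_factors(counts)
  man <- as.data.frame(manifest)
  single <- man$category == "PERT" & !grepl("+", man$instance_id, fixed = TRUE)
  pert <- man[single, ]
  wt_of <- function(region) paste0("WT|", region)
  scram_ids <- man$seq_id[man$category == "SCRAM"]
  tps <- sort(unique(as.character(counts$timepoint)))
  n_tp <- length(tps)

  ids <- c(man$seq_id[man$category %in% c("WT", "SCRAM")], pert$seq_id,
           if (include_rand) man$seq_id[man$category == "RAND"])
  ids <- intersect(ids, unique(counts$sequence_id))
  alphas <- estimate_alpha(counts[counts$sequence_id %in% ids, ], sf)
  alpha_tp <- stats::aggregate(alpha ~ sequence_id + timepoint, alphas, mean)

  a_of <- function(id, tp) {
    alpha_tp$alpha[alpha_tp$sequence_id == id & alpha_tp$timepoint == tp]
  }

  # MAD z-tests against the scrambled alpha null, per timepoint
  mad_rows <- list()
  for (tp in tps) {
    null_a <- alpha_tp$alpha[alpha_tp$sequence_id %in% scram_ids &
                               alpha_tp$timepoint == tp]
    test_set <- rbind(
      data.frame(seq_id = wt_of(unique(man$region[man$category == "WT"])),
                 role = "WT", method = NA_integer_,
                 instance_id = NA_character_, stringsAsFactors = FALSE),
      data.frame(seq_id = pert$seq_id, role = "PERT", method = pert$method,
                 instance_id = pert$instance_id, stringsAsFactors = FALSE))
    test_set <- test_set[test_set$seq_id %in% alpha_tp$sequence_id, ]
    a <- vapply(test_set$seq_id, function(id) a_of(id, tp), numeric(1))
    mt <- mad_ztest(a, null_a, alternative = "greater")
    mad_rows[[tp]] <- data.frame(test_set, timepoint = tp, z = mt$z,
                                 pvalue = mt$pvalue, stringsAsFactors = FALSE)
  }
  mad_tab <- do.call(rbind, mad_rows)
  batch <- interaction(mad_tab$timepoint,
                       ifelse(mad_tab$role == "WT", "WT",
                              paste0("PERT_m", mad_tab$method)), drop = TRUE)
  mad_tab$fdr <- bh_adjust(mad_tab$pvalue, batch)

  # per-timepoint PERT-vs-WT LRTs
  pt_rows <- list()
  for (i in seq_len(nrow(pert))) {
    wt_id <- wt_of(pert$region[i])
    for (tp in tps) {
      sub <- counts[counts$sequence_id %in% c(pert$seq_id[i], wt_id) &
                      counts$timepoint == tp, ]
      lrt <- lrt_compare(sub, ~ sequence, ~ 1, sf = sf,
                         dna_design = ~ replicate + barcode, ref = wt_id)
      lfc <- log(a_of(pert$seq_id[i], tp)) - log(a_of(wt_id, tp))
      pt_rows[[length(pt_rows) + 1L]] <- data.frame(
        instance_id = pert$instance_id[i], method = pert$method[i],
        region = pert$region[i], seq_id = pert$seq_id[i], timepoint = tp,
        statistic = lrt$statistic, pvalue = lrt$pvalue, lfc = lfc,
        stringsAsFactors = FALSE)
    }
  }
  per_tp <- do.call(rbind, pt_rows)
  per_tp$fdr <- bh_adjust(per_tp$pvalue, per_tp$method)  # jointly across tps

  # temporal comparisons
  off <- scram_temporal_offsets(counts[counts$sequence_id %in% scram_ids, ], sf)
  tmp_rows <- list()
  add_tmp <- function(instance_id, method, region, comparison, lrt, lfc) {
    tmp_rows[[length(tmp_rows) + 1L]] <<- data.frame(
      instance_id = instance_id, method = method, region = region,
      comparison = comparison, statistic = lrt$statistic, df = lrt$df,
      pvalue = lrt$pvalue, lfc = lfc, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(pert))) {
    wt_id <- wt_of(pert$region[i])
    sub <- counts[counts$sequence_id %in% c(pert$seq_id[i], wt_id), ]
    lrt <- lrt_compare(sub, ~ timepoint * sequence, ~ timepoint, sf = sf,
                       ref = wt_id)
    lfc <- mean(log(alpha_tp$alpha[alpha_tp$sequence_id == pert$seq_id[i]])) -
      mean(log(alpha_tp$alpha[alpha_tp$sequence_id == wt_id]))
    add_tmp(pert$instance_id[i], pert$method[i], pert$region[i], "PERT_WT",
            lrt, lfc)
    subp <- counts[counts$sequence_id == pert$seq_id[i], ]
    add_tmp(pert$instance_id[i], pert$method[i], pert$region[i], "PERT_SCRAM",
            lrt_compare(subp, ~ timepoint, ~ 1, sf = sf, offsets = off), NA)
  }
  for (region in unique(man$region[man$category == "WT"])) {
    wt_id <- wt_of(region)
    if (!wt_id %in% counts$sequence_id) next
    subw <- counts[counts$sequence_id == wt_id, ]
    add_tmp(NA_character_, NA_integer_, region, "WT_SCRAM",
            lrt_compare(subw, ~ timepoint, ~ 1, sf = sf, offsets = off), NA)
  }
  temporal <- do.call(rbind, tmp_rows)
  temporal$fdr <- bh_adjust(temporal$pvalue,
                            interaction(temporal$comparison,
                                        ifelse(is.na(temporal$method), 0L,
                                               temporal$method), drop = TRUE))

  out <- list(alphas = alphas, alpha_tp = alpha_tp, mad = mad_tab,
              per_tp = per_tp, temporal = temporal, scram_offsets = off,
              n_timepoints = n_tp, size_factors = sf)
  class(out) <- "mpra_tests"
  out
}

#' Apply the four functional-site filters
#'
#' Per motif instance and perturbation method: (1) the perturbed sequence
#' deviates from wild type in at least one timepoint; (2) its time course
#' deviates from wild type; (3) the wild type is more active than the
#' scrambled null at every timepoint, or the perturbed sequence at one or
#' more; (4) the perturbed or the wild-type time course deviates from the
#' scrambled-control behaviour. All at the given FDR threshold. Direction is
#' summarized from the sign of the temporal log fold change, with instances
#' showing both significantly increased and decreased timepoints flagged
#' mixed.
#'
#' @param tests an `mpra_tests` object from [run_mpra_tests()].
#' @param fdr FDR threshold (default 0.05).
#' @return data.frame of class `filter_results` with columns `instance_id`,
#'   `method`, `region`, `motif`, `windows`, `f1`-`f4`, `pass`,
#'   `n_sig_up`, `n_sig_down`, `direction`, `temporal_fdr`, `temporal_lfc`.
#' @export
apply_filters <- function(tests, fdr = 0.05) {
  stopifnot(inherits(tests, "mpra_tests"))
  n_tp <- tests$n_timepoints
  keys <- unique(tests$per_tp[, c("instance_id", "method", "region")])
  for (need in c("per_tp", "temporal", "mad")) {
    if (is.null(tests[[need]]) || !nrow(tests[[need]])) {
      stop("missing comparison table: ", need)
    }
  }
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    pt <- tests$per_tp[tests$per_tp$instance_id == k$instance_id &
                         tests$per_tp$method == k$method, ]
    tmp <- tests$temporal[!is.na(tests$temporal$instance_id) &
                            tests$temporal$instance_id == k$instance_id &
                            tests$temporal$method == k$method, ]
    t_pw <- tmp[tmp$comparison == "PERT_WT", ]
    t_ps <- tmp[tmp$comparison == "PERT_SCRAM", ]
    t_ws <- tests$temporal[tests$temporal$comparison == "WT_SCRAM" &
                             tests$temporal$region == k$region, ]
    mad_wt <- tests$mad[tests$mad$role == "WT" &
                          tests$mad$seq_id == paste0("WT|", k$region), ]
    mad_pt <- tests$mad[tests$mad$role == "PERT" &
                          !is.na(tests$mad$instance_id) &
                          tests$mad$instance_id == k$instance_id &
                          tests$mad$method == k$method, ]
    if (!nrow(t_pw) || !nrow(t_ps) || !nrow(t_ws) || !nrow(mad_wt) ||
        !nrow(mad_pt)) {
      stop("missing comparison for instance ", k$instance_id, " method ",
           k$method)
    }
    f1 <- any(pt$fdr < fdr)
    f2 <- t_pw$fdr[1] < fdr
    f3 <- sum(mad_wt$fdr < fdr) == n_tp || any(mad_pt$fdr < fdr)
    f4 <- t_ps$fdr[1] < fdr || t_ws$fdr[1] < fdr
    sig <- pt$fdr < fdr
    n_up <- sum(sig & pt$lfc > 0); n_dn <- sum(sig & pt$lfc < 0)
    direction <- if (n_up > 0 && n_dn > 0) {
      "mixed"
    } else if (t_pw$lfc[1] < 0) "activating" else "dampening"
    data.frame(k, motif = parse_instance(k$instance_id)$motif,
               windows = parse_instance(k$instance_id)$windows,
               f1 = f1, f2 = f2, f3 = f3, f4 = f4,
               pass = f1 && f2 && f3 && f4,
               n_sig_up = n_up, n_sig_down = n_dn, direction = direction,
               temporal_fdr = t_pw$fdr[1], temporal_lfc = t_pw$lfc[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("filter_results", "data.frame")
  out
}

#' Consensus functional regulatory sites across perturbation methods
#'
#' An instance is a functional regulatory site (FRS) when it passes all four
#' filters in the nucleotide-shuffle method (3) and in at least one of the
#' fixed-replacement methods (1 or 2), with the direction of effect agreeing
#' among the passing methods. Duplicates — identical perturbed coordinates
#' called under different PWMs — are resolved by keeping the record with the
#' lowest temporal FDR.
#'
#' @param filter_results output of [apply_filters()].
#' @return data.frame of class `frs_records`: `instance_id`, `region`,
#'   `motif`, `windows`, `direction`, `supporting_methods`,
#'   `min_temporal_fdr`.
#' @export
consensus_frs <- function(filter_results) {
  fr <- as.data.frame(filter_results)
  out <- lapply(split(fr, fr$instance_id), function(d) {
    d3 <- d[d$method == 3, ]; d12 <- d[d$method %in% c(1, 2) & d$pass, ]
    if (!nrow(d3) || !d3$pass[1] || !nrow(d12)) return(NULL)
    agree <- d12[d12$direction == d3$direction[1], ]
    if (!nrow(agree)) return(NULL)
    sup <- sort(c(3L, agree$method))
    data.frame(instance_id = d$instance_id[1], region = d$region[1],
               motif = d$motif[1], windows = d$windows[1],
               direction = d3$direction[1],
               supporting_methods = paste(sup, collapse = ","),
               min_temporal_fdr = min(d$temporal_fdr[d$method %in% sup]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(instance_id = character(), region = character(),
                      motif = character(), windows = character(),
                      direction = character(), supporting_methods = character(),
                      min_temporal_fdr = numeric(), stringsAsFactors = FALSE)
  }
  # duplicate coordinates under different PWMs: keep lowest temporal FDR
  key <- paste(out$region, out$windows)
  out <- out[order(key, out$min_temporal_fdr), ]
  out <- out[!duplicated(paste(out$region, out$windows)), ]
  rownames(out) <- NULL
  class(out) <- c("frs_records", "data.frame")
  out
}

#' Assign main and sub-categories to functional regulatory sites
#'
#' Activating sites are essential when the perturbed sequence is
#' indistinguishable from the scrambled controls (temporal FDR above the
#' threshold, or the MAD test non-significant at every timepoint — the two
#' clauses combined with OR as printed, switchable to AND), otherwise
#' contributing. Dampening sites are silencing when the wild type is
#' indistinguishable from the controls under the same rule, otherwise
#' inhibiting. Mixed-direction sites are retained with an `NA` sub-category.
#'
#' @param frs an `frs_records` data.frame.
#' @param tests the `mpra_tests` object the records came from.
#' @param fdr FDR threshold.
#' @param method perturbation method whose comparisons anchor the
#'   categorization (default 3, the method every FRS must pass).
#' @param clause `"or"` (printed rule) or `"and"`.
#' @return `frs` with an added `sub_category` column.
#' @export
categorize <- function(frs, tests, fdr = 0.05, method = 3L,
                       clause = c("or", "and")) {
  clause <- match.arg(clause)
  comb <- if (clause == "or") `||` else `&&`
  n_tp <- tests$n_timepoints
  sub <- character(nrow(frs))
  for (i in seq_len(nrow(frs))) {
    iid <- frs$instance_id[i]; region <- frs$region[i]
    t_ps <- tests$temporal[tests$temporal$comparison == "PERT_SCRAM" &
                             !is.na(tests$temporal$instance_id) &
                             tests$temporal$instance_id == iid &
                             tests$temporal$method == method, ]
    t_ws <- tests$temporal[tests$temporal$comparison == "WT_SCRAM" &
                             tests$temporal$region == region, ]
    mad_pt <- tests$mad[tests$mad$role == "PERT" &
                          !is.na(tests$mad$instance_id) &
                          tests$mad$instance_id == iid &
                          tests$mad$method == method, ]
    mad_wt <- tests$mad[tests$mad$role == "WT" &
                          tests$mad$seq_id == paste0("WT|", region), ]
    sub[i] <- switch(frs$direction[i],
      activating = if (comb(t_ps$fdr[1] > fdr,
                            sum(mad_pt$fdr > fdr) == n_tp)) {
        "essential"
      } else "contributing",
      dampening = if (comb(t_ws$fdr[1] > fdr,
                           sum(mad_wt$fdr > fdr) == n_tp)) {
        "silencing"
      } else "inhibiting",
      mixed = NA_character_)
  }
  frs$sub_category <- sub
  frs
}

#' Fit activation dynamics of an activating site
#'
#' Ordinary least squares of the absolute perturbation effect
#' (WT - PERT alpha) on the wild-type activity level across timepoints:
#' `delta ~ a + b * WT`. The implied fold-change curve
#' `FC = (1 - b) - a / WT` saturates at high wild-type activity; the fitted
#' intercept and slope are returned as is.
#'
#' @param wt_alpha,pert_alpha per-timepoint alpha values of the wild-type
#'   and perturbed sequence (same length, >= 3 timepoints).
#' @return list with `a` (intercept), `b` (slope), `r_squared`, and the `lm`
#'   fit.
#' @export
fit_dynamics <- function(wt_alpha, pert_alpha) {
  stopifnot(length(wt_alpha) == length(pert_alpha))
  if (length(wt_alpha) < 3) stop("need at least 3 timepoints to fit dynamics")
  delta <- wt_alpha - pert_alpha
  fit <- stats::lm(delta ~ wt_alpha)
  list(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]),
       r_squared = suppressWarnings(summary(fit)$r.squared), fit = fit)
}
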