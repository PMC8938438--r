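#' Assign barcodes to sequences from association reads
#'
#' A barcode is confidently assigned to the sequence with the most supporting
#' UMIs when that winner has at least `min_umis` UMIs and carries at least
#' `min_frac` of all the barcode's UMIs (both bounds inclusive); otherwise
#' the barcode is ambiguous. Ties are never assigned.
#'
#' @param read_table data.frame with columns `barcode`, `sequence_id`,
#'   `umi_count` (one row per observed barcode-sequence support).
#' @param min_umis minimum winner UMI count (default 3).
#' @param min_frac minimum winner majority fraction (default 0.8).
#' @return data.frame of class `barcode_assignments` with columns `barcode`,
#'   `sequence_id`, `n_umis`, `majority_fraction`, `status`; summary
#'   fractions attached as attribute `summary`.
#' @export
assign_barcodes <- function(read_table, min_umis = 3, min_frac = 0.8) {
  need <- c("barcode", "sequence_id", "umi_count")
  stopifnot(all(need %in% names(read_table)))
  bad <- !stats::complete.cases(read_table[, need]) |
    !is.finite(read_table$umi_count) | read_table$umi_count < 0
  if (any(bad)) {
    warning(sum(bad), " malformed association rows skipped")
    read_table <- read_table[!bad, ]
  }
  agg <- stats::aggregate(umi_count ~ barcode + sequence_id, read_table, sum)
  total <- stats::aggregate(umi_count ~ barcode, agg, sum)
  names(total)[2] <- "total"
  # winner per barcode: max UMIs, flag exact ties
  ord <- agg[order(agg$barcode, -agg$umi_count), ]
  first <- !duplicated(ord$barcode)
  win <- ord[first, ]
  rest <- ord[!first, ]
  second <- rest[!duplicated(rest$barcode), ]
  tied <- win$barcode %in% second$barcode[
    second$umi_count == win$umi_count[match(second$barcode, win$barcode)]]
  win <- merge(win, total, by = "barcode")
  win$majority_fraction <- win$umi_count / win$total
  assigned <- !tied &
    win$umi_count >= min_umis &
    win$majority_fraction >= min_frac - 1e-12
  out <- data.frame(barcode = win$barcode, sequence_id = win$sequence_id,
                    n_umis = win$umi_count,
                    majority_fraction = win$majority_fraction,
                    status = ifelse(assigned, "assigned", "ambiguous"),
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- c(n_barcodes = nrow(out),
                            frac_assigned = mean(assigned),
                            frac_ambiguous = mean(!assigned))
  class(out) <- c("barcode_assignments", "data.frame")
  out
}

#' Tabulate MPRA counts against confident barcode assignments
#'
#' Keeps only rows whose barcode is confidently assigned (exact string match,
#' no error correction) and reports, per library (timepoint x replicate),
#' the fractions of counted barcodes that were assigned, ambiguous, or never
#' observed in the association run.
#'
#' @param mpra_reads count data.frame with columns `barcode`, `timepoint`,
#'   `replicate`, `dna`, `rna` (a `sequence_id` column, if present, is
#'   replaced by the association's assignment).
#' @param assignments result of [assign_barcodes()].
#' @return list with `counts` (an `mpra_counts` data.frame restricted to
#'   assigned barcodes) and `class_stats` (per-library barcode-class
#'   fractions).
#' @export
count_barcodes <- function(mpra_reads, assignments) {
  amb <- assignments$barcode[assignments$status == "ambiguous"]
  asg <- assignments[assignments$status == "assigned", ]
  cls <- ifelse(mpra_reads$barcode %in% asg$barcode, "assigned",
                ifelse(mpra_reads$barcode %in% amb, "ambiguous", "unobserved"))
  lib <- interaction(mpra_reads$timepoint, mpra_reads$replicate, drop = TRUE)
  tab <- table(lib, factor(cls, c("assigned", "ambiguous", "unobserved")))
  class_stats <- data.frame(library = rownames(tab),
                            as.data.frame.matrix(sweep(tab, 1, rowSums(tab), "/")),
                            stringsAsFactors = FALSE)
  counts <- mpra_reads[cls == "assigned", ]
  counts$sequence_id <- asg$sequence_id[match(counts$barcode, asg$barcode)]
  rownames(counts) <- NULL
  class(counts) <- c("mpra_counts", "data.frame")
  list(counts = counts, class_stats = class_stats)
}

#' Filter counts to barcodes present in paired DNA and RNA libraries
#'
#' A barcode is retained within a (timepoint, replicate) pair only when it
#' has a positive count in both the DNA and the RNA library of that pair;
#' the rule is evaluated per pair, not globally, so a barcode can survive in
#' some samples and be dropped in others.
#'
#' @param counts an `mpra_counts` data.frame.
#' @return The filtered `mpra_counts`.
#' @export
filter_counts <- function(counts) {
  keep <- counts$dna > 0 & counts$rna > 0
  pairs <- unique(counts[, c("timepoint", "replicate")])
  for (i in seq_len(nrow(pairs))) {
    sel <- counts$timepoint == pairs$timepoint[i] &
      counts$replicate == pairs$replicate[i]
    if (!any(keep[sel])) {
      warning("no barcodes retained for ", pairs$timepoint[i], "/",
              pairs$replicate[i])
    }
  }
  out <- counts[keep, ]
  rownames(out) <- NULL
  class(out) <- c("mpra_counts", "data.frame")
  out
}
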