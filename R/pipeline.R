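#' Choose non-overlapping instance pairs for double perturbation
#'
#' Picks up to `n_pairs` selected regions carrying at least two selected
#' single-hit instances with non-overlapping windows and pairs the first two
#' such instances per region.
#'
#' @param selection a `design_selection`.
#' @param hits motif-hit table.
#' @param n_pairs maximum number of pairs.
#' @param seed integer seed (region sampling).
#' @return data.frame with `pair_id`, `region`, `instance1`, `instance2` (or
#'   zero rows).
#' @export
choose_pairs <- function(selection, hits, n_pairs, seed = 1L) {
  if (n_pairs < 1) {
    return(data.frame(pair_id = character(), region = character(),
                      instance1 = character(), instance2 = character()))
  }
  with_seed(seed, {
    out <- list()
    for (region in sample(selection$regions)) {
      ed <- selection$edges[selection$edges$region == region, ]
      h <- hits[hits$region_id == region & hits$motif_id %in% ed$motif, ]
      h <- h[!duplicated(h$motif_id), ]        # one hit per motif
      if (nrow(h) < 2) next
      found <- FALSE
      for (i in seq_len(nrow(h) - 1)) {
        for (j in (i + 1):nrow(h)) {
          if (h$start[i] < h$end[j] && h$start[j] < h$end[i]) next
          out[[length(out) + 1L]] <- data.frame(
            region = region,
            instance1 = hit_instance_id(region, h$motif_id[i], h$start[i], h$end[i]),
            instance2 = hit_instance_id(region, h$motif_id[j], h$start[j], h$end[j]),
            stringsAsFactors = FALSE)
          found <- TRUE
          break
        }
        if (found) break
      }
      if (length(out) >= n_pairs) break
    }
    if (!length(out)) {
      return(data.frame(pair_id = character(), region = character(),
                        instance1 = character(), instance2 = character()))
    }
    res <- do.call(rbind, out)
    res <- data.frame(pair_id = sprintf("pair%03d", seq_len(nrow(res))), res,
                      stringsAsFactors = FALSE)
    res
  })
}

run_pair_tests <- function(counts, manifest, pairs, sf) {
  if (is.null(pairs) || !nrow(pairs)) return(NULL)
  man <- as.data.frame(manifest)
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    for (m in 1:3) {
      dbl <- man[man$category == "DBL" & man$pair_id == pairs$pair_id[k] &
                   man$method == m, ]
      s1 <- man[man$category == "PERT" & man$instance_id == pairs$instance1[k] &
                  man$method == m, ]
      s2 <- man[man$category == "PERT" & man$instance_id == pairs$instance2[k] &
                  man$method == m, ]
      wt <- man[man$category == "WT" & man$region == pairs$region[k], ]
      ids <- c(wt$seq_id, s1$seq_id, s2$seq_id, dbl$seq_id)
      sub <- counts[counts$sequence_id %in% ids, ]
      sub$pert1 <- sub$sequence_id %in% c(s1$seq_id, dbl$seq_id)
      sub$pert2 <- sub$sequence_id %in% c(s2$seq_id, dbl$seq_id)
      ti <- tryCatch(test_interaction(sub, sf = sf), error = function(e) NULL)
      if (is.null(ti)) next
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = pairs$pair_id[k], region = pairs$region[k],
        instance1 = pairs$instance1[k], instance2 = pairs$instance2[k],
        windows1 = parse_instance(pairs$instance1[k])$windows,
        windows2 = parse_instance(pairs$instance2[k])$windows,
        method = m, gamma = ti$gamma, pvalue = ti$pvalue,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Run the full synthetic perturbation-MPRA pipeline
#'
#' Orchestrates every stage end to end — graph simulation, ILP design
#' selection, oligo library construction, barcode association, count
#' simulation and filtering, activity quantification, four-filter FRS
#' calling with categorization, activation-dynamics fits and pair
#' interaction tests — writing each stage's tables under `out_dir` plus a
#' JSON summary. Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param n_pairs number of double-perturbation pairs to design.
#' @param fdr FDR threshold used throughout.
#' @param backend MILP solver backend, see [solve_design()].
#' @param params [design_params()] for the selection ILP.
#' @return Invisibly, a list with every stage's objects (`graph`,
#'   `selection`, `constraint_report`, `manifest`, `assignments`, `counts`,
#'   `tests`, `filters`, `frs`, `pair_results`, `dynamics`, `summary`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("mpra_run_"),
                         n_pairs = 4, fdr = 0.05, backend = "auto",
                         params = design_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[perturbMPRA] ", sprintf(...))

  log_stage("simulate: graph (%d regions, %d motifs, %d properties, seed %d)",
            config$n_regions, config$n_motifs, config$n_properties, config$seed)
  graph <- generate_graph(config)
  write_tripartite_graph(graph, file.path(out_dir, "graph"))
  seqs <- generate_sequences(graph, config)

  log_stage("design: ILP over %d candidate instances", nrow(graph$instances))
  model <- build_ilp(graph, params)
  selection <- solve_design(model, backend = backend)
  if (selection$status == "infeasible") {
    stop("design stage failed: ILP infeasible (",
         selection$infeasible_hint %||% "unknown family", ")")
  }
  report <- check_constraints(graph, selection, params)
  write_tsv(selection$edges, file.path(out_dir, "selection.tsv"))
  jsonlite::write_json(report, file.path(out_dir, "constraint_report.json"),
                       dataframe = "rows", auto_unbox = TRUE)

  log_stage("library: non-motif derivation and oligo construction")
  sel_hits <- merge(seqs$hits, selection$edges,
                    by.x = c("region_id", "motif_id"),
                    by.y = c("region", "motif"))
  nm <- derive_nonmotif_sequences(
    background = unname(seqs$sequences),
    scanner = make_pwm_scanner(seqs$pwms),
    max_width = max(vapply(seqs$pwms, function(p) p$width, integer(1))),
    contexts = sel_hits[, c("region_id", "start", "end")],
    sequences = seqs$sequences, n_candidates = 1000, max_contexts = 5,
    seed = substream_seed(config$seed, "nonmotif"))
  pairs <- choose_pairs(selection, seqs$hits, n_pairs,
                        seed = substream_seed(config$seed, "pairs"))
  manifest <- build_library(selection, seqs$sequences, seqs$hits,
                            nm$sequences, config, pairs = pairs)
  write_library(manifest, file.path(out_dir, "library.fa"),
                file.path(out_dir, "library.tsv"))

  log_stage("truth + counts: %d sequences x %d barcodes", nrow(manifest),
            config$barcodes_per_sequence)
  single <- manifest$category == "PERT" &
    !grepl("+", manifest$instance_id, fixed = TRUE)
  instances <- unique(data.frame(
    instance_id = manifest$instance_id[single],
    region = manifest$region[single],
    motif = parse_instance(manifest$instance_id[single])$motif,
    stringsAsFactors = FALSE))
  # composite (joint) instances inherit component effects; register them too
  comp <- unique(manifest$instance_id[manifest$category == "PERT" & !single])
  comp_parts <- unique(unlist(strsplit(comp, "+", fixed = TRUE)))
  extra <- setdiff(comp_parts, instances$instance_id)
  if (length(extra)) {
    instances <- rbind(instances,
                       data.frame(instance_id = extra,
                                  region = parse_instance(extra)$region,
                                  motif = parse_instance(extra)$motif))
  }
  truth <- generate_truth(instances, config, pairs = pairs)
  library <- assign_sim_barcodes(manifest, config)
  assoc_reads <- simulate_association_reads(library, config)
  assignments <- assign_barcodes(assoc_reads)
  raw_counts <- simulate_counts(truth, library, config)
  cb <- count_barcodes(raw_counts, assignments)
  counts <- filter_counts(cb$counts)
  write_tsv(counts, file.path(out_dir, "counts.tsv"))

  log_stage("quantify + classify: %d retained count rows", nrow(counts))
  sf <- compute_size_factors(counts)
  tests <- run_mpra_tests(counts, manifest, sf)
  filters <- apply_filters(tests, fdr = fdr)
  frs <- categorize(consensus_frs(filters), tests, fdr = fdr)
  write_tsv(filters, file.path(out_dir, "filters.tsv"))
  write_tsv(frs, file.path(out_dir, "frs.tsv"))

  dyn <- list()
  act <- frs[frs$direction == "activating" & !is.na(frs$sub_category), ]
  for (i in seq_len(nrow(act))) {
    wt_id <- paste0("WT|", act$region[i])
    p3 <- manifest$seq_id[manifest$category == "PERT" & manifest$method == 3 &
                            manifest$instance_id == act$instance_id[i]]
    a <- tests$alpha_tp
    wt_a <- a$alpha[a$sequence_id == wt_id]
    pt_a <- a$alpha[a$sequence_id == p3]
    if (length(wt_a) >= 3 && length(wt_a) == length(pt_a)) {
      d <- fit_dynamics(wt_a, pt_a)
      dyn[[act$instance_id[i]]] <- data.frame(
        instance_id = act$instance_id[i], a = d$a, b = d$b,
        r_squared = d$r_squared, stringsAsFactors = FALSE)
    }
  }
  dynamics <- if (length(dyn)) do.call(rbind, dyn) else NULL
  if (!is.null(dynamics)) {
    rownames(dynamics) <- NULL
    write_tsv(dynamics, file.path(out_dir, "dynamics.tsv"))
  }

  pair_tests <- run_pair_tests(counts, manifest, pairs, sf)
  pair_results <- if (!is.null(pair_tests)) {
    classify_pairs(pair_tests, filters, fdr = fdr)
  } else NULL
  if (!is.null(pair_results)) {
    write_tsv(pair_results, file.path(out_dir, "pairs.tsv"))
  }

  summary <- list(
    n_regions_selected = length(selection$regions),
    n_motifs_selected = length(selection$motifs),
    n_instances_selected = nrow(selection$edges),
    n_sequences_designed = nrow(manifest),
    constraints_satisfied = all(report$satisfied),
    association = as.list(attr(assignments, "summary")),
    n_frs = nrow(frs),
    frs_by_direction = as.list(table(frs$direction)),
    frs_by_category = as.list(table(frs$sub_category)),
    pair_labels = if (!is.null(pair_results)) {
      as.list(table(pair_results$label))
    } else NULL,
    median_dynamics_r2 = if (!is.null(dynamics)) {
      stats::median(dynamics$r_squared)
    } else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_stage("done: %d FRS (%s)", nrow(frs),
            paste(names(summary$frs_by_direction),
                  unlist(summary$frs_by_direction), collapse = ", "))

  invisible(list(graph = graph, selection = selection,
                 constraint_report = report, sequences = seqs,
                 nonmotif = nm, manifest = manifest, truth = truth,
                 assignments = assignments, counts = counts, tests = tests,
                 filters = filters, frs = frs, dynamics = dynamics,
                 pair_tests = pair_tests, pair_results = pair_results,
                 summary = summary, out_dir = out_dir))
}

#' Validate pipeline input files
#'
#' Schema and coordinate-convention checks for the TSV/FASTA inputs: motif
#' hit tables need 0-based half-open coordinates with `end > start`, count
#' tables need non-negative integer counts, association tables positive UMI
#' counts, and barcodes are checked against the configured length.
#'
#' @param paths named list with any of `hits`, `counts`, `association`,
#'   `fasta`.
#' @param barcode_length expected barcode length (warning level).
#' @return data.frame report (`file`, `level`, `message`); zero rows when
#'   everything is well-formed.
#' @export
validate_inputs <- function(paths, barcode_length = 15L) {
  report <- list()
  note <- function(file, level, message) {
    report[[length(report) + 1L]] <<- data.frame(
      file = file, level = level, message = message, stringsAsFactors = FALSE)
  }
  if (!is.null(paths$hits)) {
    h <- read_tsv(paths$hits)
    need <- c("region_id", "motif_id", "start", "end", "strand")
    if (!all(need %in% names(h))) {
      note(paths$hits, "error", paste("missing columns:",
                                      paste(setdiff(need, names(h)), collapse = ", ")))
    } else {
      if (any(h$end <= h$start)) {
        note(paths$hits, "error",
             sprintf("%d hits with end <= start", sum(h$end <= h$start)))
      }
      if (any(h$start < 0)) note(paths$hits, "error", "negative start coordinates")
      if (!all(h$strand %in% c("+", "-"))) {
        note(paths$hits, "error", "strand must be + or -")
      }
    }
  }
  if (!is.null(paths$counts)) {
    cts <- read_tsv(paths$counts)
    need <- c("barcode", "sequence_id", "timepoint", "replicate", "dna", "rna")
    if (!all(need %in% names(cts))) {
      note(paths$counts, "error", paste("missing columns:",
                                        paste(setdiff(need, names(cts)), collapse = ", ")))
    } else {
      if (any(cts$dna < 0 | cts$rna < 0)) {
        note(paths$counts, "error", "negative counts")
      }
      bad_len <- nchar(cts$barcode) != barcode_length
      if (any(bad_len)) {
        note(paths$counts, "warning",
             sprintf("%d barcodes differ from configured length %d",
                     sum(bad_len), barcode_length))
      }
    }
  }
  if (!is.null(paths$association)) {
    a <- read_tsv(paths$association)
    need <- c("barcode", "sequence_id", "umi_count")
    if (!all(need %in% names(a))) {
      note(paths$association, "error", paste("missing columns:",
                                             paste(setdiff(need, names(a)), collapse = ", ")))
    } else if (any(a$umi_count <= 0)) {
      note(paths$association, "error", "non-positive UMI counts")
    }
  }
  if (!is.null(paths$fasta)) {
    ss <- tryCatch(Biostrings::readDNAStringSet(paths$fasta),
                   error = function(e) NULL)
    if (is.null(ss)) {
      note(paths$fasta, "error", "unreadable FASTA")
    } else if (length(unique(Biostrings::width(ss))) > 1) {
      note(paths$fasta, "warning", "sequences of unequal length")
    }
  }
  if (!length(report)) {
    return(data.frame(file = character(), level = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, report)
}
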