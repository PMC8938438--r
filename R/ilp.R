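#' Design-selection ILP parameters
#'
#' Bounds of the selection program: every property must be covered by at
#' least `min_motifs_per_property` selected motifs and
#' `min(min_regions_per_property, degree)` selected regions; every selected
#' region carries at least `min(min_motifs_per_region, degree)` selected
#' motifs; every selected motif is placed in at least
#' `min(min_regions_per_motif, degree)` selected regions; at most
#' `max_motifs_per_tf` motifs per TF group, every hand-picked TF represented;
#' at least `region_fraction` of all regions used; selected edges outnumber
#' selected low-confidence edges `lowconf_mult`-fold; selected high-degree
#' motifs outnumber the rest `tb_ratio`-fold. The objective charges 1 per
#' selected region plus `edge_cost` per selected instance (one synthesized
#' oligo per perturbation method).
#'
#' @param min_motifs_per_property,min_regions_per_property,min_motifs_per_region,min_regions_per_motif,max_motifs_per_tf,region_fraction,lowconf_mult,tb_ratio,edge_cost numeric bounds as described.
#' @return A list of class `design_params`.
#' @export
design_params <- function(min_motifs_per_property = 12,
                          min_regions_per_property = 17,
                          min_motifs_per_region = 3,
                          min_regions_per_motif = 20,
                          max_motifs_per_tf = 2,
                          region_fraction = 0.4,
                          lowconf_mult = 5,
                          tb_ratio = 1.5,
                          edge_cost = 3) {
  p <- as.list(environment())
  class(p) <- "design_params"
  p
}

ILP_FAMILIES <- c("property_motifs", "property_regions", "region_motifs",
                  "motif_regions", "edge_coupling", "tf_group_max",
                  "hand_picked", "region_fraction", "low_confidence",
                  "high_degree_balance")

#' Build the design-selection integer linear program
#'
#' Encodes the tripartite graph and [design_params()] bounds as a 0/1 linear
#' program over region indicators, motif indicators and instance-edge
#' indicators. Edge indicators are coupled to their endpoints from below
#' (`e >= theta_t + theta_r - 1`, as the objective pressure alone would
#' suffice at the optimum) and, to make feasibility solver-independent, also
#' from above (`e <= theta_t`, `e <= theta_r`). Constraint families that are
#' vacuous on the given graph (empty property layer, no hand-picked TFs, no
#' low-confidence edges) are omitted and recorded in `$omitted`.
#'
#' @param graph a [tripartite_graph()].
#' @param params a [design_params()].
#' @return An object of class `ilp_model` (sparse triplet representation).
#' @export
build_ilp <- function(graph, params = design_params()) {
  nR <- length(graph$regions); nT <- length(graph$motifs)
  nE <- nrow(graph$instances)
  idx_r <- stats::setNames(seq_len(nR), graph$regions)
  idx_t <- stats::setNames(nR + seq_len(nT), graph$motifs)
  idx_e <- nR + nT + seq_len(nE)
  nvar <- nR + nT + nE
  obj <- c(rep(1, nR), rep(0, nT), rep(params$edge_cost, nE))

  ti <- list(); tj <- list(); tx <- list()
  row_lb <- numeric(0); row_ub <- numeric(0); row_family <- character(0)
  omitted <- character(0)
  add_row <- function(j, x, lb, ub, family) {
    ti[[length(ti) + 1L]] <<- rep(length(row_lb) + 1L, length(j))
    tj[[length(tj) + 1L]] <<- j
    tx[[length(tx) + 1L]] <<- x
    row_lb <<- c(row_lb, lb); row_ub <<- c(row_ub, ub)
    row_family <<- c(row_family, family)
  }
  INF <- 1e30

  degR_t <- deg_R_motif(graph)
  degT_r <- deg_T_region(graph)

  if (length(graph$properties)) {
    for (p in graph$properties) {
      tm <- graph$motif_props$motif[graph$motif_props$property == p]
      add_row(unname(idx_t[tm]), rep(1, length(tm)),
              params$min_motifs_per_property, INF, "property_motifs")
      rg <- graph$region_props$region[graph$region_props$property == p]
      add_row(unname(idx_r[rg]), rep(1, length(rg)),
              min(params$min_regions_per_property, length(rg)), INF,
              "property_regions")
    }
  } else {
    omitted <- c(omitted, "property_motifs", "property_regions")
  }

  for (r in graph$regions) {          # selected region carries >= min(3, deg) motifs
    tm <- graph$instances$motif[graph$instances$region == r]
    need <- min(params$min_motifs_per_region, degT_r[[r]])
    if (need > 0) {
      add_row(c(unname(idx_t[tm]), unname(idx_r[r])),
              c(rep(1, length(tm)), -need), 0, INF, "region_motifs")
    }
  }
  for (t in graph$motifs) {           # selected motif placed in >= min(20, deg) regions
    rg <- graph$instances$region[graph$instances$motif == t]
    need <- min(params$min_regions_per_motif, degR_t[[t]])
    if (need > 0) {
      add_row(c(unname(idx_r[rg]), unname(idx_t[t])),
              c(rep(1, length(rg)), -need), 0, INF, "motif_regions")
    }
  }
  for (k in seq_len(nE)) {            # e coupled to its endpoints
    jt <- unname(idx_t[graph$instances$motif[k]])
    jr <- unname(idx_r[graph$instances$region[k]])
    add_row(c(idx_e[k], jt, jr), c(1, -1, -1), -1, INF, "edge_coupling")
    add_row(c(idx_e[k], jt), c(1, -1), -INF, 0, "edge_coupling")
    add_row(c(idx_e[k], jr), c(1, -1), -INF, 0, "edge_coupling")
  }
  for (g in unique(graph$tf_group)) {
    tm <- graph$motifs[graph$tf_group == g]
    add_row(unname(idx_t[tm]), rep(1, length(tm)),
            -INF, params$max_motifs_per_tf, "tf_group_max")
  }
  if (length(graph$hand_picked)) {
    for (g in graph$hand_picked) {
      tm <- graph$motifs[graph$tf_group == g]
      add_row(unname(idx_t[tm]), rep(1, length(tm)), 1, INF, "hand_picked")
    }
  } else omitted <- c(omitted, "hand_picked")

  add_row(seq_len(nR), rep(1, nR), params$region_fraction * nR, INF,
          "region_fraction")

  if (any(graph$instances$low_confidence)) {
    coef <- ifelse(graph$instances$low_confidence, 1 - params$lowconf_mult, 1)
    add_row(idx_e, coef, 0, INF, "low_confidence")
  } else omitted <- c(omitted, "low_confidence")

  tb <- high_degree_motifs(graph)
  coef_t <- ifelse(graph$motifs %in% tb, 1, -params$tb_ratio)
  add_row(unname(idx_t[graph$motifs]), coef_t, 0, INF, "high_degree_balance")

  model <- list(graph = graph, params = params, nvar = nvar, obj = obj,
                idx_r = idx_r, idx_t = idx_t, idx_e = idx_e,
                A = list(i = unlist(ti), j = unlist(tj), x = unlist(tx)),
                row_lb = row_lb, row_ub = row_ub, row_family = row_family,
                omitted = omitted)
  class(model) <- "ilp_model"
  model
}

#' @export
print.ilp_model <- function(x, ...) {
  cat(sprintf("Design ILP: %d binary variables, %d constraint rows\n",
              x$nvar, length(x$row_lb)))
  if (length(x$omitted)) {
    cat("  omitted vacuous families:", paste(x$omitted, collapse = ", "), "\n")
  }
  invisible(x)
}

new_selection <- function(graph, theta_r, theta_t, objective, status,
                          gap = 0, infeasible_hint = NULL) {
  sel_edges <- graph$instances[graph$instances$motif %in% graph$motifs[theta_t] &
                               graph$instances$region %in% graph$regions[theta_r], ]
  rownames(sel_edges) <- NULL
  out <- list(regions = graph$regions[theta_r], motifs = graph$motifs[theta_t],
              edges = sel_edges, objective = objective, status = status,
              gap = gap, infeasible_hint = infeasible_hint)
  class(out) <- "design_selection"
  out
}

#' @export
print.design_selection <- function(x, ...) {
  cat(sprintf("Design selection [%s]: %d regions, %d motifs, %d instances; objective %s\n",
              x$status, length(x$regions), length(x$motifs), nrow(x$edges),
              format(x$objective)))
  if (!is.null(x$infeasible_hint)) {
    cat("  infeasibility traced to family:", x$infeasible_hint, "\n")
  }
  invisible(x)
}

python_available <- function() nzchar(Sys.which("python"))

solve_highs <- function(model, time_limit) {
  script <- system.file("python", "solve_milp.py", package = "perturbMPRA")
  if (!nzchar(script)) stop("bundled MILP solver script not found")
  inp <- tempfile(fileext = ".json"); out <- tempfile(fileext = ".json")
  on.exit(unlink(c(inp, out)))
  jsonlite::write_json(list(nvar = model$nvar, obj = model$obj, A = model$A,
                            row_lb = model$row_lb, row_ub = model$row_ub,
                            time_limit = time_limit),
                       inp, auto_unbox = TRUE, digits = NA)
  ret <- system2("python", c(shQuote(script), shQuote(inp), shQuote(out)),
                 stdout = TRUE, stderr = TRUE)
  if (!file.exists(out)) {
    stop("MILP backend failed: ", paste(ret, collapse = "\n"))
  }
  jsonlite::read_json(out, simplifyVector = TRUE)
}

solve_enumerate <- function(model) {
  graph <- model$graph; params <- model$params
  nR <- length(graph$regions); nT <- length(graph$motifs)
  if (nR + nT > 16) {
    stop("exhaustive backend limited to graphs with <= 16 region+motif nodes")
  }
  best <- NULL; best_obj <- Inf
  for (mask in 0:(2^(nR + nT) - 1)) {
    bits <- as.logical(bitwAnd(bitwShiftR(mask, 0:(nR + nT - 1)), 1L))
    theta_r <- bits[seq_len(nR)]; theta_t <- bits[nR + seq_len(nT)]
    sel <- new_selection(graph, theta_r, theta_t, NA_real_, "candidate")
    rep <- check_constraints(graph, sel, params)
    if (all(rep$satisfied)) {
      obj <- sum(theta_r) + params$edge_cost * nrow(sel$edges)
      if (obj < best_obj) {
        best_obj <- obj
        best <- new_selection(graph, theta_r, theta_t, obj, "optimal")
      }
    }
  }
  if (is.null(best)) {
    return(new_selection(graph, rep(FALSE, nR), rep(FALSE, nT), NA_real_,
                         "infeasible"))
  }
  best
}

#' Solve the design-selection ILP
#'
#' The default backend hands the model to a branch-and-bound MILP solver
#' (HiGHS, through the bundled scipy front end); the `"enumerate"` backend
#' searches all region/motif indicator assignments exhaustively (edge
#' indicators are forced by their endpoints) and is exact on small graphs.
#' Infeasible models are probed by re-solving with one constraint family
#' dropped at a time; the first family whose removal restores feasibility is
#' reported as the likely cause.
#'
#' @param model an `ilp_model` from [build_ilp()].
#' @param backend `"auto"` (HiGHS when python is on the PATH, otherwise
#'   exhaustive), `"highs"` or `"enumerate"`.
#' @param time_limit solver time limit in seconds.
#' @param probe_infeasible trace infeasibility to a constraint family.
#' @return A `design_selection` with selected regions, motifs, instance
#'   edges, objective value, solver status and optimality gap.
#' @export
solve_design <- function(model, backend = c("auto", "highs", "enumerate"),
                         time_limit = 120, probe_infeasible = TRUE) {
  backend <- match.arg(backend)
  if (backend == "auto") {
    backend <- if (python_available()) "highs" else "enumerate"
  }
  if (backend == "enumerate") return(solve_enumerate(model))

  res <- solve_highs(model, time_limit)
  graph <- model$graph
  if (identical(res$status, "infeasible") || is.null(res$x)) {
    hint <- NULL
    if (probe_infeasible) hint <- probe_infeasibility(model, time_limit)
    sel <- new_selection(graph, rep(FALSE, length(graph$regions)),
                         rep(FALSE, length(graph$motifs)), NA_real_,
                         "infeasible", infeasible_hint = hint)
    return(sel)
  }
  x <- as.integer(res$x)
  theta_r <- x[model$idx_r] == 1L
  theta_t <- x[model$idx_t] == 1L
  status <- res$status
  if (identical(status, "time_limit")) {
    warning("solver hit the time limit; returning incumbent with gap ",
            format(res$gap))
  }
  new_selection(graph, theta_r, theta_t, res$objective, status,
                gap = res$gap %||% 0)
}

probe_infeasibility <- function(model, time_limit) {
  for (fam in unique(model$row_family)) {
    keep <- model$row_family != fam
    sub <- model
    keep_rows <- which(keep)
    tri_keep <- model$A$i %in% keep_rows
    remap <- match(model$A$i[tri_keep], keep_rows)
    sub$A <- list(i = remap, j = model$A$j[tri_keep], x = model$A$x[tri_keep])
    sub$row_lb <- model$row_lb[keep]; sub$row_ub <- model$row_ub[keep]
    sub$row_family <- model$row_family[keep]
    res <- tryCatch(solve_highs(sub, time_limit), error = function(e) NULL)
    if (!is.null(res) && !identical(res$status, "infeasible")) return(fam)
  }
  NULL
}

#' Verify a design selection against the raw graph
#'
#' Recomputes every constraint family from the graph's edge lists and the
#' selection alone — no solver state is consulted — and reports a satisfied
#' flag and worst-case margin (minimum slack) per family. Families that do
#' not apply to the graph (no properties, no hand-picked TFs, no
#' low-confidence edges) are reported satisfied with margin `NA`.
#'
#' @param graph a [tripartite_graph()].
#' @param selection a `design_selection`.
#' @param params the [design_params()] the selection is checked against.
#' @return data.frame of class `constraint_report` with columns `family`,
#'   `satisfied`, `margin`, `detail`.
#' @export
check_constraints <- function(graph, selection, params = design_params()) {
  sel_r <- graph$regions %in% selection$regions
  sel_t <- graph$motifs %in% selection$motifs
  names(sel_r) <- graph$regions; names(sel_t) <- graph$motifs
  inst <- graph$instances
  forced <- inst[sel_t[inst$motif] & sel_r[inst$region], c("motif", "region")]

  out <- data.frame(family = ILP_FAMILIES, satisfied = TRUE, margin = NA_real_,
                    detail = "", stringsAsFactors = FALSE)
  set_fam <- function(fam, margin, detail = "") {
    i <- match(fam, out$family)
    out$margin[i] <<- margin
    out$satisfied[i] <<- is.na(margin) || margin >= -1e-9
    out$detail[i] <<- detail
  }

  if (length(graph$properties)) {
    mp <- vapply(graph$properties, function(p) {
      tm <- graph$motif_props$motif[graph$motif_props$property == p]
      sum(sel_t[tm]) - params$min_motifs_per_property
    }, numeric(1))
    set_fam("property_motifs", min(mp),
            sprintf("worst property: %s", graph$properties[which.min(mp)]))
    rp <- vapply(graph$properties, function(p) {
      rg <- graph$region_props$region[graph$region_props$property == p]
      sum(sel_r[rg]) - min(params$min_regions_per_property, length(rg))
    }, numeric(1))
    set_fam("property_regions", min(rp),
            sprintf("worst property: %s", graph$properties[which.min(rp)]))
  }

  degT_r <- deg_T_region(graph); degR_t <- deg_R_motif(graph)
  if (any(sel_r)) {
    rm <- vapply(names(sel_r)[sel_r], function(r) {
      tm <- inst$motif[inst$region == r]
      sum(sel_t[tm]) - min(params$min_motifs_per_region, degT_r[[r]])
    }, numeric(1))
    set_fam("region_motifs", min(rm),
            sprintf("worst region: %s", names(rm)[which.min(rm)]))
  }
  if (any(sel_t)) {
    mr <- vapply(names(sel_t)[sel_t], function(t) {
      rg <- inst$region[inst$motif == t]
      sum(sel_r[rg]) - min(params$min_regions_per_motif, degR_t[[t]])
    }, numeric(1))
    set_fam("motif_regions", min(mr),
            sprintf("worst motif: %s", names(mr)[which.min(mr)]))
  }

  key <- function(d) paste(d$motif, d$region)
  mismatch <- length(union(setdiff(key(forced), key(selection$edges)),
                           setdiff(key(selection$edges), key(forced))))
  set_fam("edge_coupling", -mismatch,
          if (mismatch) sprintf("%d edges differ from forced set", mismatch) else "")

  grp <- split(sel_t, graph$tf_group)
  set_fam("tf_group_max",
          min(vapply(grp, function(v) params$max_motifs_per_tf - sum(v),
                     numeric(1))))
  if (length(graph$hand_picked)) {
    hp <- vapply(graph$hand_picked,
                 function(g) sum(sel_t[graph$tf_group == g]) - 1, numeric(1))
    set_fam("hand_picked", min(hp),
            sprintf("worst TF: %s", graph$hand_picked[which.min(hp)]))
  }
  set_fam("region_fraction",
          sum(sel_r) - params$region_fraction * length(graph$regions))
  if (any(inst$low_confidence)) {
    low <- inst$low_confidence[sel_t[inst$motif] & sel_r[inst$region]]
    set_fam("low_confidence", length(low) - params$lowconf_mult * sum(low))
  }
  tb <- high_degree_motifs(graph)
  set_fam("high_degree_balance",
          sum(sel_t[tb]) - params$tb_ratio * sum(sel_t[setdiff(graph$motifs, tb)]))

  class(out) <- c("constraint_report", "data.frame")
  out
}

#' Summarize a selection with the quantities the design bounds govern
#'
#' @param graph a [tripartite_graph()].
#' @param selection a `design_selection`.
#' @return list with per-motif selected-region counts, per-property selected
#'   motif/region counts, per-region selected-motif counts, the selected
#'   region fraction and the selected high-degree motif fraction.
#' @export
selection_summary <- function(graph, selection) {
  ed <- selection$edges
  regions_per_motif <- vapply(selection$motifs,
                              function(t) sum(ed$motif == t), integer(1))
  motifs_per_region <- vapply(selection$regions,
                              function(r) length(unique(ed$motif[ed$region == r])),
                              integer(1))
  motifs_per_property <- if (length(graph$properties)) {
    vapply(graph$properties, function(p) {
      sum(graph$motif_props$motif[graph$motif_props$property == p] %in%
            selection$motifs)
    }, integer(1))
  } else integer(0)
  regions_per_property <- if (length(graph$properties)) {
    vapply(graph$properties, function(p) {
      sum(graph$region_props$region[graph$region_props$property == p] %in%
            selection$regions)
    }, integer(1))
  } else integer(0)
  tb <- high_degree_motifs(graph)
  list(regions_per_motif = regions_per_motif,
       motifs_per_region = motifs_per_region,
       motifs_per_property = motifs_per_property,
       regions_per_property = regions_per_property,
       region_fraction = length(selection$regions) / length(graph$regions),
       high_degree_fraction = mean(selection$motifs %in% tb))
}
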