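#' Tripartite design graph
#'
#' The design universe for a perturbation MPRA: one node layer of candidate
#' genomic regions, one of DNA-binding motifs, and one of biological
#' properties (temporal chromatin/expression patterns, pathway membership,
#' curated factors). Motif-region edges are the candidate motif instances;
#' each carries a low-confidence flag (membership in the lower-confidence
#' edge subset). Motifs are partitioned into TF groups, a subset of which are
#' hand-picked and must be represented in any selection.
#'
#' @param regions character vector of region ids.
#' @param motifs character vector of motif ids.
#' @param properties character vector of property ids (may be empty).
#' @param instances data.frame with columns `motif`, `region`,
#'   `low_confidence` (logical); the candidate motif instances.
#' @param motif_props data.frame with columns `motif`, `property`.
#' @param region_props data.frame with columns `region`, `property`.
#' @param tf_group named character vector mapping each motif to its TF group.
#' @param hand_picked character vector of TF group names that must be used.
#' @param tb_min minimum region-degree for a motif to count as high-degree
#'   (the broadly-placed subset); default 5.
#' @return An object of class `tripartite_graph`.
#' @export
tripartite_graph <- function(regions, motifs, properties = character(),
                             instances,
                             motif_props = data.frame(motif = character(),
                                                      property = character()),
                             region_props = data.frame(region = character(),
                                                       property = character()),
                             tf_group = NULL, hand_picked = character(),
                             tb_min = 5L) {
  if (is.null(tf_group)) tf_group <- stats::setNames(motifs, motifs)
  stopifnot(all(instances$motif %in% motifs),
            all(instances$region %in% regions),
            all(motif_props$motif %in% motifs),
            all(motif_props$property %in% properties),
            all(region_props$region %in% regions),
            all(region_props$property %in% properties),
            all(motifs %in% names(tf_group)),
            all(hand_picked %in% tf_group))
  if (is.null(instances$low_confidence)) instances$low_confidence <- FALSE
  instances <- unique(instances[, c("motif", "region", "low_confidence")])
  if (anyDuplicated(instances[, c("motif", "region")])) {
    stop("duplicate motif-region edges with conflicting confidence flags")
  }
  g <- list(regions = regions, motifs = motifs, properties = properties,
            instances = instances, motif_props = unique(motif_props),
            region_props = unique(region_props),
            tf_group = tf_group[motifs], hand_picked = hand_picked,
            tb_min = as.integer(tb_min))
  class(g) <- "tripartite_graph"
  g
}

#' @export
print.tripartite_graph <- function(x, ...) {
  cat(sprintf(paste0("Tripartite design graph: %d regions, %d motifs, ",
                     "%d properties, %d edges\n"),
              length(x$regions), length(x$motifs), length(x$properties),
              n_edges(x)))
  cat(sprintf("  instance edges: %d (%.1f%% low-confidence); TF groups: %d (%d hand-picked)\n",
              nrow(x$instances), 100 * mean(x$instances$low_confidence),
              length(unique(x$tf_group)), length(x$hand_picked)))
  invisible(x)
}

#' Total edge count of a tripartite graph (instance + property edges)
#' @param graph a `tripartite_graph`.
#' @return integer.
#' @export
n_edges <- function(graph) {
  nrow(graph$instances) + nrow(graph$motif_props) + nrow(graph$region_props)
}

# region-degree of each motif (number of candidate instance edges)
deg_R_motif <- function(graph) {
  tab <- table(factor(graph$instances$motif, levels = graph$motifs))
  stats::setNames(as.integer(tab), graph$motifs)
}

# motif-degree of each region
deg_T_region <- function(graph) {
  tab <- table(factor(graph$instances$region, levels = graph$regions))
  stats::setNames(as.integer(tab), graph$regions)
}

# motif- and region-degree of each property
deg_property <- function(graph) {
  pm <- table(factor(graph$motif_props$property, levels = graph$properties))
  pr <- table(factor(graph$region_props$property, levels = graph$properties))
  data.frame(property = graph$properties,
             deg_motif = as.integer(pm), deg_region = as.integer(pr),
             stringsAsFactors = FALSE)
}

#' High-degree motif subset
#'
#' Motifs connected to at least `tb_min` regions in the input graph (the
#' threshold is a property of the graph, not of a selection).
#'
#' @param graph a `tripartite_graph`.
#' @return character vector of motif ids.
#' @export
high_degree_motifs <- function(graph) {
  d <- deg_R_motif(graph)
  names(d)[d >= graph$tb_min]
}

#' Write a tripartite graph to a directory of TSV tables
#'
#' Emits `nodes_regions.tsv`, `nodes_motifs.tsv` (with TF group and
#' hand-picked flag), `nodes_properties.tsv` and three edge lists
#' (`edges_instances.tsv`, `edges_motif_props.tsv`, `edges_region_props.tsv`).
#'
#' @param graph a `tripartite_graph`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_tripartite_graph <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(data.frame(region = graph$regions), file.path(dir, "nodes_regions.tsv"))
  write_tsv(data.frame(motif = graph$motifs,
                       tf_group = unname(graph$tf_group),
                       hand_picked = unname(graph$tf_group) %in% graph$hand_picked),
            file.path(dir, "nodes_motifs.tsv"))
  write_tsv(data.frame(property = graph$properties),
            file.path(dir, "nodes_properties.tsv"))
  write_tsv(graph$instances, file.path(dir, "edges_instances.tsv"))
  write_tsv(graph$motif_props, file.path(dir, "edges_motif_props.tsv"))
  write_tsv(graph$region_props, file.path(dir, "edges_region_props.tsv"))
  write_tsv(data.frame(key = "tb_min", value = graph$tb_min),
            file.path(dir, "graph_params.tsv"))
  invisible(dir)
}

#' Read a tripartite graph written by [write_tripartite_graph()]
#' @param dir directory containing the TSV tables.
#' @return A `tripartite_graph`.
#' @export
read_tripartite_graph <- function(dir) {
  motifs <- read_tsv(file.path(dir, "nodes_motifs.tsv"))
  params <- read_tsv(file.path(dir, "graph_params.tsv"))
  inst <- read_tsv(file.path(dir, "edges_instances.tsv"))
  inst$low_confidence <- as.logical(inst$low_confidence)
  tripartite_graph(
    regions = as.character(read_tsv(file.path(dir, "nodes_regions.tsv"))$region),
    motifs = as.character(motifs$motif),
    properties = as.character(read_tsv(file.path(dir, "nodes_properties.tsv"))$property),
    instances = inst,
    motif_props = read_tsv(file.path(dir, "edges_motif_props.tsv")),
    region_props = read_tsv(file.path(dir, "edges_region_props.tsv")),
    tf_group = stats::setNames(as.character(motifs$tf_group), motifs$motif),
    hand_picked = unique(as.character(motifs$tf_group[as.logical(motifs$hand_picked)])),
    tb_min = as.integer(params$value[params$key == "tb_min"]))
}
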