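#' Build the signature co-occurrence network
#'
#' Applies one BH correction over all unordered species pairs and keeps edges
#' with q below `cfg$edge_fdr` (default 0.01). Edge sign comes from the
#' correlation. Modules are not assigned yet; see [louvain_modules()].
#'
#' @param rho Symmetric SparCC correlation matrix.
#' @param p Symmetric permutation p-value matrix, conformable with `rho`.
#' @param cfg A [sparcc_config()] (only `edge_fdr` is used).
#' @param directions Optional tibble with `species_id` and `direction`
#'   (depleted/enriched) to annotate nodes.
#' @return An object of class `signature_network`: `nodes` tibble
#'   (`species_id`, `module`, `degree`, optional `direction`) and `edges`
#'   tibble (`species_a`, `species_b`, `rho`, `p`, `q`, `sign`).
#' @export
build_network <- function(rho, p, cfg = sparcc_config(), directions = NULL) {
  stopifnot(is.matrix(rho), is.matrix(p), all(dim(rho) == dim(p)))
  ids <- rownames(rho) %||% paste0("sp", seq_len(nrow(rho)))
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  pairs <- tibble::tibble(
    species_a = ids[ut[, 1]], species_b = ids[ut[, 2]],
    rho = rho[ut], p = p[ut])
  pairs$q <- bh_fdr(pairs$p)
  edges <- pairs[!is.na(pairs$q) & pairs$q < cfg$edge_fdr, , drop = FALSE]
  edges$sign <- ifelse(edges$rho >= 0, "+", "-")
  deg <- table(factor(c(edges$species_a, edges$species_b), levels = ids))
  nodes <- tibble::tibble(species_id = ids, module = NA_integer_,
                          degree = as.integer(deg))
  if (!is.null(directions))
    nodes <- dplyr::left_join(nodes, dplyr::select(directions, "species_id", "direction"),
                              by = "species_id")
  structure(list(nodes = nodes, edges = edges, edge_fdr = cfg$edge_fdr),
            class = "signature_network")
}

#' @export
print.signature_network <- function(x, ...) {
  cat(sprintf("<signature_network> %d nodes, %d edges (FDR < %g), %s modules\n",
              nrow(x$nodes), nrow(x$edges), x$edge_fdr,
              if (all(is.na(x$nodes$module))) "no" else as.character(max(x$nodes$module))))
  invisible(x)
}

#' Assign network modules by Louvain community detection
#'
#' Maximises weighted modularity (Blondel's algorithm, resolution 1.0 by
#' default) on the positive-edge subgraph: edge weight is the SparCC rho for
#' positive edges; negative edges are excluded from the objective but remain
#' in the network. Nodes with no positive edge get singleton modules. The
#' assignment is deterministic under a fixed seed.
#'
#' @param net A [build_network()] result.
#' @param resolution Modularity resolution parameter.
#' @param seed Integer seed.
#' @return `net` with `nodes$module` filled (integer labels, numbered by
#'   first-node order).
#' @export
louvain_modules <- function(net, resolution = 1.0, seed = 1L) {
  stopifnot(inherits(net, "signature_network"))
  pos <- net$edges[net$edges$rho > 0, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    pos[, c("species_a", "species_b", "rho")], directed = FALSE,
    vertices = net$nodes$species_id)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, weights = igraph::E(g)$rho, resolution = resolution)
  memb <- igraph::membership(comm)
  memb <- memb[net$nodes$species_id]
  # relabel deterministically by first appearance in node order
  net$nodes$module <- as.integer(factor(memb, levels = unique(memb)))
  net
}

#' Per-node degree
#'
#' Count of retained incident edges per node (node size in the published
#' network rendering is proportional to this).
#'
#' @param net A [build_network()] result.
#' @return Tibble `species_id`, `degree`.
#' @export
hub_degrees <- function(net) {
  stopifnot(inherits(net, "signature_network"))
  dplyr::select(net$nodes, "species_id", "degree")
}

#' Convert a signature network to an igraph object
#'
#' @param net A [build_network()] result.
#' @param annotations Optional tibble from [read_annotation()] joined onto
#'   nodes.
#' @return An undirected igraph with node attributes (module, degree,
#'   direction, annotation fields) and edge attributes (rho, p, q, sign).
#' @export
as_igraph <- function(net, annotations = NULL) {
  stopifnot(inherits(net, "signature_network"))
  nodes <- net$nodes
  if (!is.null(annotations))
    nodes <- dplyr::left_join(nodes, annotations, by = "species_id")
  igraph::graph_from_data_frame(net$edges, directed = FALSE, vertices = nodes)
}

#' Export a signature network
#'
#' `write_graphml()` writes GraphML with all node/edge attributes;
#' `write_edges()` writes the edge list as TSV (the published
#' correlation-matrix artifact's content).
#'
#' @param net A [build_network()] result.
#' @param path Output path.
#' @param annotations Optional annotation tibble (GraphML only).
#' @export
write_graphml <- function(net, path, annotations = NULL) {
  igraph::write_graph(as_igraph(net, annotations), path, format = "graphml")
  invisible(net)
}

#' @rdname write_graphml
#' @export
write_edges <- function(net, path) {
  readr::write_tsv(net$edges, path, progress = FALSE)
  invisible(net)
}

#' Tidy a signature network
#'
#' @param x A [build_network()] result.
#' @param ... Unused.
#' @return The edge tibble.
#' @method tidy signature_network
#' @export
tidy.signature_network <- function(x, ...) x$edges

#' One-row network summary
#'
#' @inheritParams tidy.signature_network
#' @return Tibble: node, edge, module counts and the positive-edge fraction.
#' @method glance signature_network
#' @export
glance.signature_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    n_modules = if (all(is.na(x$nodes$module))) NA_integer_ else max(x$nodes$module),
    prop_positive = if (nrow(x$edges)) mean(x$edges$sign == "+") else NA_real_,
    edge_fdr = x$edge_fdr)
}
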