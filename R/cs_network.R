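## Compound-similarity (CS) network: node filtering, Louvain modules, labels.

#' Louvain community detection with deterministic, size-ordered labels
#'
#' Thin wrapper around [igraph::cluster_louvain()]. The provided seed fixes
#' R's RNG (which igraph's implementation draws from), so the partition is
#' reproducible. Singleton components end up as their own modules. Raw module
#' ids are renumbered 1, 2, ... by decreasing module size, ties broken by the
#' lexicographically smallest member id, so labels are stable across runs.
#'
#' @param graph an igraph object; a `weight` edge attribute is honoured.
#' @param resolution Louvain resolution parameter (default 1.0).
#' @param seed integer RNG seed.
#' @param weighted use the `weight` edge attribute if present (default TRUE).
#' @return named integer vector: vertex name -> module id (1-based).
#' @export
louvain_partition <- function(graph, resolution = 1.0, seed = 1L,
                              weighted = TRUE) {
  stopifnot(igraph::vcount(graph) > 0)
  w <- if (weighted && "weight" %in% igraph::edge_attr_names(graph))
    igraph::E(graph)$weight else NA
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  memb <- igraph::membership(igraph::cluster_louvain(graph, weights = w,
                                                     resolution = resolution))
  ids <- igraph::V(graph)$name %||% as.character(seq_len(igraph::vcount(graph)))
  names(memb) <- ids
  relabel_by_size(memb)
}

# renumber modules by decreasing size; ties by smallest member id
relabel_by_size <- function(membership) {
  sizes <- table(membership)
  first_id <- tapply(names(membership), membership, function(x) min(sort(x)))
  ord <- order(-as.integer(sizes[names(first_id)]), first_id)
  new <- stats::setNames(seq_along(ord), names(first_id)[ord])
  out <- new[as.character(membership)]
  names(out) <- names(membership)
  storage.mode(out) <- "integer"
  out
}

# map integer module ids to display labels, pooling small modules
module_labels <- function(membership, prefix, min_size = 3,
                          others = paste0(sub("_Module", "", prefix), "_others")) {
  sizes <- table(membership)
  big <- as.integer(names(sizes)[as.integer(sizes) >= min_size])
  lab <- stats::setNames(paste0(prefix, "_", seq_along(sort(big))), sort(big))
  out <- ifelse(as.character(membership) %in% names(lab),
                lab[as.character(membership)], others)
  stats::setNames(out, names(membership))
}

#' Assemble the compound-similarity network
#'
#' Nodes are the compounds that pass both filters of the bilayer analysis:
#' at least one similarity edge at the chosen threshold AND at least one
#' predicted target in the interaction table. Edges are restricted to
#' surviving nodes, weighted by their Tanimoto coefficient, and the network
#' is partitioned by Louvain community detection. Modules smaller than
#' `min_module_size` are pooled into a `CS_others` bucket for display, while
#' the raw integer partition is kept alongside.
#'
#' @param compounds a [compound_set] (only ids are needed here).
#' @param edges similarity edge list from [build_similarity_edges()].
#' @param interactions an interaction table from [load_interactions()] or a
#'   data.frame with a `compound` column.
#' @param resolution,seed,weighted passed to [louvain_partition()].
#' @param min_module_size modules below this size are pooled (default 3).
#' @return A `cs_network` object: igraph `graph` (vertex attributes `module`,
#'   `degree`), the integer `partition`, display `labels`, and counts of
#'   compounds excluded by each filter.
#' @export
assemble_cs_network <- function(compounds, edges, interactions,
                                resolution = 1.0, seed = 1L,
                                weighted = TRUE, min_module_size = 3) {
  ids <- if (inherits(compounds, "compound_set")) compounds$info$id
         else as.character(compounds)
  icomp <- unique(as.character(interactions$compound))
  with_edge <- ids[ids %in% unique(c(edges$a, edges$b))]
  with_target <- ids[ids %in% icomp]
  nodes <- intersect(with_edge, with_target)
  excluded <- c(no_edge = length(ids) - length(with_edge),
                no_target = length(ids) - length(with_target),
                kept = length(nodes))
  if (length(nodes) == 0)
    stop_bn("no compounds survive the similarity + target filters ",
            sprintf("(%d lacked edges, %d lacked targets)",
                    excluded[["no_edge"]], excluded[["no_target"]]))
  e <- edges[edges$a %in% nodes & edges$b %in% nodes, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$a, to = e$b, weight = e$tc),
    directed = FALSE,
    vertices = data.frame(name = sort(nodes)))
  part <- louvain_partition(g, resolution = resolution, seed = seed,
                            weighted = weighted)
  labels <- module_labels(part, "CS_Module", min_size = min_module_size,
                          others = "CS_others")
  deg <- igraph::degree(g)
  igraph::V(g)$module <- unname(labels[igraph::V(g)$name])
  igraph::V(g)$degree <- unname(deg[igraph::V(g)$name])
  structure(list(graph = g, edges = e, partition = part, labels = labels,
                 degrees = deg, excluded = excluded),
            class = "cs_network")
}

#' @export
print.cs_network <- function(x, ...) {
  cat("<cs_network> ", igraph::vcount(x$graph), " compounds, ",
      igraph::ecount(x$graph), " similarity edges, ",
      length(unique(x$labels)), " module labels\n", sep = "")
  invisible(x)
}

#' Summarize CS-network modules
#'
#' One row per module label: size, mean within-module Tanimoto similarity
#' (NA for singleton modules), and the highest-degree members. The mean
#' between-module Tanimoto over network edges is attached as attribute
#' `mean_between_tc` for comparison.
#'
#' @param net a `cs_network`.
#' @param n_top how many top-degree member ids to list per module.
#' @return data.frame with columns `module`, `size`, `mean_intra_tc`,
#'   `top_members`.
#' @export
summarize_modules <- function(net, n_top = 3) {
  stopifnot(inherits(net, "cs_network"))
  lab <- net$labels
  e <- net$edges
  la <- lab[e$a]; lb <- lab[e$b]
  intra <- la == lb
  mods <- names(sort(table(lab), decreasing = TRUE))
  rows <- lapply(mods, function(m) {
    members <- names(lab)[lab == m]
    mtc <- if (length(members) < 2) NA_real_ else {
      sel <- intra & la == m
      if (any(sel)) mean(e$tc[sel]) else NA_real_
    }
    top <- members[order(-net$degrees[members], members)][seq_len(min(n_top, length(members)))]
    data.frame(module = m, size = length(members), mean_intra_tc = mtc,
               top_members = paste(top, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_between_tc") <- if (any(!intra)) mean(e$tc[!intra]) else NA_real_
  out
}

#' Write a network (CS or TPT) as GraphML
#'
#' @param net a `cs_network` or `tpt_network`.
#' @param path output `.graphml` file.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' Write module membership as TSV
#'
#' @param net a `cs_network` or `tpt_network`.
#' @param path output file with columns `id`, `module`, `degree`.
#' @export
write_module_tsv <- function(net, path) {
  out <- data.frame(id = names(net$labels),
                    module = unname(net$labels),
                    degree = unname(net$degrees[names(net$labels)]))
  out <- out[order(out$module, -out$degree, out$id), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
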