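## Target layer: pathway annotations, hypergeometric over-representation,
## target-protein-target (TPT) projection and Louvain modules.

#' Read pathway annotations in GMT format
#'
#' One pathway per line: `id<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a line are collapsed; lines with fewer than three
#' fields are skipped with a warning.
#'
#' @param path GMT file.
#' @return A `pathway_db`: named list of pathways, each
#'   `list(id, name, members)`.
#' @export
load_gmt <- function(path) {
  if (!file.exists(path)) stop_bn("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_bn("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short))
    warning(sprintf("skipped %d GMT line(s) with fewer than 3 fields", sum(short)))
  fields <- fields[!short]
  if (length(fields) == 0) stop_bn("no usable pathway lines in ", path)
  pw <- lapply(fields, function(f)
    list(id = f[1], name = f[2], members = unique(f[-(1:2)])))
  ids <- vapply(pw, `[[`, "", "id")
  if (anyDuplicated(ids)) stop_bn("duplicate pathway ids in ", path)
  structure(stats::setNames(pw, ids), class = "pathway_db")
}

#' Write pathway annotations in GMT format
#'
#' @param pathways a `pathway_db`.
#' @param path output file.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(pathways, function(p)
    paste(c(p$id, p$name, p$members), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.pathway_db <- function(x, ...) {
  cat("<pathway_db> ", length(x), " pathways, ",
      length(unique(unlist(lapply(x, `[[`, "members")))), " distinct genes\n",
      sep = "")
  invisible(x)
}

#' Hypergeometric over-representation of targets in pathways
#'
#' For each pathway, members are intersected with the background universe and
#' the upper hypergeometric tail `P(X >= overlap)` is computed for the
#' overlap between the query target set and the pathway. Pathways passing the
#' significance cutoff are returned sorted by ascending p. By default raw
#' p-values are thresholded (`adjust = "none"`); Benjamini-Hochberg
#' adjustment is available, in which case the cutoff applies to the adjusted
#' values.
#'
#' @param query character vector of target symbols (must lie in `background`).
#' @param pathways a `pathway_db`.
#' @param background character vector: the gene universe.
#' @param alpha significance cutoff (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame `pathway`, `name`, `overlap`, `pathway_size`,
#'   `query_size`, `background_size`, `p` (and `padj` when adjusted), one row
#'   per retained pathway. The full unfiltered table is attached as attribute
#'   `all`.
#' @export
enrich_targets <- function(query, pathways, background, alpha = 0.05,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  if (length(query) == 0) stop_bn("empty query target set")
  if (!all(query %in% background))
    stop_bn("query targets outside the background universe: ",
            paste(utils::head(setdiff(query, background), 5), collapse = ", "))
  if (!(alpha > 0 && alpha <= 1)) stop_bn("alpha must be in (0, 1]")
  n_bg <- length(background)
  n_q <- length(query)
  rows <- lapply(pathways, function(p) {
    members <- intersect(p$members, background)
    m <- length(members)
    if (m == 0) return(NULL)  # pathway empty after intersection: dropped
    ov <- length(intersect(members, query))
    p_val <- stats::phyper(ov - 1, m, n_bg - m, n_q, lower.tail = FALSE)
    data.frame(pathway = p$id, name = p$name, overlap = ov, pathway_size = m,
               query_size = n_q, background_size = n_bg, p = p_val,
               stringsAsFactors = FALSE)
  })
  all_res <- do.call(rbind, rows)
  if (is.null(all_res)) stop_bn("no pathway overlaps the background universe")
  rownames(all_res) <- NULL
  if (adjust == "BH") {
    all_res$padj <- stats::p.adjust(all_res$p, method = "BH")
    keep <- all_res$padj < alpha
  } else {
    keep <- all_res$p < alpha
  }
  out <- all_res[keep, , drop = FALSE]
  out <- out[order(out$p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- all_res
  out
}

#' Build the target-protein-target network from enriched pathways
#'
#' Nodes are the targets belonging to at least one enriched pathway (after
#' background intersection, restricted to the query when one is recorded);
#' two targets are joined iff they co-occur in at least one enriched pathway,
#' with edge weight equal to the number of enriched pathways they share. The
#' network is partitioned with the same Louvain procedure as the compound
#' layer, labelled `TPT_Module_1`, `TPT_Module_2`, ... by decreasing size.
#'
#' @param enriched filtered result table from [enrich_targets()].
#' @param pathways the `pathway_db` the enrichment was run against.
#' @param restrict optional character vector; keep only these targets as
#'   nodes (typically the predicted-target query).
#' @param resolution,seed,weighted passed to [louvain_partition()].
#' @param min_module_size modules below this size are pooled into
#'   `TPT_others` (default 3).
#' @return A `tpt_network` object mirroring `cs_network`.
#' @export
build_tpt_network <- function(enriched, pathways, restrict = NULL,
                              resolution = 1.0, seed = 1L, weighted = TRUE,
                              min_module_size = 3) {
  if (nrow(enriched) == 0) stop_bn("no enriched pathways: TPT network is empty")
  member_sets <- lapply(enriched$pathway, function(id) {
    m <- pathways[[id]]$members
    if (!is.null(restrict)) m <- intersect(m, restrict)
    sort(unique(m))
  })
  names(member_sets) <- enriched$pathway
  nodes <- sort(unique(unlist(member_sets)))
  if (length(nodes) == 0) stop_bn("enriched pathways contain no usable targets")
  all_pairs <- unlist(lapply(member_sets, function(ms) {
    if (length(ms) < 2) return(NULL)
    prs <- utils::combn(ms, 2)
    paste(prs[1, ], prs[2, ], sep = "\r")
  }))
  if (length(all_pairs)) {
    cnt <- table(all_pairs)
    ab <- do.call(rbind, strsplit(names(cnt), "\r", fixed = TRUE))
    edf <- data.frame(from = ab[, 1], to = ab[, 2],
                      weight = as.integer(cnt),
                      stringsAsFactors = FALSE)
  } else {
    edf <- data.frame(from = character(), to = character(), weight = integer())
  }
  g <- igraph::graph_from_data_frame(edf, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  part <- louvain_partition(g, resolution = resolution, seed = seed,
                            weighted = weighted)
  labels <- module_labels(part, "TPT_Module", min_size = min_module_size,
                          others = "TPT_others")
  deg <- igraph::degree(g)
  igraph::V(g)$module <- unname(labels[igraph::V(g)$name])
  igraph::V(g)$degree <- unname(deg[igraph::V(g)$name])
  structure(list(graph = g,
                 edges = stats::setNames(edf, c("a", "b", "weight")),
                 partition = part, labels = labels, degrees = deg,
                 enriched = enriched, member_sets = member_sets),
            class = "tpt_network")
}

#' @export
print.tpt_network <- function(x, ...) {
  cat("<tpt_network> ", igraph::vcount(x$graph), " targets, ",
      igraph::ecount(x$graph), " co-membership edges, ",
      length(unique(x$labels)), " module labels\n", sep = "")
  invisible(x)
}

#' Functional propensity of TPT modules
#'
#' Ranks, for every target module, the enriched pathways most characteristic
#' of it. The score is coverage times significance:
#' `(members inside the module / pathway size) * -log10(p)`, so a pathway
#' both concentrated in the module and strongly enriched ranks first. The
#' scoring is deliberately isolated in this one function so an alternative
#' propensity measure can be swapped in.
#'
#' @param net a `tpt_network`.
#' @param enriched filtered table from [enrich_targets()].
#' @param pathways the `pathway_db`.
#' @param top_k pathways to report per module (default 5).
#' @return data.frame `module`, `pathway`, `name`, `inside`, `pathway_size`,
#'   `coverage`, `p`, `score`, `rank`.
#' @export
module_propensity <- function(net, enriched, pathways, top_k = 5) {
  stopifnot(inherits(net, "tpt_network"))
  lab <- net$labels
  mods <- sort(unique(lab))
  rows <- list()
  for (m in mods) {
    members <- names(lab)[lab == m]
    sc <- lapply(seq_len(nrow(enriched)), function(i) {
      pid <- enriched$pathway[i]
      pm <- intersect(pathways[[pid]]$members, names(lab))
      if (length(pm) == 0) return(NULL)
      inside <- length(intersect(pm, members))
      cov <- inside / length(pm)
      data.frame(module = m, pathway = pid, name = enriched$name[i],
                 inside = inside, pathway_size = length(pm), coverage = cov,
                 p = enriched$p[i],
                 score = cov * -log10(enriched$p[i]),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, sc)
    if (is.null(tab)) next
    tab <- tab[order(-tab$score, tab$p, tab$pathway), , drop = FALSE]
    tab <- utils::head(tab, top_k)
    tab$rank <- seq_len(nrow(tab))
    rows[[m]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an enrichment table as TSV
#'
#' @param enriched table from [enrich_targets()].
#' @param path output file.
#' @export
write_enrichment_tsv <- function(enriched, path) {
  utils::write.table(enriched, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
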