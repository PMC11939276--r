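## Bilayer coupling of the CS and TPT layers: the module-association matrix
## e_uv and per-compound contributions C(i)_uv. This scoring is the core of
## the package and is implemented here from its definition:
##
##   e_uv    = sum over i in m_u, j in m_v of d_ij
##   C(i)_uv = sum over j in m_v of d_ij          (i in m_u)
##
## so that sum over i in m_u of C(i)_uv = e_uv for every module pair, and the
## grand total of e equals the total interaction weight between networked
## compounds and networked targets.

#' Load a compound-target interaction table
#'
#' Reads a 3-column TSV (`compound`, `target`, `source`; header optional,
#' detected from the first line) with one row per prediction, merges rows on
#' the (compound, target) pair, and assigns the interaction weight `d`:
#' 1 per pair (`"indicator"`, default) or the number of distinct predictor
#' sources supporting the pair (`"source_count"`).
#'
#' @param path TSV file.
#' @param weighting `"indicator"` or `"source_count"`.
#' @param known_sources declared predictor vocabulary; labels outside it are
#'   kept with a warning.
#' @return An `interaction_table` data.frame: `compound`, `target`,
#'   `sources` (comma-joined), `d`. Malformed rows are skipped with a count.
#' @export
load_interactions <- function(path,
                              weighting = c("indicator", "source_count"),
                              known_sources = c("SuperPred", "SEA", "TCMSP")) {
  weighting <- match.arg(weighting)
  if (!file.exists(path)) stop_bn("interaction file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_bn("empty interaction file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (identical(tolower(fields[[1]][1]), "compound")) {
    fields <- fields[-1]
  }
  bad <- lengths(fields) < 3
  if (any(bad))
    warning(sprintf("skipped %d malformed interaction row(s)", sum(bad)))
  fields <- fields[!bad]
  if (length(fields) == 0) stop_bn("no usable interaction rows in ", path)
  df <- data.frame(compound = vapply(fields, `[`, "", 1),
                   target = vapply(fields, `[`, "", 2),
                   source = vapply(fields, `[`, "", 3),
                   stringsAsFactors = FALSE)
  unknown <- setdiff(unique(df$source), known_sources)
  if (length(unknown))
    warning("unknown predictor source label(s): ",
            paste(unknown, collapse = ", "), " (kept)")
  interaction_table(df, weighting = weighting)
}

#' Build an interaction table from per-prediction rows
#'
#' @param predictions data.frame with `compound`, `target`, `source`.
#' @param weighting `"indicator"` (d = 1 per pair) or `"source_count"`
#'   (d = number of distinct sources).
#' @return An `interaction_table` data.frame.
#' @export
interaction_table <- function(predictions,
                              weighting = c("indicator", "source_count")) {
  weighting <- match.arg(weighting)
  key <- paste(predictions$compound, predictions$target, sep = "\r")
  src <- tapply(predictions$source, key, function(s) sort(unique(s)))
  ab <- do.call(rbind, strsplit(names(src), "\r", fixed = TRUE))
  out <- data.frame(compound = ab[, 1], target = ab[, 2],
                    sources = vapply(src, paste, "", collapse = ","),
                    d = if (weighting == "indicator") 1
                        else as.numeric(lengths(src)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$compound, out$target), ]
  rownames(out) <- NULL
  attr(out, "weighting") <- weighting
  class(out) <- c("interaction_table", "data.frame")
  out
}

#' Module-association matrix and per-compound contributions
#'
#' Couples the partitioned compound layer and target layer through the
#' interaction table. Interactions whose compound is not a CS-network node or
#' whose target is not a TPT-network node are excluded from all sums (their
#' count is reported). For every pair of modules (m_u, m_v), e_uv is the sum
#' of interaction weights d_ij across the pair, and each compound's
#' contribution C(i)_uv is its own share of that sum.
#'
#' @param cs a `cs_network`, or any list with a named `labels` vector
#'   (compound id -> module label) and optionally `degrees` (used only for
#'   rank tie-breaks; defaults to 0).
#' @param tpt a `tpt_network`, or any list with a named `labels` vector
#'   (target -> module label).
#' @param interactions an `interaction_table`.
#' @param normalized also report `C_norm = C / e_uv` per cell (default FALSE;
#'   the ranking is unchanged because normalization is monotone within a
#'   cell).
#' @return A `module_association` object: matrix `e` (rows = compound
#'   modules, columns = target modules, ordered by label), data.frame
#'   `contributions` (`compound`, `m_u`, `m_v`, `C`), the used interaction
#'   rows, compound degrees (for rank tie-breaks) and exclusion counts.
#' @export
module_association <- function(cs, tpt, interactions, normalized = FALSE) {
  stopifnot(!is.null(cs$labels), !is.null(names(cs$labels)),
            !is.null(tpt$labels), !is.null(names(tpt$labels)))
  if (is.null(cs$degrees))
    cs$degrees <- stats::setNames(rep(0L, length(cs$labels)), names(cs$labels))
  it <- as.data.frame(interactions)
  in_cs <- it$compound %in% names(cs$labels)
  in_tpt <- it$target %in% names(tpt$labels)
  used <- it[in_cs & in_tpt, , drop = FALSE]
  excluded <- c(compound_not_in_cs = sum(!in_cs),
                target_not_in_tpt = sum(in_cs & !in_tpt))
  if (nrow(used) == 0)
    stop_bn("no interaction joins the two layers: ",
            sprintf("%d rows lost to the compound filter, %d to the target filter",
                    excluded[[1]], excluded[[2]]))
  used$m_u <- unname(cs$labels[used$compound])
  used$m_v <- unname(tpt$labels[used$target])
  e <- tapply(used$d, list(used$m_u, used$m_v), sum, default = 0)
  u_levels <- sort(unique(unname(cs$labels)))
  v_levels <- sort(unique(unname(tpt$labels)))
  full <- matrix(0, length(u_levels), length(v_levels),
                 dimnames = list(u_levels, v_levels))
  full[rownames(e), colnames(e)] <- e
  contrib <- stats::aggregate(d ~ compound + m_u + m_v, data = used, FUN = sum)
  names(contrib)[names(contrib) == "d"] <- "C"
  if (normalized) {
    cell_e <- full[cbind(contrib$m_u, contrib$m_v)]
    contrib$C_norm <- contrib$C / cell_e
  }
  contrib <- contrib[order(contrib$m_u, contrib$m_v, -contrib$C,
                           contrib$compound), ]
  rownames(contrib) <- NULL
  structure(list(e = full, contributions = contrib, interactions = used,
                 cs_labels = cs$labels, tpt_labels = tpt$labels,
                 degrees = cs$degrees, excluded = excluded),
            class = "module_association")
}

#' @export
print.module_association <- function(x, ...) {
  cat("<module_association> ", nrow(x$e), " compound modules x ", ncol(x$e),
      " target modules; total weight ", sum(x$e), "\n", sep = "")
  invisible(x)
}

#' Rank compounds of a module by their contribution to a target module
#'
#' All compounds of module `u` are ranked by C(i)_uv descending (compounds of
#' `u` with no interaction into `v` count as 0), ties broken by CS-network
#' degree descending, then by compound id, so the ordering is deterministic.
#'
#' @param ma a `module_association`.
#' @param u compound-module label (e.g. `"CS_Module_2"`).
#' @param v target-module label (e.g. `"TPT_Module_1"`).
#' @param k how many compounds to return.
#' @return data.frame `compound`, `C`, `degree`, `rank`.
#' @export
rank_compounds <- function(ma, u, v, k = 3) {
  stopifnot(inherits(ma, "module_association"))
  if (!is.numeric(k) || k <= 0) stop_bn("k must be a positive integer")
  if (!u %in% rownames(ma$e)) stop_bn("unknown compound module: ", u)
  if (!v %in% colnames(ma$e)) stop_bn("unknown target module: ", v)
  members <- names(ma$cs_labels)[ma$cs_labels == u]
  cc <- ma$contributions
  cc <- cc[cc$m_u == u & cc$m_v == v, c("compound", "C")]
  C <- stats::setNames(rep(0, length(members)), members)
  C[cc$compound] <- cc$C
  deg <- ma$degrees[members]
  ord <- order(-C, -deg, members)
  out <- data.frame(compound = members[ord], C = unname(C[ord]),
                    degree = unname(deg[ord]), stringsAsFactors = FALSE)
  out <- utils::head(out, k)
  out$rank <- seq_len(nrow(out))
  out
}

#' Focus the bilayer association on one enriched pathway
#'
#' Identifies where a pathway of interest sits in the bilayer map: the target
#' modules containing its member targets, the compound modules with nonzero
#' association into those modules, and a contribution ranking restricted to
#' the pathway's member targets (every networked compound scored by its total
#' interaction weight onto those targets).
#'
#' @param ma a `module_association`.
#' @param tpt the `tpt_network`.
#' @param enriched filtered table from [enrich_targets()].
#' @param pathway pathway id or name; must be among the enriched results.
#' @param k size of the restricted ranking (default 10).
#' @return list: `pathway`, `targets` (member targets present in the TPT
#'   network), `target_modules`, `compound_modules`, `cells` (highlighted
#'   (u, v) pairs with their e_uv), `ranking`.
#' @export
pathway_focus <- function(ma, tpt, enriched, pathway, k = 10) {
  stopifnot(inherits(ma, "module_association"))
  hit <- enriched$pathway == pathway | enriched$name == pathway
  if (!any(hit))
    stop_bn("pathway not among the enriched results: ", pathway)
  pid <- enriched$pathway[which(hit)[1]]
  targets <- intersect(tpt$member_sets[[pid]] %||% character(0),
                       names(tpt$labels))
  if (length(targets) == 0)
    stop_bn("no member of pathway ", pid, " is present in the TPT network")
  v_mods <- sort(unique(unname(tpt$labels[targets])))
  it <- ma$interactions
  focal <- it[it$target %in% targets, , drop = FALSE]
  u_mods <- sort(unique(focal$m_u))
  cells <- expand.grid(m_u = u_mods, m_v = v_mods, stringsAsFactors = FALSE)
  cells$e_uv <- ma$e[cbind(cells$m_u, cells$m_v)]
  if (nrow(focal)) {
    sc <- stats::aggregate(d ~ compound, data = focal, FUN = sum)
    names(sc)[2] <- "C_focal"
    sc$m_u <- unname(ma$cs_labels[sc$compound])
    deg <- ma$degrees[sc$compound]
    ord <- order(-sc$C_focal, -deg, sc$compound)
    ranking <- utils::head(sc[ord, c("compound", "m_u", "C_focal")], k)
    ranking$rank <- seq_len(nrow(ranking))
    rownames(ranking) <- NULL
  } else {
    ranking <- data.frame(compound = character(), m_u = character(),
                          C_focal = numeric(), rank = integer())
  }
  list(pathway = pid, targets = targets, target_modules = v_mods,
       compound_modules = u_mods, cells = cells, ranking = ranking)
}

#' Write the e_uv association matrix as a TSV table
#'
#' Rows are compound modules, columns target modules, both in label order;
#' cell values are the e_uv association strengths exactly as computed.
#'
#' @param ma a `module_association`.
#' @param path output file.
#' @export
export_association_heatmap_table <- function(ma, path) {
  m <- ma$e[order(rownames(ma$e)), order(colnames(ma$e)), drop = FALSE]
  df <- data.frame(module = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-compound contributions as TSV
#'
#' @param ma a `module_association`.
#' @param path output file with columns `compound`, `m_u`, `m_v`, `C`,
#'   `rank` (rank within the (m_u, m_v) cell).
#' @export
write_contributions_tsv <- function(ma, path) {
  cc <- ma$contributions
  cc$rank <- stats::ave(-cc$C, cc$m_u, cc$m_v, FUN = rank)
  utils::write.table(cc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
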