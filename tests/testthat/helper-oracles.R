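# Independent oracles and fixture builders used across the suite. All are
# deliberately naive (set arithmetic, exhaustive enumeration, double loops)
# so they cannot share a code path with the implementation they check.

rand_fp <- function(L = 64, density = 0.3) as.integer(stats::runif(L) < density)

# Tanimoto by explicit set arithmetic over bit indices
tanimoto_brute <- function(a, b) {
  A <- which(a == 1L); B <- which(b == 1L)
  u <- union(A, B)
  if (length(u) == 0) return(0)
  length(intersect(A, B)) / length(u)
}

# all-pairs thresholding by double loop
edges_brute <- function(fp, threshold) {
  n <- nrow(fp)
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tc <- tanimoto_brute(fp[i, ], fp[j, ])
    if (tc >= threshold) out[[length(out) + 1]] <- c(i, j, tc)
  }
  if (length(out) == 0)
    return(data.frame(i = integer(), j = integer(), tc = numeric()))
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2], tc = m[, 3])
}

# upper hypergeometric tail by exhaustive enumeration of all draws of size k
# from a background of size bg in which the pathway is the first m elements
hyper_tail_enum <- function(overlap, m, bg, k) {
  draws <- utils::combn(bg, k)
  hits <- colSums(draws <= m)
  sum(hits >= overlap) / ncol(draws)
}

# planted two-block graph: n/2 + n/2, within-block edge prob p_in, between
# p_out; returns the igraph and the planted membership
planted_two_block <- function(n = 40, p_in = 0.9, p_out = 0.02) {
  half <- n / 2
  memb <- rep(1:2, each = half)
  el <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- if (memb[i] == memb[j]) p_in else p_out
    if (stats::runif(1) < p) el[[length(el) + 1]] <- c(i, j)
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(el)) g <- igraph::add_edges(g, unlist(el))
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  list(graph = g, membership = memb)
}

adjusted_agreement <- function(a, b) mclust::adjustedRandIndex(a, b)

# tiny pathway_db built in code
make_pathways <- function(...) {
  pws <- list(...)
  out <- lapply(seq_along(pws), function(i)
    list(id = names(pws)[i], name = names(pws)[i],
         members = unique(pws[[i]])))
  structure(stats::setNames(out, names(pws)), class = "pathway_db")
}

# interaction_table from triples without touching the TSV reader
make_interactions <- function(compound, target,
                              source = "SuperPred", weighting = "indicator") {
  interaction_table(data.frame(compound = compound, target = target,
                               source = source, stringsAsFactors = FALSE),
                    weighting = weighting)
}

# a compound_set with hand-written fingerprints (list of set-bit indices)
make_compounds <- function(bit_sets, L = 32) {
  ids <- names(bit_sets)
  fp <- t(vapply(bit_sets, function(b) {
    v <- integer(L); v[b] <- 1L; v
  }, integer(L)))
  rownames(fp) <- ids
  compound_set(data.frame(id = ids, name = ids, smiles = NA_character_), fp)
}

# down-scaled synthetic spec for fast pipeline tests (same structure, ~5x
# smaller); analysis behaviour at this size is checked by test-synthetic.R
tiny_spec <- function(seed = 1L, ...) {
  defaults <- list(n_compounds = 200, n_clusters = 6, others_fraction = 0.3,
                   n_targets = 160, universe_size = 800, n_pathways = 40,
                   decoy_pathway_fraction = 0.25, pathway_size_mean = 12,
                   pathway_size_min = 6, background_interaction_rate = 0.01,
                   focal_pathway_size = 10, active_extra_targets = 6,
                   seed = seed)
  do.call(synthetic_spec, utils::modifyList(defaults, list(...)))
}

std_smiles_path <- function() {
  system.file("extdata", "xbj_standards.smi", package = "bilayernet")
}
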