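## Planted-structure synthetic data: compound clusters with controlled
## fingerprint similarity, a pathway universe with block-structured target
## modules, and an interaction table with boosted (cluster, module) pairs
## plus a small set of planted "active" compounds concentrated on one focal
## pathway. Everything is a pure function of the spec (same spec, byte-
## identical outputs).

#' Parameters of the synthetic bilayer benchmark
#'
#' Defaults emulate the scale of a real multi-herb compound collection:
#' ~1000 compounds of which ~70% fall into structural clusters (the rest are
#' structural singletons that never reach the similarity threshold), ~850
#' candidate targets of which ~80% sit in four pathway blocks, and a pathway
#' universe over a larger gene background so over-representation is
#' meaningful.
#'
#' Fingerprint geometry: cluster seed fingerprints have density
#' `fp_density` (0.25), members flip each bit independently at rate
#' `within_cluster_flip_rate` (0.02). The expected Tanimoto between two
#' members of the same cluster is
#' `(d(1-e)^2 + (1-d)e^2) / (d(1-e^2) + (1-d)(2e-e^2))` ~= 0.86 at the
#' defaults, comfortably above the 0.8 edge threshold, while unrelated
#' compounds sit near `d/(2-d)` ~= 0.14.
#'
#' @param n_compounds total compounds (default 1000).
#' @param n_clusters structural clusters (default 15).
#' @param others_fraction fraction of unclustered compounds (default 0.30).
#' @param cluster_exponent power-law exponent for cluster sizes (default
#'   0.7; sizes are proportional to `k^-exponent`, giving the uneven module
#'   sizes seen in real compound collections).
#' @param fp_length fingerprint length in bits (default 2048).
#' @param fp_density seed fingerprint bit density (default 0.25).
#' @param within_cluster_flip_rate per-bit flip rate within clusters
#'   (default 0.02).
#' @param between_cluster_overlap fraction of seed set-bits shared by all
#'   cluster seeds (default 0.05).
#' @param n_targets candidate target symbols (default 850).
#' @param universe_size gene universe for enrichment, targets plus decoy
#'   genes (default 4000).
#' @param enriched_target_fraction fraction of targets placed in pathway
#'   blocks (default 0.80).
#' @param n_target_modules pathway blocks / planted target modules
#'   (default 4).
#' @param n_pathways total pathways (default 120).
#' @param decoy_pathway_fraction fraction of pathways drawn from decoy genes
#'   only (default 1/6).
#' @param pathway_purity fraction of a block pathway's members drawn from
#'   its home block (default 0.85).
#' @param pathway_size_mean,pathway_size_min member-count distribution
#'   (Poisson mean 18, floor 8).
#' @param background_interaction_rate Bernoulli rate p0 for any
#'   (compound, target) pair (default 0.004).
#' @param planted_pair_boost multiplier on p0 for a cluster's preferred
#'   target module (default 12).
#' @param n_planted_actives planted active compounds (default 3).
#' @param active_extra_targets focal-pathway targets added to each active
#'   (default 8).
#' @param focal_pathway_size members of the focal pathway (default 15).
#' @param sources predictor source vocabulary.
#' @param seed integer RNG seed.
#' @return A validated `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_compounds = 1000,
                           n_clusters = 15,
                           others_fraction = 0.30,
                           cluster_exponent = 0.7,
                           fp_length = 2048,
                           fp_density = 0.25,
                           within_cluster_flip_rate = 0.02,
                           between_cluster_overlap = 0.05,
                           n_targets = 850,
                           universe_size = 4000,
                           enriched_target_fraction = 0.80,
                           n_target_modules = 4,
                           n_pathways = 120,
                           decoy_pathway_fraction = 1 / 6,
                           pathway_purity = 0.85,
                           pathway_size_mean = 18,
                           pathway_size_min = 8,
                           background_interaction_rate = 0.004,
                           planted_pair_boost = 12,
                           n_planted_actives = 3,
                           active_extra_targets = 8,
                           focal_pathway_size = 15,
                           sources = c("SuperPred", "SEA", "TCMSP"),
                           seed = 1L) {
  spec <- as.list(environment())
  rates <- c(others_fraction, fp_density, within_cluster_flip_rate,
             between_cluster_overlap, enriched_target_fraction,
             decoy_pathway_fraction, pathway_purity,
             background_interaction_rate)
  if (any(rates < 0 | rates > 1)) stop_bn("all rates must lie in [0, 1]")
  counts <- c(n_compounds, n_clusters, fp_length, n_targets, universe_size,
              n_target_modules, n_pathways, n_planted_actives,
              active_extra_targets, focal_pathway_size)
  if (any(counts <= 0)) stop_bn("all counts must be positive")
  if (universe_size <= n_targets)
    stop_bn("universe_size must exceed n_targets")
  if (active_extra_targets > focal_pathway_size)
    stop_bn("active_extra_targets cannot exceed focal_pathway_size")
  if (fp_length %% 4 != 0) stop_bn("fp_length must be a multiple of 4")
  spec$seed <- as.integer(seed)
  structure(spec, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> ", x$n_compounds, " compounds / ", x$n_clusters,
      " clusters; ", x$n_targets, " targets / ", x$n_target_modules,
      " modules; ", x$n_pathways, " pathways; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# deterministic cluster sizes: truncated power law over ranks, largest first
cluster_sizes <- function(spec) {
  n_cl <- round(spec$n_compounds * (1 - spec$others_fraction))
  w <- (seq_len(spec$n_clusters))^(-spec$cluster_exponent)
  sizes <- floor(w / sum(w) * n_cl)
  minimum <- max(4, spec$n_planted_actives + 1)
  sizes <- pmax(sizes, minimum)
  # absorb the rounding drift in the largest cluster
  sizes[1] <- sizes[1] + (n_cl - sum(sizes))
  if (sizes[1] < minimum) stop_bn("cluster size budget too small")
  sizes
}

# preferred target module of each cluster: round-robin
cluster_preferences <- function(spec) {
  ((seq_len(spec$n_clusters) - 1) %% spec$n_target_modules) + 1
}

# cluster hosting the planted actives: preferred module differs from the
# focal module (1), size closest to the median of the eligible clusters
actives_cluster <- function(spec) {
  sizes <- cluster_sizes(spec)
  pref <- cluster_preferences(spec)
  eligible <- which(pref != 1)
  if (length(eligible) == 0) stop_bn("need a cluster not aimed at the focal module")
  med <- stats::median(sizes[eligible])
  eligible[which.min(abs(sizes[eligible] - med))]
}

#' Generate the synthetic compound library
#'
#' Per cluster, a random seed fingerprint (density `fp_density`, with a
#' small bit set shared across all clusters controlled by
#' `between_cluster_overlap`); members copy the seed with independent per-bit
#' flips at `within_cluster_flip_rate`. Unclustered "others" compounds get
#' independent random fingerprints and therefore essentially never reach the
#' similarity threshold.
#'
#' @param spec a [synthetic_spec()].
#' @return list: `compounds` (a [compound_set] carrying fingerprints, no
#'   SMILES) and `truth` (`cluster` map with NA for others, `actives`,
#'   `cluster_sizes`, `cluster_preference`).
#' @export
generate_compounds <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(derive_seed(spec$seed, 101))
  L <- spec$fp_length
  sizes <- cluster_sizes(spec)
  n_cl <- sum(sizes)
  n_others <- spec$n_compounds - n_cl
  n_bits <- round(spec$fp_density * L)
  n_shared <- round(spec$between_cluster_overlap * n_bits)
  shared <- sample.int(L, n_shared)
  seeds <- matrix(0L, spec$n_clusters, L)
  for (k in seq_len(spec$n_clusters)) {
    extra <- sample(setdiff(seq_len(L), shared), n_bits - n_shared)
    seeds[k, c(shared, extra)] <- 1L
  }
  fp <- matrix(0L, spec$n_compounds, L)
  cluster <- rep(NA_integer_, spec$n_compounds)
  row <- 1L
  for (k in seq_len(spec$n_clusters)) {
    flips <- matrix(stats::runif(sizes[k] * L) < spec$within_cluster_flip_rate,
                    sizes[k], L)
    block <- xor(flips, matrix(as.logical(seeds[k, ]), sizes[k], L, byrow = TRUE))
    fp[row:(row + sizes[k] - 1L), ] <- block * 1L
    cluster[row:(row + sizes[k] - 1L)] <- k
    row <- row + sizes[k]
  }
  if (n_others > 0)
    fp[row:spec$n_compounds, ] <-
      (matrix(stats::runif(n_others * L), n_others, L) < spec$fp_density) * 1L
  ids <- sprintf("CMP%04d", seq_len(spec$n_compounds))
  rownames(fp) <- ids
  info <- data.frame(id = ids, name = sprintf("compound_%04d", seq_len(spec$n_compounds)),
                     smiles = NA_character_, stringsAsFactors = FALSE)
  ac <- actives_cluster(spec)
  actives <- ids[which(cluster == ac)[seq_len(spec$n_planted_actives)]]
  list(compounds = compound_set(info, fp),
       truth = list(cluster = stats::setNames(cluster, ids),
                    actives = actives,
                    actives_cluster = ac,
                    cluster_sizes = sizes,
                    cluster_preference = cluster_preferences(spec)))
}

#' Generate the synthetic pathway universe and target modules
#'
#' Targets are split into `n_target_modules` equal blocks (plus a free,
#' pathway-less remainder); block pathways draw `pathway_purity` of their
#' members from their home block and the rest from other blocks, decoy
#' pathways draw only from decoy genes so they never enrich against a
#' compound-derived query. The first pathway of module 1 is the focal
#' pathway: `focal_pathway_size` members, all inside its block (an analog of
#' an oxidative-stress response pathway concentrated in one target module).
#'
#' @param spec a [synthetic_spec()].
#' @return list: `pathways` (a `pathway_db`), `truth` (`target_module` map
#'   with NA for free targets, `focal_pathway`, `focal_module`, `decoys`).
#' @export
generate_pathways_and_targets <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(derive_seed(spec$seed, 202))
  targets <- sprintf("TGT%04d", seq_len(spec$n_targets))
  decoys <- sprintf("GEN%04d", seq_len(spec$universe_size - spec$n_targets))
  n_mod <- round(spec$n_targets * spec$enriched_target_fraction)
  module <- rep(NA_integer_, spec$n_targets)
  module[seq_len(n_mod)] <- rep(seq_len(spec$n_target_modules),
                                length.out = n_mod)
  blocks <- split(targets[seq_len(n_mod)], module[seq_len(n_mod)])
  n_decoy_pw <- round(spec$n_pathways * spec$decoy_pathway_fraction)
  n_block_pw <- spec$n_pathways - n_decoy_pw
  home <- rep(seq_len(spec$n_target_modules), length.out = n_block_pw)
  pw <- vector("list", spec$n_pathways)
  sizes <- pmax(spec$pathway_size_min, stats::rpois(spec$n_pathways,
                                                    spec$pathway_size_mean))
  focal_idx <- which(home == 1)[1]
  for (i in seq_len(n_block_pw)) {
    blk <- blocks[[home[i]]]
    if (i == focal_idx) {
      members <- sample(blk, min(spec$focal_pathway_size, length(blk)))
    } else {
      sz <- min(sizes[i], length(blk))
      n_home <- round(spec$pathway_purity * sz)
      other <- unlist(blocks[-home[i]], use.names = FALSE)
      members <- c(sample(blk, n_home),
                   sample(other, min(sz - n_home, length(other))))
    }
    pw[[i]] <- list(id = sprintf("PW%03d", i),
                    name = if (i == focal_idx)
                      "oxidative stress response (focal)"
                    else sprintf("pathway %03d (module %d)", i, home[i]),
                    members = sort(unique(members)))
  }
  for (i in seq_len(n_decoy_pw)) {
    j <- n_block_pw + i
    pw[[j]] <- list(id = sprintf("PW%03d", j),
                    name = sprintf("decoy pathway %03d", j),
                    members = sort(sample(decoys, min(sizes[j], length(decoys)))))
  }
  ids <- vapply(pw, `[[`, "", "id")
  pathways <- structure(stats::setNames(pw, ids), class = "pathway_db")
  list(pathways = pathways,
       truth = list(target_module = stats::setNames(module, targets),
                    targets = targets,
                    decoy_genes = decoys,
                    focal_pathway = sprintf("PW%03d", focal_idx),
                    focal_module = 1L,
                    decoy_pathways = ids[seq_len(n_decoy_pw) + n_block_pw]))
}

#' Generate the synthetic compound-target interaction table
#'
#' Every (compound, target) pair is drawn Bernoulli(p0); pairs joining a
#' cluster to its preferred target module are boosted to
#' `planted_pair_boost * p0` (clipped at 1 with a warning). Each planted
#' active additionally receives `active_extra_targets` interactions drawn
#' uniformly (without replacement) from the focal pathway's members. Every
#' interaction is supported by 1-3 predictor sources.
#'
#' @param spec a [synthetic_spec()].
#' @param compounds result of [generate_compounds()].
#' @param pathways result of [generate_pathways_and_targets()].
#' @param weighting passed to [interaction_table()].
#' @return list: `interactions` (an `interaction_table`), `predictions`
#'   (one row per (pair, source), the on-disk form).
#' @export
generate_interactions <- function(spec, compounds, pathways,
                                  weighting = "indicator") {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(derive_seed(spec$seed, 303))
  ids <- compounds$compounds$info$id
  cluster <- compounds$truth$cluster
  pref <- compounds$truth$cluster_preference
  tmod <- pathways$truth$target_module
  targets <- pathways$truth$targets
  p0 <- spec$background_interaction_rate
  pboost <- spec$planted_pair_boost * p0
  if (pboost > 1) {
    warning("boosted interaction probability exceeds 1; clipped")
    pboost <- 1
  }
  n <- length(ids); t <- length(targets)
  P <- matrix(p0, n, t)
  for (k in seq_len(spec$n_clusters)) {
    rows <- which(!is.na(cluster) & cluster == k)
    cols <- which(!is.na(tmod) & tmod == pref[k])
    P[rows, cols] <- pboost
  }
  hits <- matrix(stats::runif(n * t), n, t) < P
  # planted actives: exactly active_extra_targets distinct focal members each
  focal_members <- pathways$pathways[[pathways$truth$focal_pathway]]$members
  for (a in compounds$truth$actives) {
    extra <- sample(focal_members, spec$active_extra_targets)
    hits[match(a, ids), match(extra, targets)] <- TRUE
  }
  idx <- which(hits, arr.ind = TRUE)
  pair_comp <- ids[idx[, 1]]
  pair_targ <- targets[idx[, 2]]
  n_src <- sample(seq_along(spec$sources), nrow(idx), replace = TRUE)
  src_list <- lapply(n_src, function(k) sample(spec$sources, k))
  predictions <- data.frame(
    compound = rep(pair_comp, n_src),
    target = rep(pair_targ, n_src),
    source = unlist(src_list),
    stringsAsFactors = FALSE)
  predictions <- predictions[order(predictions$compound, predictions$target,
                                   predictions$source), ]
  rownames(predictions) <- NULL
  list(interactions = interaction_table(predictions, weighting = weighting),
       predictions = predictions)
}

#' Generate a complete synthetic dataset in memory
#'
#' @param spec a [synthetic_spec()].
#' @param weighting interaction weighting mode.
#' @return list: `compounds` ([compound_set]), `pathways` (`pathway_db`),
#'   `interactions`, `predictions`, and `truth` (merged ground-truth maps).
#' @export
generate_dataset <- function(spec, weighting = "indicator") {
  cp <- generate_compounds(spec)
  pt <- generate_pathways_and_targets(spec)
  it <- generate_interactions(spec, cp, pt, weighting = weighting)
  list(compounds = cp$compounds,
       pathways = pt$pathways,
       interactions = it$interactions,
       predictions = it$predictions,
       truth = c(cp$truth, pt$truth))
}

#' Write a synthetic dataset to disk
#'
#' Emits four plain-text files: `compounds.tsv` (id, name, cluster,
#' hex-encoded fingerprint), `interactions.tsv` (compound, target, source;
#' one row per prediction), `pathways.gmt`, and `ground_truth.json`.
#' Re-running with the same spec reproduces byte-identical files.
#'
#' @param spec a [synthetic_spec()].
#' @param outdir output directory (created if missing).
#' @return (invisibly) named vector of the written paths.
#' @export
emit_dataset <- function(spec, outdir) {
  ds <- generate_dataset(spec)
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop_bn("cannot create output directory: ", outdir)
  paths <- c(compounds = file.path(outdir, "compounds.tsv"),
             interactions = file.path(outdir, "interactions.tsv"),
             pathways = file.path(outdir, "pathways.gmt"),
             truth = file.path(outdir, "ground_truth.json"))
  fp_hex <- apply(ds$compounds$fingerprints, 1, fp_to_hex)
  comp <- data.frame(id = ds$compounds$info$id,
                     name = ds$compounds$info$name,
                     cluster = unname(ds$truth$cluster),
                     fingerprint = unname(fp_hex))
  utils::write.table(comp, paths["compounds"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds$predictions, paths["interactions"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(ds$pathways, paths["pathways"])
  truth <- ds$truth
  truth$cluster <- as.list(truth$cluster)
  truth$target_module <- as.list(truth$target_module)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, null = "null",
                       na = "null", pretty = TRUE)
  invisible(paths)
}

#' Read a fingerprint table written by [emit_dataset()]
#'
#' @param path `compounds.tsv` with hex-encoded fingerprints.
#' @return a [compound_set] with fingerprints; the `cluster` column (if
#'   present) is attached as attribute `cluster`.
#' @export
read_fingerprint_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  fp <- t(vapply(df$fingerprint, hex_to_fp,
                 integer(nchar(df$fingerprint[1]) * 4L)))
  rownames(fp) <- df$id
  out <- compound_set(data.frame(id = df$id, name = df$name,
                                 smiles = NA_character_), fp)
  if ("cluster" %in% names(df))
    attr(out, "cluster") <- stats::setNames(df$cluster, df$id)
  out
}
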