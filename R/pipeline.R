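## End-to-end orchestration: validated run configuration, the in-memory
## analysis path shared by tests and scripts, and the file-writing pipeline
## with its run manifest.

#' Run the bilayer analysis on in-memory inputs
#'
#' The computational core of the pipeline, usable without any file I/O:
#' similarity edges -> CS network (similarity + target filters, Louvain) ->
#' hypergeometric enrichment of the predicted-target query -> TPT network
#' (Louvain) -> module-association matrix with per-compound contributions.
#'
#' The enrichment query is the set of targets predicted for CS-network
#' compounds; the background defaults to the union of all pathway genes and
#' the query.
#'
#' @param compounds a [compound_set] with fingerprints.
#' @param pathways a `pathway_db`.
#' @param interactions an `interaction_table`.
#' @param tc_threshold Tanimoto edge threshold (default 0.8).
#' @param resolution Louvain resolution (default 1.0).
#' @param seed integer seed; per-stage seeds are derived from it.
#' @param alpha enrichment cutoff (default 0.05).
#' @param adjust `"none"` or `"BH"`.
#' @param min_module_size pooling threshold for module labels.
#' @param weighted run Louvain on edge weights (default TRUE).
#' @param background optional explicit gene universe.
#' @return list with `edges`, `cs`, `query`, `background`, `enriched`,
#'   `tpt`, `ma`.
#' @export
analyze_bilayer <- function(compounds, pathways, interactions,
                            tc_threshold = 0.8, resolution = 1.0, seed = 1L,
                            alpha = 0.05, adjust = "none",
                            min_module_size = 3, weighted = TRUE,
                            background = NULL) {
  edges <- build_similarity_edges(compounds, threshold = tc_threshold)
  cs <- assemble_cs_network(compounds, edges, interactions,
                            resolution = resolution,
                            seed = derive_seed(seed, 3),
                            weighted = weighted,
                            min_module_size = min_module_size)
  it <- as.data.frame(interactions)
  query <- sort(unique(it$target[it$compound %in% names(cs$labels)]))
  if (is.null(background))
    background <- sort(unique(c(unlist(lapply(pathways, `[[`, "members")),
                                query)))
  enriched <- enrich_targets(query, pathways, background, alpha = alpha,
                             adjust = adjust)
  tpt <- build_tpt_network(enriched, pathways, restrict = query,
                           resolution = resolution,
                           seed = derive_seed(seed, 4),
                           weighted = weighted,
                           min_module_size = min_module_size)
  ma <- module_association(cs, tpt, interactions)
  list(edges = edges, cs = cs, query = query, background = background,
       enriched = enriched, tpt = tpt, ma = ma)
}

#' Run the default synthetic benchmark once
#'
#' Generates a synthetic dataset from `spec` and runs [analyze_bilayer()] on
#' it with the given analysis constants.
#'
#' @param spec a [synthetic_spec()].
#' @param ... passed to [analyze_bilayer()] (`tc_threshold`, `resolution`,
#'   `alpha`, ...). The analysis seed defaults to the spec's seed.
#' @param seed analysis seed (Louvain); defaults to `spec$seed`.
#' @return the [analyze_bilayer()] result plus `dataset` (with ground truth).
#' @export
run_synthetic_analysis <- function(spec, ..., seed = spec$seed) {
  ds <- generate_dataset(spec)
  res <- analyze_bilayer(ds$compounds, ds$pathways, ds$interactions,
                         seed = seed, ...)
  res$dataset <- ds
  res
}

## ---- configuration ---------------------------------------------------------

config_defaults <- function() {
  list(mode = "synthetic",
       synthetic = list(),           # synthetic_spec() overrides
       compounds = NULL,             # real mode: SMILES/SDF path
       interactions = NULL,          # real mode: interaction TSV
       pathways = NULL,              # real mode: GMT path
       fp_length = 2048,
       fp_kind = "atompair",
       tc_threshold = 0.8,
       resolution = 1.0,
       alpha = 0.05,
       adjust = "none",
       weighting = "indicator",
       min_module_size = 3,
       weighted_louvain = TRUE,
       focal_pathway = NULL,
       top_k = 3,
       seed = 1L,
       outdir = "bilayernet_run",
       verbose = TRUE)
}

#' Validate a run configuration
#'
#' Accepts a YAML file path or a named list, fills in documented defaults,
#' and collects every validation problem before failing, so a broken config
#' is reported in full. Unknown keys produce warnings, value errors abort.
#'
#' @param config path to a YAML file or a named list.
#' @return a validated `run_config` list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_bn("config file not found: ", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  stopifnot(is.list(config))
  defs <- config_defaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown))
    warning("unknown config key(s) ignored: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defs, config[intersect(names(config), names(defs))])
  errs <- character(0)
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(cfg$mode %in% c("synthetic", "real"), "mode must be 'synthetic' or 'real'")
  chk(is.numeric(cfg$tc_threshold) && cfg$tc_threshold >= 0 && cfg$tc_threshold <= 1,
      "tc_threshold must be in [0, 1]")
  chk(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha <= 1,
      "alpha must be in (0,1]")
  chk(is.numeric(cfg$resolution) && cfg$resolution > 0,
      "resolution must be positive")
  chk(is.numeric(cfg$top_k) && cfg$top_k >= 1, "top_k must be >= 1")
  chk(cfg$weighting %in% c("indicator", "source_count"),
      "weighting must be 'indicator' or 'source_count'")
  chk(cfg$adjust %in% c("none", "BH"), "adjust must be 'none' or 'BH'")
  chk(is.numeric(cfg$min_module_size) && cfg$min_module_size >= 1,
      "min_module_size must be >= 1")
  chk(is.numeric(cfg$seed), "seed must be an integer")
  if (identical(cfg$mode, "real")) {
    for (f in c("compounds", "interactions", "pathways")) {
      if (is.null(cfg[[f]]))
        errs <- c(errs, sprintf("real mode requires input '%s'", f))
      else if (!file.exists(cfg[[f]]))
        errs <- c(errs, sprintf("input '%s' not found: %s", f, cfg[[f]]))
    }
  } else {
    chk(is.list(cfg$synthetic), "synthetic must be a mapping of spec overrides")
  }
  if (length(errs))
    stop_bn("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full pipeline and write all stage outputs
#'
#' Stages: (1) obtain inputs (generate + emit the synthetic dataset, or load
#' the real-mode files), (2) similarity edges, (3) CS network, (4) enrichment
#' and TPT network, (5) bilayer scoring, (6) ranking / pathway focus. Every
#' stage writes its output files into `outdir` and the run manifest records
#' the configuration, its hash, derived seeds, per-stage row counts and the
#' final top-k table. One seed in the config fans out to per-stage seeds via
#' a fixed Lehmer step, so individual stages are reproducible.
#'
#' @param config a `run_config` from [validate_config()], a YAML path, or a
#'   named list of overrides.
#' @return (invisibly) the manifest list; all outputs under `config$outdir`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  out <- cfg$outdir
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE, showWarnings = FALSE))
    stop_bn("cannot create output directory: ", out)
  log_path <- file.path(out, "run.log")
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(line, "\n", file = log_path, append = TRUE)
    bn_log(..., verbose = cfg$verbose)
  }
  stage <- function(name, expr) {
    logf("stage ", name, " started")
    tryCatch(expr, error = function(e)
      stop_bn(sprintf("stage '%s' failed: %s", name, conditionMessage(e))))
  }

  counts <- list()
  truth <- NULL
  # 1. inputs
  if (identical(cfg$mode, "synthetic")) {
    spec <- do.call(synthetic_spec,
                    utils::modifyList(list(seed = derive_seed(cfg$seed, 1)),
                                      cfg$synthetic))
    ds <- stage("simulate", {
      emit_dataset(spec, file.path(out, "synthetic"))
      generate_dataset(spec, weighting = cfg$weighting)
    })
    compounds <- ds$compounds
    pathways <- ds$pathways
    interactions <- ds$interactions
    truth <- ds$truth
    if (is.null(cfg$focal_pathway)) cfg$focal_pathway <- truth$focal_pathway
  } else {
    compounds <- stage("parse_structures", {
      cs <- parse_structures(cfg$compounds)
      compute_fingerprints(cs, fp_length = cfg$fp_length, fp_kind = cfg$fp_kind)
    })
    pathways <- stage("load_gmt", load_gmt(cfg$pathways))
    interactions <- stage("load_interactions",
                          load_interactions(cfg$interactions,
                                            weighting = cfg$weighting))
  }
  counts$compounds <- length(compounds)
  counts$pathways <- length(pathways)
  counts$interactions <- nrow(interactions)

  # 2-5. analysis
  res <- stage("analyze", analyze_bilayer(
    compounds, pathways, interactions,
    tc_threshold = cfg$tc_threshold, resolution = cfg$resolution,
    seed = cfg$seed, alpha = cfg$alpha, adjust = cfg$adjust,
    min_module_size = cfg$min_module_size,
    weighted = cfg$weighted_louvain))
  counts$similarity_edges <- nrow(res$edges)
  counts$cs_nodes <- igraph::vcount(res$cs$graph)
  counts$cs_edges <- igraph::ecount(res$cs$graph)
  counts$cs_modules <- length(setdiff(unique(res$cs$labels), "CS_others"))
  counts$predicted_targets <- length(res$query)
  counts$enriched_pathways <- nrow(res$enriched)
  counts$tpt_nodes <- igraph::vcount(res$tpt$graph)
  counts$tpt_edges <- igraph::ecount(res$tpt$graph)
  counts$tpt_modules <- length(setdiff(unique(res$tpt$labels), "TPT_others"))

  stage("write_outputs", {
    write_edges_tsv(res$edges, file.path(out, "similarity_edges.tsv"))
    write_network_graphml(res$cs, file.path(out, "cs_network.graphml"))
    write_module_tsv(res$cs, file.path(out, "cs_modules.tsv"))
    write_enrichment_tsv(res$enriched, file.path(out, "enrichment.tsv"))
    write_network_graphml(res$tpt, file.path(out, "tpt_network.graphml"))
    write_module_tsv(res$tpt, file.path(out, "tpt_modules.tsv"))
    export_association_heatmap_table(res$ma, file.path(out, "e_matrix.tsv"))
    write_contributions_tsv(res$ma, file.path(out, "contributions.tsv"))
  })

  # 6. ranking
  top <- stage("rank", {
    if (!is.null(cfg$focal_pathway) &&
        any(res$enriched$pathway == cfg$focal_pathway |
            res$enriched$name == cfg$focal_pathway)) {
      # candidate actives for the pathway of interest: contribution ranking
      # restricted to that pathway's member targets
      focus <- pathway_focus(res$ma, res$tpt, res$enriched, cfg$focal_pathway,
                             k = cfg$top_k)
      rk <- focus$ranking
      rk$focal_pathway <- focus$pathway
      rk
    } else {
      cell <- which(res$ma$e == max(res$ma$e), arr.ind = TRUE)[1, ]
      u <- rownames(res$ma$e)[cell[1]]; v <- colnames(res$ma$e)[cell[2]]
      rk <- rank_compounds(res$ma, u, v, k = cfg$top_k)
      rk$m_u <- u; rk$m_v <- v
      rk
    }
  })
  utils::write.table(top, file.path(out, "top_compounds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(config = unclass(cfg),
                   stage_seeds = list(simulate = derive_seed(cfg$seed, 1),
                                      cs_louvain = derive_seed(cfg$seed, 3),
                                      tpt_louvain = derive_seed(cfg$seed, 4)),
                   counts = counts,
                   top_compounds = top,
                   files = list.files(out, recursive = TRUE))
  hash_file <- tempfile()
  jsonlite::write_json(manifest, hash_file, auto_unbox = TRUE, digits = NA)
  manifest$manifest_hash <- unname(tools::md5sum(hash_file))
  unlink(hash_file)
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  logf("pipeline finished: ", counts$cs_nodes, " networked compounds, ",
       counts$tpt_nodes, " networked targets")
  if (!is.null(truth)) manifest$truth <- truth
  invisible(manifest)
}
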