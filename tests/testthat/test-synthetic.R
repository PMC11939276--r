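# The planted-structure generator: determinism, fingerprint geometry,
# pathway blocks, interaction plants, emitted-file consistency.

test_that("synthetic_spec validates its parameters", {
  expect_s3_class(synthetic_spec(), "synthetic_spec")
  expect_error(synthetic_spec(others_fraction = 1.2), "rates")
  expect_error(synthetic_spec(n_targets = 0), "positive")
  expect_error(synthetic_spec(universe_size = 100, n_targets = 850), "exceed")
  expect_error(synthetic_spec(active_extra_targets = 99, focal_pathway_size = 5),
               "cannot exceed")
})

test_that("generation is deterministic and seed-sensitive", {
  s1 <- tiny_spec(seed = 5L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  emit_dataset(s1, d1)
  emit_dataset(s1, d2)
  for (f in c("compounds.tsv", "interactions.tsv", "pathways.gmt",
              "ground_truth.json"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  d3 <- withr::local_tempdir()
  emit_dataset(tiny_spec(seed = 6L), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "compounds.tsv"))),
                         unname(tools::md5sum(file.path(d3, "compounds.tsv")))))
})

test_that("zero flip rate gives identical fingerprints within a cluster", {
  spec <- tiny_spec(seed = 2L, within_cluster_flip_rate = 0,
                    between_cluster_overlap = 0)
  cp <- generate_compounds(spec)
  fp <- cp$compounds$fingerprints
  cl <- cp$truth$cluster
  m1 <- which(cl == 1)
  expect_equal(tanimoto(fp[m1[1], ], fp[m1[2], ]), 1)
  # disjoint-seed clusters: cross-cluster similarity is tiny, never 0.8
  m2 <- which(cl == 2)
  expect_lt(tanimoto(fp[m1[1], ], fp[m2[1], ]), 0.8)
})

test_that("within-cluster similarity exceeds cross-cluster similarity", {
  for (seed in 1:5) {
    cp <- generate_compounds(tiny_spec(seed = seed))
    fp <- cp$compounds$fingerprints
    cl <- cp$truth$cluster
    tc <- tanimoto_matrix(fp)
    same <- outer(cl, cl, "==") & !is.na(outer(cl, cl, "+"))
    ut <- upper.tri(tc)
    expect_gt(mean(tc[ut & same]), 0.8)
    expect_lt(mean(tc[ut & !same], na.rm = TRUE), 0.3)
    expect_gt(mean(tc[ut & same]), mean(tc[ut & !same], na.rm = TRUE))
  }
})

test_that("pathway blocks respect purity and host the focal pathway", {
  spec <- tiny_spec(seed = 3L, pathway_purity = 1.0)
  pt <- generate_pathways_and_targets(spec)
  tm <- pt$truth$target_module
  decoys <- pt$truth$decoy_pathways
  for (pw in pt$pathways) {
    if (pw$id %in% decoys) next
    mods <- unique(tm[pw$members])
    expect_length(mods[!is.na(mods)], 1)  # purity 1: never straddles blocks
  }
  # focal pathway members all share one module label
  focal <- pt$pathways[[pt$truth$focal_pathway]]
  expect_equal(unique(unname(tm[focal$members])), pt$truth$focal_module)
  # every block backs at least one pathway
  homes <- vapply(pt$pathways, function(p) {
    mods <- table(tm[p$members])
    if (length(mods) == 0) NA_integer_ else as.integer(names(which.max(mods)))
  }, 1L)
  expect_setequal(stats::na.omit(unique(homes)), seq_len(spec$n_target_modules))
})

test_that("planted actives receive their focal-pathway interactions", {
  # background rate zero: actives carry exactly their planted interactions
  spec <- tiny_spec(seed = 4L, background_interaction_rate = 0)
  cp <- generate_compounds(spec)
  pt <- generate_pathways_and_targets(spec)
  it <- generate_interactions(spec, cp, pt)$interactions
  focal <- pt$pathways[[pt$truth$focal_pathway]]$members
  for (a in cp$truth$actives) {
    mine <- it$target[it$compound == a]
    expect_length(mine, spec$active_extra_targets)
    expect_true(all(mine %in% focal))
  }
  # no background, no boost (boost multiplies the background rate):
  # only the planted interactions exist at all
  expect_setequal(unique(it$compound), cp$truth$actives)
})

test_that("interactions concentrate on each cluster's preferred module", {
  spec <- tiny_spec(seed = 7L)
  ds <- generate_dataset(spec)
  it <- ds$interactions
  cl <- ds$truth$cluster
  pref <- ds$truth$cluster_preference
  tm <- ds$truth$target_module
  it_cl <- cl[it$compound]
  it_tm <- tm[it$target]
  keep <- !is.na(it_cl) & !is.na(it_tm)
  on_pref <- pref[it_cl[keep]] == it_tm[keep]
  # boosted (cluster, preferred-module) pairs dominate the clustered rows
  expect_gt(mean(on_pref), 0.5)
  # and the per-pair rate ratio is far above 1
  n_pref_pairs <- sum(vapply(seq_len(spec$n_clusters), function(k)
    sum(cl == k, na.rm = TRUE) * sum(tm == pref[k], na.rm = TRUE), 1))
  n_all_pairs <- sum(!is.na(cl)) * length(tm)
  rate_pref <- sum(on_pref) / n_pref_pairs
  rate_off <- sum(!on_pref) / (n_all_pairs - n_pref_pairs)
  expect_gt(rate_pref / rate_off, 3)
})

test_that("emitted files are consistent with the ground truth", {
  spec <- tiny_spec(seed = 8L)
  d <- withr::local_tempdir()
  emit_dataset(spec, d)
  comp <- utils::read.table(file.path(d, "compounds.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  truth <- jsonlite::read_json(file.path(d, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_true(all(unlist(truth$actives) %in% comp$id))
  expect_equal(nrow(comp), spec$n_compounds)
  # fingerprints survive the hex round-trip
  cs <- read_fingerprint_tsv(file.path(d, "compounds.tsv"))
  direct <- generate_compounds(spec)$compounds
  expect_identical(cs$fingerprints, direct$fingerprints)
  # interactions file matches the in-memory table after merging
  it_file <- load_interactions(file.path(d, "interactions.tsv"))
  it_mem <- generate_dataset(spec)$interactions
  expect_equal(it_file$compound, it_mem$compound)
  expect_equal(it_file$target, it_mem$target)
  expect_equal(it_file$d, it_mem$d)
})
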