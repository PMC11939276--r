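# Interaction loading, e_uv / C(i)_uv scoring, ranking, pathway focus.

fake_layer <- function(labels, degrees = NULL) {
  list(labels = labels,
       degrees = degrees %||% stats::setNames(rep(0L, length(labels)),
                                              names(labels)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("load_interactions merges sources under both weighting modes", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("compound\ttarget\tsource",
               "c1\tT1\tSEA", "c1\tT1\tTCMSP",
               "c2\tT1\tSuperPred", "c2\tT2\tSEA",
               "c3\tT3\tSEA"), f)
  ind <- load_interactions(f, weighting = "indicator")
  expect_equal(nrow(ind), 4)  # (c1,T1) merged
  expect_true(all(ind$d == 1))
  expect_equal(ind$sources[ind$compound == "c1"], "SEA,TCMSP")
  sc <- load_interactions(f, weighting = "source_count")
  expect_equal(sc$d[sc$compound == "c1" & sc$target == "T1"], 2)
  expect_equal(sc$d[sc$compound == "c3"], 1)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1\tT1\tMysteryDB", "c2\tT2"), f2)
  expect_warning(expect_warning(load_interactions(f2), "malformed"),
                 "unknown predictor source")
})

test_that("module_association computes e_uv and contributions by summation", {
  cs <- fake_layer(c(c1 = "CS_Module_1", c2 = "CS_Module_1"))
  tpt <- fake_layer(c(t1 = "TPT_Module_1", t2 = "TPT_Module_1"))
  it <- make_interactions(c("c1", "c2", "c2"), c("t1", "t1", "t2"))
  ma <- module_association(cs, tpt, it)
  expect_equal(ma$e["CS_Module_1", "TPT_Module_1"], 3)
  cc <- ma$contributions
  expect_equal(cc$C[cc$compound == "c1"], 1)
  expect_equal(cc$C[cc$compound == "c2"], 2)
  # definition identity: contributions within a cell sum to e_uv
  expect_equal(sum(cc$C), ma$e["CS_Module_1", "TPT_Module_1"])

  # interactions that join no module pair leave a zero cell
  cs2 <- fake_layer(c(c1 = "CS_Module_1", c9 = "CS_Module_2"))
  ma2 <- module_association(cs2, tpt, it)
  expect_equal(ma2$e["CS_Module_2", "TPT_Module_1"], 0)

  # nothing joining the layers is fatal
  expect_error(
    module_association(fake_layer(c(zz = "CS_Module_1")), tpt, it),
    "no interaction joins")
})

test_that("conservation holds on random bilayer instances", {
  set.seed(61)
  for (rep in 1:20) {
    n_c <- sample(5:20, 1); n_t <- sample(5:20, 1)
    comps <- sprintf("c%02d", seq_len(n_c))
    targs <- sprintf("t%02d", seq_len(n_t))
    cs <- fake_layer(stats::setNames(paste0("U", sample(1:3, n_c, TRUE)), comps))
    tpt <- fake_layer(stats::setNames(paste0("V", sample(1:3, n_t, TRUE)), targs))
    pairs <- expand.grid(compound = comps, target = targs,
                         stringsAsFactors = FALSE)
    pairs <- pairs[stats::runif(nrow(pairs)) < 0.3, ]
    if (nrow(pairs) == 0) next
    it <- make_interactions(pairs$compound, pairs$target,
                            source = sample(c("SEA", "TCMSP", "SuperPred"),
                                            nrow(pairs), TRUE),
                            weighting = sample(c("indicator", "source_count"), 1))
    ma <- module_association(cs, tpt, it)
    expect_equal(sum(ma$e), sum(ma$interactions$d))
    for (u in rownames(ma$e)) for (v in colnames(ma$e)) {
      cc <- ma$contributions
      expect_equal(sum(cc$C[cc$m_u == u & cc$m_v == v]), ma$e[u, v])
    }
  }
})

test_that("merging two compound modules adds their e rows elementwise", {
  set.seed(62)
  comps <- sprintf("c%02d", 1:12)
  targs <- sprintf("t%02d", 1:10)
  labs <- stats::setNames(paste0("U", sample(1:3, 12, TRUE)), comps)
  labs[1:2] <- c("U1", "U2")  # both merged modules are populated
  tpt <- fake_layer(stats::setNames(paste0("V", sample(1:2, 10, TRUE)), targs))
  pairs <- expand.grid(compound = comps, target = targs,
                       stringsAsFactors = FALSE)
  pairs <- pairs[stats::runif(nrow(pairs)) < 0.4, ]
  it <- make_interactions(pairs$compound, pairs$target)
  e_fine <- module_association(fake_layer(labs), tpt, it)$e
  merged <- labs
  merged[merged %in% c("U1", "U2")] <- "U12"
  e_coarse <- module_association(fake_layer(merged), tpt, it)$e
  expect_equal(e_coarse["U12", ], e_fine["U1", ] + e_fine["U2", ])
})

test_that("rank_compounds orders by C, then degree, then id", {
  cs <- fake_layer(c(c1 = "U1", c2 = "U1", c3 = "U1"),
                   degrees = c(c1 = 5L, c2 = 9L, c3 = 2L))
  tpt <- fake_layer(c(t1 = "V1", t2 = "V1"))
  it <- make_interactions(c("c1", "c2", "c2"), c("t1", "t1", "t2"))
  top1 <- rank_compounds(module_association(cs, tpt, it), "U1", "V1", k = 1)
  expect_equal(top1$compound, "c2")

  # all-equal contributions: degree decides, then id
  it2 <- make_interactions(c("c1", "c2", "c3"), c("t1", "t1", "t1"))
  r <- rank_compounds(module_association(cs, tpt, it2), "U1", "V1", k = 3)
  expect_equal(r$compound, c("c2", "c1", "c3"))

  ma <- module_association(cs, tpt, it)
  expect_error(rank_compounds(ma, "U1", "V1", k = 0), "positive")
  expect_error(rank_compounds(ma, "nope", "V1", k = 1), "unknown compound module")
})

test_that("pathway_focus highlights the right cells and restricts the ranking", {
  genes <- c("A", "B", "C", "X", "Y", "Z")
  db <- make_pathways(inside = c("A", "B", "C"),
                      split = c("A", "X"),
                      far = c("X", "Y", "Z"))
  enr <- data.frame(pathway = c("inside", "split", "far"),
                    name = c("inside", "split", "far"),
                    overlap = 3, pathway_size = c(3, 2, 3), query_size = 6,
                    background_size = 60, p = c(1e-5, 1e-3, 1e-5),
                    stringsAsFactors = FALSE)
  tpt <- build_tpt_network(enr, db, seed = 1L)
  cs <- fake_layer(c(c1 = "CS_Module_1", c2 = "CS_Module_2"))
  it <- make_interactions(c("c1", "c1", "c2"), c("A", "B", "X"))
  ma <- module_association(cs, tpt, it)

  # pathway fully inside one target module: one highlighted column
  foc <- pathway_focus(ma, tpt, enr, "inside")
  expect_length(foc$target_modules, 1)
  expect_equal(foc$ranking$compound[1], "c1")
  expect_equal(foc$ranking$C_focal[1], 2)

  # pathway straddling the two modules: two highlighted columns
  foc2 <- pathway_focus(ma, tpt, enr, "split")
  expect_length(foc2$target_modules, 2)

  expect_error(pathway_focus(ma, tpt, enr, "unknown pw"), "not among")
})

test_that("the e_uv table round-trips through its TSV export", {
  cs <- fake_layer(c(c1 = "CS_Module_1", c2 = "CS_Module_2"))
  tpt <- fake_layer(c(t1 = "TPT_Module_1", t2 = "TPT_Module_2"))
  it <- make_interactions(c("c1", "c1", "c2"), c("t1", "t2", "t2"))
  ma <- module_association(cs, tpt, it)
  f <- withr::local_tempfile(fileext = ".tsv")
  export_association_heatmap_table(ma, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t", row.names = 1,
                            check.names = FALSE)
  expect_equal(as.matrix(back), ma$e)

  zero <- ma; zero$e[] <- 0
  export_association_heatmap_table(zero, f)
  expect_true(all(utils::read.table(f, header = TRUE, sep = "\t",
                                    row.names = 1) == 0))
})
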