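# GMT parsing, hypergeometric enrichment, TPT projection and propensity.

test_that("load_gmt parses, deduplicates and rejects junk", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("pw1\tfirst pathway\tA\tB\tC",
               "pw2\tsecond pathway\tB\tB\tD"), f)
  db <- load_gmt(f)
  expect_length(db, 2)
  expect_setequal(db[["pw2"]]$members, c("B", "D"))  # duplicate collapsed

  f2 <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("pw1\tok\tA\tB", "orphan\tno-genes"), f2)
  expect_warning(db2 <- load_gmt(f2), "fewer than 3 fields")
  expect_length(db2, 1)

  f3 <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(0), f3)
  expect_error(load_gmt(f3), "empty GMT")
})

test_that("hypergeometric tail matches closed form on the worked example", {
  # background 10, pathway 5, query 5, overlap 5: P = 1 / C(10,5) = 1/252
  db <- make_pathways(pw = paste0("g", 1:5))
  res <- enrich_targets(paste0("g", 1:5), db, paste0("g", 1:10))
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$overlap, 5)

  # pathway empty after background intersection is dropped
  db2 <- make_pathways(pw = paste0("g", 1:5), ghost = c("zz1", "zz2"))
  res2 <- enrich_targets(paste0("g", 1:5), db2, paste0("g", 1:10))
  expect_false("ghost" %in% res2$pathway)

  # query == background: every overlap is certain, p = 1, nothing passes
  res3 <- enrich_targets(paste0("g", 1:10), db, paste0("g", 1:10))
  expect_equal(nrow(res3), 0)
  expect_true(all(attr(res3, "all")$p == 1))

  expect_error(enrich_targets(character(0), db, paste0("g", 1:10)), "empty query")
  expect_error(enrich_targets("zzz", db, paste0("g", 1:10)), "outside the background")
})

test_that("hypergeometric p equals exhaustive enumeration for small universes", {
  set.seed(41)
  for (rep in 1:25) {
    bg <- sample(5:12, 1)
    m <- sample(1:(bg - 1), 1)       # pathway = first m genes
    k <- sample(1:bg, 1)             # query size
    genes <- sprintf("g%02d", seq_len(bg))
    query <- sample(genes, k)
    db <- make_pathways(pw = genes[seq_len(m)])
    got <- attr(enrich_targets(query, db, genes, alpha = 1), "all")
    ov <- got$overlap[got$pathway == "pw"]
    expect_equal(got$p[got$pathway == "pw"],
                 hyper_tail_enum(ov, m, bg, k), tolerance = 1e-12)
  }
})

test_that("TPT projection links targets co-occurring in enriched pathways", {
  genes <- sprintf("g%02d", 1:40)
  # one enriched pathway {A,B,C}: triangle, all weights 1
  db <- make_pathways(tri = c("A", "B", "C"))
  enr <- data.frame(pathway = "tri", name = "tri", overlap = 3,
                    pathway_size = 3, query_size = 3, background_size = 40,
                    p = 1e-4, stringsAsFactors = FALSE)
  net <- build_tpt_network(enr, db, seed = 1L)
  expect_equal(igraph::vcount(net$graph), 3)
  expect_equal(igraph::ecount(net$graph), 3)
  expect_true(all(net$edges$weight == 1))
  expect_equal(length(unique(net$labels)), 1)  # single pathway, one module

  # {A,B} and {A,C}: path B - A - C, no B-C edge
  db2 <- make_pathways(p1 = c("A", "B"), p2 = c("A", "C"))
  enr2 <- data.frame(pathway = c("p1", "p2"), name = c("p1", "p2"),
                     overlap = 2, pathway_size = 2, query_size = 3,
                     background_size = 40, p = 1e-4, stringsAsFactors = FALSE)
  net2 <- build_tpt_network(enr2, db2, seed = 1L)
  expect_equal(igraph::ecount(net2$graph), 2)
  expect_setequal(paste(net2$edges$a, net2$edges$b),
                  c("A B", "A C"))

  # a target in no enriched pathway never becomes a node
  expect_false("Z" %in% names(net2$labels))

  # two pathway-disjoint target sets -> two modules
  db3 <- make_pathways(m1 = c("A", "B", "C"), m2 = c("X", "Y", "Z"))
  enr3 <- data.frame(pathway = c("m1", "m2"), name = c("m1", "m2"),
                     overlap = 3, pathway_size = 3, query_size = 6,
                     background_size = 40, p = 1e-4, stringsAsFactors = FALSE)
  net3 <- build_tpt_network(enr3, db3, seed = 1L, min_module_size = 1)
  expect_equal(length(unique(net3$labels)), 2)
})

test_that("TPT edge weights equal a brute-force co-membership count", {
  set.seed(51)
  genes <- sprintf("g%02d", 1:15)
  for (rep in 1:10) {
    sets <- lapply(1:5, function(i) sample(genes, sample(2:6, 1)))
    names(sets) <- paste0("pw", 1:5)
    db <- do.call(make_pathways, sets)
    enr <- data.frame(pathway = names(sets), name = names(sets),
                      overlap = lengths(sets), pathway_size = lengths(sets),
                      query_size = 15, background_size = 15, p = 1e-3,
                      stringsAsFactors = FALSE)
    net <- build_tpt_network(enr, db, seed = rep)
    # nodes are exactly the union of enriched member sets
    expect_setequal(names(net$labels), unique(unlist(sets)))
    for (r in seq_len(nrow(net$edges))) {
      a <- net$edges$a[r]; b <- net$edges$b[r]
      shared <- sum(vapply(sets, function(s) a %in% s && b %in% s, TRUE))
      expect_equal(net$edges$weight[r], shared)
    }
  }
})

test_that("module_propensity puts a module's defining pathway first", {
  db <- make_pathways(own = c("A", "B", "C", "D"),
                      other = c("X", "Y", "Z"),
                      mixed = c("A", "X"))
  enr <- data.frame(pathway = c("own", "other", "mixed"),
                    name = c("own", "other", "mixed"),
                    overlap = c(4, 3, 2), pathway_size = c(4, 3, 2),
                    query_size = 7, background_size = 50,
                    p = c(1e-6, 1e-6, 1e-2), stringsAsFactors = FALSE)
  net <- build_tpt_network(enr, db, seed = 1L)
  prop <- module_propensity(net, enr, db, top_k = 3)
  own_module <- unname(net$labels[["A"]])
  top <- prop[prop$module == own_module & prop$rank == 1, ]
  expect_equal(top$pathway, "own")
})
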