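test_that("edge_weight evaluates the children-count formula and clips", {
  cfg <- hgs_config(c = 2, d = c(is_a = 0.3, part_of = 0.2), w_max = 0.9)
  expect_equal(edge_weight(3, "is_a", cfg), 1 / 5 + 0.3)          # = 0.5
  expect_equal(edge_weight(0, "is_a", cfg), 0.8)                  # below clip
  cfg1 <- hgs_config(c = 1, d = c(is_a = 0.3), w_max = 0.9)
  expect_equal(edge_weight(0, "is_a", cfg1), 0.9)                 # clipped
  expect_error(edge_weight(-1, "is_a", cfg), "non-negative")
  expect_error(edge_weight(1, "regulates", cfg), "relation")
  expect_error(hgs_config(c = 0), "positive")
  expect_error(hgs_config(d = c(is_a = 1.2)), "\\[0, 1\\)")
  expect_error(hgs_config(w_max = 1), "\\(0, 1\\)")
})

test_that("semantic values decay multiplicatively along a chain", {
  ch <- chain_dag()
  s <- semantic_values(ch, "C", cfg_fixed(0.5))
  expect_equal(s[["C"]], 1)
  expect_equal(s[["B"]], 0.5)
  expect_equal(s[["A"]], 0.25)

  root <- semantic_values(ch, "A", cfg_fixed(0.5))
  expect_identical(names(root), "A")
  expect_equal(root[["A"]], 1)
})

test_that("semantic value at a shared ancestor is the max over paths", {
  # diamond D->B (is_a), D->C (part_of), B->A, C->A (is_a); c=5 gives
  # w(D->B)=1/5+0.3=0.5, w(D->C)=1/5+0.6=0.8, w(B->A)=w(C->A)=1/6+0.3
  cfg <- hgs_config(c = 5, d = c(is_a = 0.3, part_of = 0.6), w_max = 0.9)
  s <- semantic_values(diamond_dag(), "D", cfg)
  expect_equal(s[["B"]], 0.5)
  expect_equal(s[["C"]], 0.8)
  expect_equal(s[["A"]], (1 / 6 + 0.3) * 0.8)  # stronger path via C wins
})

test_that("weight_on switch selects whose children count feeds the weight", {
  ch <- chain_dag()
  cfg_child <- hgs_config(c = 2, d = c(is_a = 0.1), w_max = 0.9, weight_on = "child")
  cfg_parent <- hgs_config(c = 2, d = c(is_a = 0.1), w_max = 0.9, weight_on = "parent")
  # edge C->B: C has 0 children, B has 1
  expect_equal(semantic_values(ch, "C", cfg_child)[["B"]], 1 / 2 + 0.1)
  expect_equal(semantic_values(ch, "C", cfg_parent)[["B"]], 1 / 3 + 0.1)
})

test_that("term similarity matches the hand-computed chain value exactly", {
  ch <- chain_dag()
  cfg <- cfg_fixed(0.5)
  expect_equal(term_similarity(ch, "C", "B", cfg), 2.25 / 3.25, tolerance = 1e-14)
  expect_identical(term_similarity(ch, "B", "B", cfg), 1)
  # disjoint components share no ancestor
  two <- ontology_dag(c("A", "B", "X", "Y"),
                      data.frame(child = c("B", "Y"), parent = c("A", "X"),
                                 relation = "is_a"))
  expect_equal(term_similarity(two, "B", "Y", cfg), 0)
  expect_equal(term_similarity(two, "B", "Y", cfg),
               term_similarity(two, "Y", "B", cfg))
})

test_that("term similarity equals a fixed-weight Wang oracle on random DAGs", {
  dag <- synth_dag(60, 5, 2, 0, seed = 7)   # single relation kind
  cfg <- cfg_fixed(0.8)
  set.seed(7)
  for (i in 1:25) {
    ab <- sample(dag$terms, 2)
    expect_equal(term_similarity(dag, ab[1], ab[2], cfg),
                 wang_term_sim(dag, ab[1], ab[2], 0.8), tolerance = 1e-9)
  }
})

test_that("gene similarity is the best-match average over term pairs", {
  ch <- chain_dag()
  cfg <- cfg_fixed(0.5)
  expect_equal(gene_similarity(ch, "C", "C", cfg), 1)
  s_cb <- term_similarity(ch, "C", "B", cfg)
  expect_equal(gene_similarity(ch, "C", "B", cfg), s_cb)   # single-pair BMA
  # terms1={C,B}, terms2={B}: (max(s_cb) + max(1) + max(s_cb, 1)) / 3
  expect_equal(gene_similarity(ch, c("C", "B"), "B", cfg), (s_cb + 1 + 1) / 3)
  expect_equal(gene_similarity(ch, c("C", "B"), "B", cfg),
               gene_similarity(ch, "B", c("C", "B"), cfg))
  expect_error(gene_similarity(ch, character(0), "B", cfg), "empty")
})

test_that("adding an unrelated term dilutes the best-match average", {
  two <- ontology_dag(c("A", "B", "C", "X", "Y"),
                      data.frame(child = c("B", "C", "Y"),
                                 parent = c("A", "B", "X"),
                                 relation = "is_a"))
  cfg <- cfg_fixed(0.5)
  base <- gene_similarity(two, "C", "B", cfg)
  diluted <- gene_similarity(two, "C", c("B", "Y"), cfg)  # Y shares nothing
  expect_lt(diluted, base)
})

test_that("GFS matrix equals cache-free pairwise gene similarity", {
  dag <- synth_dag(80, 5, 2, 0.3, seed = 11)
  set.seed(11)
  ann <- stats::setNames(
    lapply(1:6, function(i) sample(dag$terms, sample(2:4, 1))),
    paste0("g", 1:6))
  m <- build_gfs_matrix(dag, ann)
  expect_equal(dim(m), c(6, 6))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(m[i, j], gene_similarity(dag, ann[[i]], ann[[j]]),
                 tolerance = 1e-12)
  }
  # trivial shapes
  expect_equal(build_gfs_matrix(dag, ann[1]), matrix(1, 1, 1, dimnames = list("g1", "g1")))
  twin <- build_gfs_matrix(dag, list(a = ann[[1]], b = ann[[1]]))
  expect_equal(unname(twin), matrix(1, 2, 2))
})

test_that("GFS matrix invariants hold on random synthetic annotation sets", {
  for (s in 0:9) {
    dag <- synth_dag(50, 4, 2, 0.25, seed = s)
    set.seed(s)
    ann <- stats::setNames(
      lapply(1:8, function(i) sample(dag$terms, sample(1:4, 1))),
      paste0("g", 1:8))
    m <- build_gfs_matrix(dag, ann)
    expect_true(isSymmetric(m, tol = 1e-12))
    expect_identical(unname(diag(m)), rep(1, 8))
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("genes with no in-ontology terms error unless dropped explicitly", {
  dag <- chain_dag()
  ann <- list(good = c("A", "B"), bad = "ZZZ")
  expect_error(build_gfs_matrix(dag, ann), "bad")
  expect_warning(m <- build_gfs_matrix(dag, ann, drop_unannotated = TRUE), "bad")
  expect_equal(rownames(m), "good")
})

test_that("annotation readers handle TSV and GAF carriers", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tA", "g1\tB", "g2\tB"), tsv)
  ann <- read_annotations(tsv)
  expect_equal(ann, list(g1 = c("A", "B"), g2 = "B"))

  gaf <- withr::local_tempfile(fileext = ".gaf")
  gaf_row <- function(gene, term, aspect)
    paste(c("DB", gene, gene, "", term, "REF", "IEA", "", aspect,
            rep("", 8)), collapse = "\t")
  writeLines(c("!gaf-version: 2.2",
               gaf_row("g1", "A", "P"),
               gaf_row("g1", "C", "F"),   # non-BP aspect dropped
               gaf_row("g2", "B", "P")), gaf)
  ann2 <- read_annotations(gaf, format = "gaf")
  expect_equal(ann2, list(g1 = "A", g2 = "B"))
})

test_that("similarity matrix CSV round trip preserves values to 6 decimals", {
  dag <- synth_dag(40, 4, 2, 0.2, seed = 3)
  set.seed(3)
  ann <- stats::setNames(lapply(1:4, function(i) sample(dag$terms, 3)),
                         paste0("g", 1:4))
  m <- build_gfs_matrix(dag, ann)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_gfs_matrix(m, csv)
  back <- read_gfs_matrix(csv)
  expect_equal(back, m, tolerance = 1e-6)
  expect_identical(rownames(back), rownames(m))
})
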