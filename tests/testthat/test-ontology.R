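test_that("read_obo parses terms, edges, obsolete flags and namespaces", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: A", "name: root", "namespace: biological_process", "",
    "[Term]", "id: B", "name: child", "namespace: biological_process",
    "is_a: A ! root", "",
    "[Term]", "id: M", "name: other", "namespace: molecular_function",
    "is_a: A", "",
    "[Term]", "id: Z", "name: gone", "namespace: biological_process",
    "is_a: A", "is_obsolete: true", "",
    "[Typedef]", "id: part_of"), obo)

  dag <- read_obo(obo)
  expect_setequal(dag$terms, c("A", "B", "M"))        # obsolete Z dropped
  expect_equal(nrow(dag$edges), 2)
  expect_equal(dag$namespace[["M"]], "molecular_function")

  bp <- read_obo(obo, namespace = "biological_process")
  expect_setequal(bp$terms, c("A", "B"))
  expect_equal(nrow(bp$edges), 1)
  expect_equal(bp$edges$relation, "is_a")
})

test_that("part_of relationships become edges; other relations are ignored", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: A", "",
    "[Term]", "id: B", "relationship: part_of A", "",
    "[Term]", "id: C", "relationship: regulates A", "is_a: B"), obo)
  dag <- read_obo(obo)
  expect_equal(nrow(dag$edges), 2)
  expect_setequal(dag$edges$relation, c("part_of", "is_a"))
  only_isa <- read_obo(obo, relations = "is_a")
  expect_equal(only_isa$edges$relation, "is_a")
})

test_that("cycles and malformed files are rejected with clear errors", {
  expect_error(
    ontology_dag(c("A", "B"),
                 data.frame(child = c("A", "B"), parent = c("B", "A"),
                            relation = "is_a")),
    "cycle")
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines("this is not OBO at all", obo)
  expect_error(read_obo(obo), "unparseable")
  expect_error(read_obo(file.path(tempdir(), "missing-xyz.obo")), "no such file")
})

test_that("ancestor_dag handles chain, root and diamond cases", {
  ch <- chain_dag()
  td <- ancestor_dag(ch, "C")
  expect_setequal(td$termset, c("A", "B", "C"))
  expect_equal(nrow(td$edges), 2)
  expect_identical(td$focus, "C")

  root <- ancestor_dag(ch, "A")
  expect_identical(root$termset, "A")
  expect_equal(nrow(root$edges), 0)

  di <- ancestor_dag(diamond_dag(), "D")
  expect_setequal(di$termset, c("A", "B", "C", "D"))
  expect_equal(nrow(di$edges), 4)

  expect_error(ancestor_dag(ch, "nope"), "unknown term")
})

test_that("children_count counts distinct children over all relation kinds", {
  di <- diamond_dag()
  expect_equal(children_count(di, "D"), 0)   # leaf
  expect_equal(children_count(di, "A"), 2)   # diamond top
  # 3 is_a children and 1 part_of child -> 4
  dag <- ontology_dag(c("P", "a", "b", "c", "d"),
                      data.frame(child = c("a", "b", "c", "d"), parent = "P",
                                 relation = c("is_a", "is_a", "is_a", "part_of")))
  expect_equal(children_count(dag, "P"), 4)
  # same pair under two relation kinds still counts one child
  dup <- ontology_dag(c("P", "a"),
                      data.frame(child = c("a", "a"), parent = "P",
                                 relation = c("is_a", "part_of")))
  expect_equal(children_count(dup, "P"), 1)
  expect_error(children_count(di, "nope"), "unknown term")
})

test_that("ancestor sets match the brute-force fixed point on random DAGs", {
  for (s in 0:19) {
    dag <- synth_dag(25, 4, 2, 0.3, seed = s)
    x <- dag$terms[[sample.int(25, 1)]]
    expect_setequal(ancestor_dag(dag, x)$termset, bf_ancestors(dag, x))
    # children counts sum to the number of distinct child-parent pairs
    uniq <- dag$edges[!duplicated(dag$edges[c("child", "parent")]), ]
    expect_equal(sum(dag$n_children), nrow(uniq))
  }
})

test_that("OBO write/read round trip reproduces the graph", {
  dag <- synth_dag(40, 5, 2, 0.3, seed = 5)
  obo <- withr::local_tempfile(fileext = ".obo")
  write_obo(dag, obo)
  back <- read_obo(obo)
  expect_setequal(back$terms, dag$terms)
  key <- function(d) sort(do.call(paste, d$edges))
  expect_identical(key(back), key(dag))
  expect_identical(back$n_children[sort(names(back$n_children))],
                   dag$n_children[sort(names(dag$n_children))])
})
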