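test_that("DAG construction validates structure and inserts a virtual root", {
  dag <- fixture_dag()
  expect_s3_class(dag, "disease_dag")
  expect_equal(dag$root, "root")
  expect_setequal(dag$ancestors$c, c("c", "a", "b", "root"))

  # several maximal terms -> virtual root
  dag2 <- disease_dag(data.frame(child = c("x", "y"), parent = c("p", "q")))
  expect_equal(dag2$root, "ROOT*")
  expect_true(all(vapply(dag2$ancestors, function(a) "ROOT*" %in% a,
                         logical(1))))

  expect_error(disease_dag(data.frame(child = "a", parent = "a")),
               "self-loop")
  expect_error(disease_dag(data.frame(child = c("a", "b", "root"),
                                      parent = c("b", "a", "a")),
               ), "cycle")
})

test_that("frequency propagation follows the child-sum recursion", {
  chain <- disease_dag(data.frame(child = c("a", "b"), parent = c("root", "a")))
  ft <- propagate_frequency(chain, c(root = 1, a = 2, b = 4))
  expect_equal(ft[c("b", "a", "root")], c(b = 4, a = 6, root = 7))

  # leaf with no children keeps its own count
  expect_equal(ft[["b"]], 4)
  # zero counts propagate to zero
  expect_equal(unname(propagate_frequency(chain, c(root = 0))), c(0, 0, 0))

  # multi-parent term counted once per parent path
  dag <- fixture_dag()
  ft2 <- propagate_frequency(dag, fixture_counts)
  # root = f(root) + FT(a) + FT(b): FT(a) = 1 + 1 + 2 = 4, FT(b) = 0 + 1 = 1
  expect_equal(ft2[["a"]], 4)
  expect_equal(ft2[["b"]], 1)
  expect_equal(ft2[["root"]], 6)
  # tree-shaped DAG conserves mass; with the double-counted "c" it exceeds it
  expect_gte(ft2[["root"]], sum(fixture_counts))
})

test_that("normalization divides by the root and flags degenerate corpora", {
  chain <- disease_dag(data.frame(child = c("a", "b"), parent = c("root", "a")))
  pt <- normalize_frequency(propagate_frequency(chain, c(root = 1, a = 2, b = 4)),
                            chain)
  expect_equal(pt[["a"]], 6 / 7)
  expect_equal(pt[["root"]], 1)
  expect_true(all(pt >= 0 & pt <= 1))
  expect_error(normalize_frequency(propagate_frequency(chain, c(root = 0)), chain),
               "degenerate corpus")
})

test_that("pair similarity handles self, root-only overlap and the diamond", {
  # diamond: c under a and b, both under root; counts chosen so
  # PT(a) = 0.5, PT(c) = 0.25
  dag <- disease_dag(data.frame(child = c("a", "b", "c", "c"),
                                parent = c("root", "root", "a", "b")))
  pt <- normalize_frequency(
    propagate_frequency(dag, c(root = 1, a = 1, b = 0, c = 1)), dag)
  expect_equal(pt[["a"]], 0.5)
  expect_equal(pt[["c"]], 0.25)
  expect_equal(semantic_similarity_pair(pt, dag, "c", "a"), 2 / 3)
  # self-similarity with informative PT
  expect_equal(semantic_similarity_pair(pt, dag, "c", "c"), 1)
  # only common ancestor is the root -> 0
  expect_equal(semantic_similarity_pair(pt, dag, "a", "b"), 0)
  # d1 an ancestor of d2: COM = {d1}
  expect_equal(semantic_similarity_pair(pt, dag, "a", "c"),
               2 * log(0.5) / (log(0.5) + log(0.25)))
  expect_error(semantic_similarity_pair(pt, dag, "zz", "a"), "unknown term")

  # a term with zero annotation mass has no information content
  dag0 <- disease_dag(data.frame(child = c("a", "e"), parent = c("root", "root")))
  pt0 <- normalize_frequency(propagate_frequency(dag0, c(root = 1, a = 2)), dag0)
  expect_equal(pt0[["e"]], 0)
  expect_equal(semantic_similarity_pair(pt0, dag0, "e", "a"), 0)
  expect_equal(semantic_similarity_pair(pt0, dag0, "e", "e"), 0)
})

test_that("similarity matrix equals the pairwise brute-force oracle", {
  dag <- fixture_dag()
  for (seed in 1:3) {
    set.seed(seed)
    counts <- stats::setNames(rpois(5, 3), dag$terms)
    counts[1] <- counts[1] + 1   # keep the corpus non-degenerate
    ann <- corpus_annotation(counts)
    s <- disease_semantic_similarity(dag, ann)[[1]]
    pt <- normalize_frequency(propagate_frequency(dag, ann), dag)
    expect_equal(s, oracle_semantic_matrix(pt, dag), tolerance = 1e-12)
    expect_equal(s, t(s))
    expect_true(all(s >= 0 & s <= 1))
  }

  # a larger random DAG against the oracle
  sim <- simulate_disease_ontology(n_terms = 25, seed = 4)
  s <- disease_semantic_similarity(sim$dag, sim$corpora[[1]])[[1]]
  pt <- normalize_frequency(propagate_frequency(sim$dag, sim$corpora[[1]]),
                            sim$dag)
  expect_equal(s, oracle_semantic_matrix(pt, sim$dag), tolerance = 1e-12)
})

test_that("identical corpora give identical matrices; unrelated leaves score 0", {
  dag <- disease_dag(data.frame(child = c("a", "b"), parent = c("root", "root")))
  ann <- corpus_annotation(c(root = 1, a = 2, b = 3))
  out <- disease_semantic_similarity(dag, list(ann, ann))
  expect_identical(out[[1]], out[[2]])
  expect_equal(out[[1]]["a", "b"], 0)
})

test_that("deeper common ancestors never decrease similarity", {
  # same pair PTs, ancestor PT decreasing -> similarity non-decreasing
  dag <- fixture_dag()
  denom <- log(0.3) + log(0.2)
  sims <- vapply(c(0.9, 0.6, 0.35), function(pa) 2 * log(pa) / denom,
                 numeric(1))
  expect_true(all(diff(sims) >= 0))
})

test_that("union propagation counts each annotation once per ancestor", {
  dag <- fixture_dag()
  s <- disease_semantic_similarity(dag, corpus_annotation(fixture_counts),
                                   mode = "union")[[1]]
  # under union mode FT(root) = total annotation mass
  ftu <- knmbp:::.propagate_frequency_union(dag, fixture_counts)
  expect_equal(ftu[["root"]], sum(fixture_counts))
  expect_true(all(s >= 0 & s <= 1))
})
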