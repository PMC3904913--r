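fx <- exportin5_example()

test_that("most particular terms: worked example, self-comparison, oracle", {
  expect_identical(most_particular_terms(fx$graph, fx$sets$hsa, fx$sets$dme),
                   "tRNA binding")
  expect_identical(most_particular_terms(fx$graph, fx$sets$hsa, fx$sets$rno),
                   "protein binding")
  expect_identical(most_particular_terms(fx$graph, fx$sets$rno, fx$sets$hsa),
                   character())

  for (seed in 1:6) {
    g <- random_dag(fixture_spec(n_terms = 22L, seed = seed))
    set.seed(seed)
    for (k in 1:4) {
      s1 <- sample_terms(g, 4L); s2 <- sample_terms(g, 4L)
      expect_setequal(most_particular_terms(g, s1, s2), oracle_mpt(g, s1, s2))
      expect_identical(most_particular_terms(g, s1, s1), character())
    }
  }

  terms <- data.frame(id = c("r1", "r2"), namespace = c("a", "b"))
  g2 <- ontology_graph(terms, NULL)
  expect_error(most_particular_terms(g2, "r1", "r2"), "mix namespaces")
})

test_that("most informative common terms: worked example, self-comparison, oracle", {
  expect_setequal(
    most_informative_common_terms(fx$graph, fx$sets$hsa, fx$sets$dme),
    c("protein transporter activity", "protein binding"))
  expect_setequal(
    most_informative_common_terms(fx$graph, fx$sets$hsa, fx$sets$rno),
    c("tRNA binding", "protein transporter activity"))
  # against itself: the deepest terms of the expanded set
  expect_setequal(
    most_informative_common_terms(fx$graph, fx$sets$hsa, fx$sets$hsa),
    c("tRNA binding", "protein binding", "protein transporter activity"))

  for (seed in 1:6) {
    g <- random_dag(fixture_spec(n_terms = 22L, seed = seed))
    set.seed(100 + seed)
    for (k in 1:4) {
      s1 <- sample_terms(g, 4L); s2 <- sample_terms(g, 4L)
      expect_setequal(most_informative_common_terms(g, s1, s2),
                      oracle_mct(g, s1, s2))
    }
  }
})

test_that("MICA informativeness: worked example, membership case, empty set, oracle", {
  expect_equal(
    mica_informativeness(fx$graph, fx$model, "tRNA binding", fx$sets$dme),
    1.8)
  # a term inside the other set is its own most informative common ancestor
  expect_equal(
    mica_informativeness(fx$graph, fx$model, "protein binding", fx$sets$dme),
    2.44)
  expect_equal(
    mica_informativeness(fx$graph, fx$model, "tRNA binding", character()),
    0)

  for (seed in 1:5) {
    g <- random_dag(fixture_spec(n_terms = 20L, seed = seed))
    model <- sv_model(g)
    set.seed(200 + seed)
    for (k in 1:4) {
      t <- sample_terms(g, 1L); s2 <- sample_terms(g, 3L)
      expect_equal(mica_informativeness(g, model, t, s2),
                   oracle_mica(g, model, t, s2))
    }
  }
})

test_that("particular informativeness reproduces the worked example and its conventions", {
  expect_equal(
    particular_informativeness(fx$graph, fx$model, fx$sets$hsa, fx$sets$dme),
    4.201 - 1.8)
  expect_equal(
    particular_informativeness(fx$graph, fx$model, fx$sets$hsa, fx$sets$rno),
    2.44 - 1.8)
  expect_equal(
    particular_informativeness(fx$graph, fx$model, fx$sets$hsa, fx$sets$hsa),
    0)
  # against the empty set the MICA contributes nothing
  expect_equal(
    particular_informativeness(fx$graph, fx$model, fx$sets$dme, character()),
    2.44 + 2.952)
})

test_that("particularity reproduces the worked example values", {
  par_dme <- particularity(fx$graph, fx$model, fx$sets$hsa, fx$sets$dme)
  expect_equal(par_dme, 2.401 / (2.401 + 2.952 + 2.44))
  expect_equal(round(par_dme, 3), 0.308)
  expect_equal(round(particularity(fx$graph, fx$model,
                                   fx$sets$hsa, fx$sets$rno), 3), 0.082)
  expect_equal(particularity(fx$graph, fx$model, fx$sets$rno, fx$sets$hsa), 0)
  expect_error(particularity(fx$graph, fx$model, character(), character()),
               "meaningless")
})

test_that("formal particularity properties hold on randomized instances", {
  for (seed in 1:8) {
    g <- random_dag(fixture_spec(n_terms = 25L, seed = seed))
    model <- sv_model(g)
    set.seed(300 + seed)
    for (k in 1:3) {
      s1 <- sample_terms(g, 4L); s2 <- sample_terms(g, 4L)
      expect_equal(particularity(g, model, s1, s1), 0)     # self
      expect_equal(particularity(g, model, s1, character()), 1)
      expect_equal(particularity(g, model, character(), s1), 0)
      p12 <- particularity(g, model, s1, s2)
      p21 <- particularity(g, model, s2, s1)
      expect_true(p12 >= 0 && p12 <= 1 && p21 >= 0 && p21 <= 1)
    }
  }
  # non-symmetry is allowed and realised on the worked example
  expect_false(isTRUE(all.equal(
    particularity(fx$graph, fx$model, fx$sets$hsa, fx$sets$dme),
    particularity(fx$graph, fx$model, fx$sets$dme, fx$sets$hsa))))
})

test_that("particularity ignores additions to the second set from a disjoint subtree", {
  for (seed in 1:5) {
    lobes <- two_lobe_graph(seed)
    g <- lobes$graph
    model <- sv_model(g)
    set.seed(400 + seed)
    s1 <- sample(lobes$lobe_a, 3L)
    s2 <- sample_terms(g, 3L)
    s3 <- sample(lobes$lobe_b, 3L)
    expect_equal(particularity(g, model, s1, s2),
                 particularity(g, model, s1, union(s2, s3)),
                 tolerance = 1e-12)
  }
})

test_that("Wang term similarity: identity, sibling enumeration, range", {
  g <- chain_graph(2)
  expect_equal(wang_term_similarity(g, "t2", "t2"), 1)

  sib <- ontology_graph(
    data.frame(id = c("root", "p", "a", "b")),
    data.frame(child = c("p", "a", "b"), parent = c("root", "p", "p"),
               relation = "is_a"))
  # shared ancestors {p, root}: S = 0.8 and 0.64 from each side
  expect_equal(wang_term_similarity(sib, "a", "b"),
               (0.8 + 0.64 + 0.8 + 0.64) / (2.44 + 2.44))

  star <- ontology_graph(
    data.frame(id = c("root", "a", "b")),
    data.frame(child = c("a", "b"), parent = "root", relation = "is_a"))
  expect_equal(wang_term_similarity(star, "a", "b"),
               (0.8 + 0.8) / (1.8 + 1.8))

  for (seed in 1:3) {
    g <- random_dag(fixture_spec(n_terms = 20L, seed = seed))
    set.seed(500 + seed)
    for (k in 1:5) {
      ab <- sample(g$terms$id, 2L)
      s <- wang_term_similarity(g, ab[1L], ab[2L])
      expect_true(s >= 0 && s <= 1)
      expect_equal(s, wang_term_similarity(g, ab[2L], ab[1L]))
    }
  }
})

test_that("Lin term similarity: identity, root-only overlap, range", {
  g <- ontology_graph(
    data.frame(id = c("root", "a", "b")),
    data.frame(child = c("a", "b"), parent = "root", relation = "is_a"))
  corpus <- annotation_corpus(g, list(g1 = "a", g2 = "b"))
  expect_equal(lin_term_similarity(g, corpus, "a", "a"), 1)
  # only shared ancestor is the root, IC(root)=0
  expect_equal(lin_term_similarity(g, corpus, "a", "b"), 0)
  expect_equal(lin_term_similarity(g, corpus, "root", "a"), 0)
})

test_that("set similarity: identity, empty-set error, bma matches the double-loop oracle", {
  g <- random_dag(fixture_spec(n_terms = 20L, seed = 3L))
  set.seed(600)
  s <- sample_terms(g, 4L)
  for (combine in c("bma", "max"))
    expect_equal(set_similarity(g, s, s, combine = combine), 1)
  # averaging the whole matrix dilutes the diagonal: self-similarity < 1
  expect_lt(set_similarity(g, s, s, combine = "avg"), 1)
  expect_error(set_similarity(g, character(), s), "empty annotation set")

  corpus <- random_corpus(g, fixture_spec(n_terms = 20L, n_genes = 15L,
                                          seed = 3L))
  for (k in 1:5) {
    s1 <- sample_terms(g, 3L); s2 <- sample_terms(g, 4L)
    expect_equal(set_similarity(g, s1, s2),
                 oracle_bma(s1, s2, function(a, b)
                   wang_term_similarity(g, a, b)))
    covered <- names(corpus$propagated_counts)
    t1 <- intersect(s1, covered); t2 <- intersect(s2, covered)
    if (length(t1) && length(t2))
      expect_equal(set_similarity(g, t1, t2, method = "lin",
                                  corpus = corpus),
                   oracle_bma(t1, t2, function(a, b)
                     lin_term_similarity(g, corpus, a, b)))
  }
})

test_that("compare_sets is self-consistent with the individual operations", {
  cmp <- compare_sets(fx$graph, fx$model, fx$sets$hsa, fx$sets$dme,
                      sim_method = "none")
  expect_true(is.na(cmp$sim))
  expect_equal(round(cmp$par12, 3), 0.308)
  expect_equal(cmp$par21, 0)
  expect_identical(cmp$mpt12, "tRNA binding")

  g <- random_dag(fixture_spec(n_terms = 22L, seed = 11L))
  model <- sv_model(g)
  set.seed(700)
  for (k in 1:4) {
    s1 <- sample_terms(g, 3L); s2 <- sample_terms(g, 4L)
    cmp <- compare_sets(g, model, s1, s2)
    expect_setequal(cmp$mpt12, most_particular_terms(g, s1, s2))
    expect_setequal(cmp$mpt21, most_particular_terms(g, s2, s1))
    expect_setequal(cmp$mct, most_informative_common_terms(g, s1, s2))
    expect_equal(cmp$par12, particularity(g, model, s1, s2))
    expect_equal(cmp$par21, particularity(g, model, s2, s1))
    expect_equal(cmp$sim, set_similarity(g, s1, s2))
    expect_equal(compare_sets(g, model, s1, s1)$par12, 0)
    expect_equal(compare_sets(g, model, s1, s1)$sim, 1)
    # invariants on the structure
    expect_length(intersect(cmp$mpt12, cmp$sg2_star), 0L)
    expect_true(all(cmp$mct %in% intersect(cmp$sg1_star, cmp$sg2_star)))
  }
})
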