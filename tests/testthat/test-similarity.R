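test_that("propagate implements the max rule over descendant multiplicities", {
  expect_equal(propagate("A1", toy$ontology), c(A = 1, A1 = 1, R = 1))
  expect_equal(propagate(c(A1 = 2, A2 = 1), toy$ontology),
               c(A = 2, A1 = 2, A2 = 1, R = 2))
  expect_length(propagate(character(0), toy$ontology), 0)
  expect_error(propagate("ZZ", toy$ontology), "unknown")
  # sum rule accumulates instead
  expect_equal(propagate(c(A1 = 2, A2 = 1), toy$ontology, rule = "sum"),
               c(A = 3, A1 = 2, A2 = 1, R = 3))
})

test_that("resnik_bma matches the worked toy examples", {
  ont <- toy$ontology; ic <- toy$ic
  expect_equal(resnik_bma(c("A1", "A2"), c("A1", "B1"), ont, ic), -log(2 / 3))
  expect_equal(resnik_bma("A1", "A1", ont, ic), -log(2 / 3))
  expect_equal(resnik_bma("A2", "B1", ont, ic), 0)
  expect_equal(resnik_bma("A2", character(0), ont, ic), 0)
  expect_error(resnik_bma(character(0), "A1", ont, ic), "empty query")
  # weighted multiplicity: duplicate query class shifts the average
  expect_equal(resnik_bma(c("A2", "A2", "B1"), "A2", ont, ic),
               (2 * -log(1 / 3) + 0) / 3)
})

test_that("cosine and jaccard match the worked toy examples", {
  ont <- toy$ontology
  q1 <- propagate("A1", ont); q2 <- propagate("A2", ont)
  b1 <- propagate("B1", ont)
  expect_equal(cosine_sim(q1, q2), 2 / 3)
  expect_equal(cosine_sim(q1, q1), 1)
  expect_equal(cosine_sim(q2, b1), 1 / 3)
  expect_equal(jaccard_sim(q1, q2), 0.5)
  expect_equal(jaccard_sim(q1, q1), 1)
  expect_equal(jaccard_sim(q2, b1), 0.2)
  empty <- propagate(character(0), ont)
  expect_equal(cosine_sim(empty, q1), 0)
  expect_equal(jaccard_sim(q1, empty), 0)
  expect_warning(z <- jaccard_sim(empty, empty), "undefined")
  expect_equal(z, 0)
})

test_that("studywise_sim averages best-matching studies", {
  ont <- toy$ontology; ic <- toy$ic
  expect_equal(studywise_sim(list("A1", "A2"), list(c("A1", "B1")),
                             "jaccard", ont), 7 / 15)
  expect_equal(studywise_sim(list(c("A1", "A2")), list(c("A1", "A2")),
                             "cosine", ont), 1)
  expect_equal(studywise_sim(list(c("A1", "A2")),
                             list(c("A1", "B1"), "B"),
                             "resnik", ont, ic), -log(2 / 3))
  expect_equal(studywise_sim(list("A1"), list(), "jaccard", ont), 0)
  expect_error(studywise_sim(list(), list("A1"), "jaccard", ont), "empty")
})

test_that("similarity ranges and symmetry properties hold on random profiles", {
  dag <- random_dag(n = 30, seed = 11)
  sets <- random_item_sets(dag$ids, n_items = 10, max_classes = 8, seed = 11)
  corpus <- item_sets_to_corpus(sets, dag$ont)
  ic <- compute_ic(dag$ont, corpus)
  max_ic <- max(ic$ic[is.finite(ic$ic)])
  set.seed(11)
  for (k in 1:40) {
    Q <- sample(dag$ids, sample(8, 1))
    I <- sample(dag$ids, sample(8, 1))
    r <- resnik_bma(Q, I, dag$ont, ic)
    expect_gte(r, 0); expect_lte(r, max_ic + 1e-12)
    pq <- propagate(Q, dag$ont); pi_ <- propagate(I, dag$ont)
    cs <- cosine_sim(pq, pi_); js <- jaccard_sim(pq, pi_)
    expect_gte(cs, 0); expect_lte(cs, 1 + 1e-12)
    expect_gte(js, 0); expect_lte(js, 1 + 1e-12)
    expect_equal(cs, cosine_sim(pi_, pq))
    expect_equal(js, jaccard_sim(pi_, pq))
  }
})

test_that("resnik_bma and studywise_sim are asymmetric by counterexample", {
  ont <- toy$ontology; ic <- toy$ic
  expect_false(isTRUE(all.equal(
    resnik_bma(c("A1", "B1"), "A1", ont, ic),
    resnik_bma("A1", c("A1", "B1"), ont, ic))))
  Qs <- list("A1", "B1"); Is <- list("A1")
  expect_false(isTRUE(all.equal(
    studywise_sim(Qs, Is, "jaccard", ont),
    studywise_sim(Is, Qs, "jaccard", ont))))
})

test_that("studywise_sim over one merged study equals the base measure", {
  dag <- random_dag(n = 25, seed = 21)
  sets <- random_item_sets(dag$ids, n_items = 6, max_classes = 6, seed = 21)
  ic <- compute_ic(dag$ont, item_sets_to_corpus(sets, dag$ont))
  set.seed(21)
  for (k in 1:10) {
    Q <- unique(sample(dag$ids, sample(6, 1)))
    I <- unique(sample(dag$ids, sample(6, 1)))
    for (mm in c("resnik", "cosine", "jaccard")) {
      base <- switch(mm,
        resnik = resnik_bma(Q, I, dag$ont, ic),
        cosine = cosine_sim(propagate(Q, dag$ont), propagate(I, dag$ont)),
        jaccard = jaccard_sim(propagate(Q, dag$ont), propagate(I, dag$ont)))
      expect_equal(studywise_sim(list(Q), list(I), mm, dag$ont, ic), base)
    }
  }
})

test_that("score dispatches models correctly", {
  ont <- toy$ontology; ic <- toy$ic
  expect_equal(score("I1", "I1", toy$corpus, "merged", "jaccard", ont, ic), 1)
  # weighted differs from merged when a class occurs in two studies
  mj <- score("D1", "I1", toy$corpus, "merged", "jaccard", ont, ic)
  wj <- score("D1", "I1", toy$corpus, "weighted", "jaccard", ont, ic)
  expect_false(isTRUE(all.equal(mj, wj)))
  # studywise on single-study items reduces to merged
  for (mm in c("resnik", "cosine", "jaccard")) {
    expect_equal(
      score("I1", "I2", toy$corpus, "studywise", mm, ont, ic),
      score("I1", "I2", toy$corpus, "merged", mm, ont, ic))
  }
  expect_error(score("D1", "I1", toy$corpus, "merged", "euclid", ont, ic),
               "unknown measure")
})

test_that("score_matrix agrees with the per-pair reference path", {
  cfg <- generator_config(n_items = 12, n_groups = 3, group_size = 2,
                          n_classes = 40, studies_per_item = c(2, 4),
                          seed = 31)
  ont <- generate_ontology(cfg)
  corpus <- generate_corpus(ont, cfg)$corpus
  ic <- compute_ic(ont, corpus)
  items <- names(corpus$items)
  for (model in c("merged", "weighted", "studywise")) {
    for (measure in c("resnik", "cosine", "jaccard")) {
      S <- score_matrix(corpus, model, measure, ont, ic,
                        queries = items[1:4])
      for (q in items[1:4]) {
        for (it in items[c(1, 5, 9)]) {
          expect_equal(S[q, it],
                       score(q, it, corpus, model, measure, ont, ic),
                       tolerance = 1e-12,
                       label = paste(model, measure, q, it))
        }
      }
    }
  }
})
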