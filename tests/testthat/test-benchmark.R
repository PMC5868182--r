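test_that("rank_candidates orders by score with mean-rank ties", {
  # four items with known pairwise structure via a hand-built corpus
  items <- list(Q = list(s1 = c("A1", "A2"), s2 = "B1", s3 = "A1", s4 = "B"),
                X = list(s1 = c("A1", "A2"), s2 = "B1", s3 = "A1", s4 = "B"),
                Y = list(s1 = "B1", s2 = "B1", s3 = "B1", s4 = "B1"),
                Z = list(s1 = "B1", s2 = "B1", s3 = "B1", s4 = "B1"),
                W = list(s1 = "A2", s2 = "A2", s3 = "A2", s4 = "A2"))
  corpus <- structure(list(items = items, dropped = 0L),
                      class = "study_corpus")
  rk <- rank_candidates("Q", corpus, "merged", "jaccard",
                        toy$ontology, toy$ic)
  expect_equal(rk$item[1], "X")
  expect_equal(rk$rank[rk$item == "X"], 1)
  # Y and Z are identical items: tied, mean rank
  expect_equal(rk$rank[rk$item == "Y"], rk$rank[rk$item == "Z"])
  expect_equal(sort(rk$rank), sort(rank(-rk$score, ties.method = "average")))
  # worst-rank policy assigns the max rank to the tied block
  rkw <- rank_candidates("Q", corpus, "merged", "jaccard",
                         toy$ontology, toy$ic, tie = "worst")
  expect_equal(rkw$rank[rkw$item == "Y"], rkw$rank[rkw$item == "Z"])
  expect_gte(rkw$rank[rkw$item == "Y"], rk$rank[rk$item == "Y"])
  expect_error(rank_candidates("NOPE", corpus, "merged", "jaccard",
                               toy$ontology, toy$ic), "not in the corpus")
})

test_that("full tie gives every candidate the mean rank", {
  items <- stats::setNames(rep(list(list(s1 = "A1", s2 = "A1", s3 = "A1",
                                         s4 = "A1", s5 = "A1")), 5),
                           paste0("it", 1:5))
  # 1 annotation only; relax filter by ranking directly
  corpus <- structure(list(items = items, dropped = 0L),
                      class = "study_corpus")
  rk <- rank_candidates("it1", corpus, "merged", "jaccard",
                        toy$ontology, toy$ic)
  expect_true(all(rk$rank == (4 + 1) / 2))
})

test_that("run_group_recovery applies filters and records cross-ranks", {
  cfg <- generator_config(n_items = 40, n_groups = 5, group_size = 3,
                          n_classes = 60, coherence = 1, noise_rate = 0,
                          seed = 17)
  ont <- generate_ontology(cfg)
  gen <- generate_corpus(ont, cfg)
  ic <- compute_ic(ont, gen$corpus)
  res <- run_group_recovery(gen$corpus, gen$groups, "studywise", "jaccard",
                            ont, ic, min_annotations = 2, min_studies = 2)
  expect_true(all(res$ranks$rank >= 1))
  expect_true(all(res$ranks$rank <= res$ranks$n_candidates))
  expect_equal(sum(res$pairs$label), nrow(res$ranks))
  # max_group_size drops oversized groups
  big <- list(G1 = names(gen$corpus$items)[1:20],
              G2 = names(gen$corpus$items)[21:23])
  res2 <- run_group_recovery(gen$corpus, big, "merged", "jaccard", ont, ic,
                             min_annotations = 1, min_studies = 1,
                             max_group_size = 15)
  expect_equal(res2$n_groups, 1L)
  # groups reduced below 2 members are dropped; none left -> error
  tiny <- list(G = c("nonexistent-a", "nonexistent-b"))
  expect_error(run_group_recovery(gen$corpus, tiny, "merged", "jaccard",
                                  ont, ic), "no group")
})

test_that("an oracle measure yields all ranks 1 and auprc 1", {
  # two groups whose members are annotated with identical, disjoint classes
  items <- list(a1 = list(s1 = "A1", s2 = "A1"),
                a2 = list(s1 = "A1", s2 = "A1"),
                b1 = list(s1 = "B1", s2 = "B1"),
                b2 = list(s1 = "B1", s2 = "B1"))
  corpus <- structure(list(items = items, dropped = 0L),
                      class = "study_corpus")
  groups <- list(GA = c("a1", "a2"), GB = c("b1", "b2"))
  res <- run_group_recovery(corpus, groups, "merged", "jaccard",
                            toy$ontology, toy$ic,
                            min_annotations = 1, min_studies = 1)
  expect_true(all(res$ranks$rank == 1))
  expect_equal(precision_recall(res$pairs$score, res$pairs$label)$auprc, 1)
})

test_that("precision_recall matches the hand-computed trapezoid", {
  pr <- precision_recall(c(0.9, 0.8, 0.7), c(1, 0, 1))
  expect_equal(pr$points$recall, c(0.5, 0.5, 1))
  expect_equal(pr$points$precision, c(1, 0.5, 2 / 3))
  expect_equal(pr$auprc, 0.5 + 0 + 0.5 * (0.5 + 2 / 3) / 2)
  expect_equal(pr$auprc, 0.7916667, tolerance = 1e-6)
  # all positives above all negatives
  expect_equal(precision_recall(c(3, 2, 1), c(1, 1, 0))$auprc, 1)
  # all labels positive
  expect_equal(precision_recall(c(3, 2, 1), c(1, 1, 1))$auprc, 1)
  # recall is non-decreasing; tied scores form one threshold block
  pr2 <- precision_recall(c(1, 1, 0.5, 0.5), c(1, 0, 1, 0))
  expect_true(all(diff(pr2$points$recall) >= 0))
  expect_equal(nrow(pr2$points), 2)
  expect_error(precision_recall(c(1, 2), c(0, 0)), "positive")
})

test_that("random scores drive auprc toward the positive prevalence", {
  set.seed(123)
  reps <- replicate(20, {
    n <- 400
    labels <- rbinom(n, 1, 0.2)
    precision_recall(runif(n), labels)$auprc
  })
  expect_lt(abs(mean(reps) - 0.2), 0.05)
})

test_that("wilcoxon matches exact enumeration and wilcox.test", {
  w <- wilcoxon_signed_rank(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$p.value, 0.125)
  expect_true(w$exact)
  # wrong direction: p near 1
  expect_gt(wilcoxon_signed_rank(c(5, 6, 7, 8), c(1, 2, 3, 4))$p.value, 0.9)
  # agreement with R for untied samples, all n <= 12
  set.seed(5)
  for (n in 3:12) {
    x <- round(rnorm(n), 6); y <- round(x + rnorm(n, 0.4), 6)
    mine <- wilcoxon_signed_rank(x, y)
    ref <- stats::wilcox.test(x, y, paired = TRUE, alternative = "less",
                              exact = TRUE)
    expect_equal(mine$p.value, unname(ref$p.value), tolerance = 1e-9)
    expect_equal(mine$statistic, unname(ref$statistic))
  }
  # normal approximation branch matches wilcox.test with correction
  set.seed(6)
  for (k in 1:5) {
    x <- rnorm(60); y <- x + rnorm(60, 0.2)
    mine <- wilcoxon_signed_rank(x, y)
    ref <- stats::wilcox.test(x, y, paired = TRUE, alternative = "less",
                              exact = FALSE, correct = TRUE)
    expect_false(mine$exact)
    expect_equal(mine$p.value, unname(ref$p.value), tolerance = 1e-12)
  }
  # zeros are dropped; all-zero differences error
  expect_equal(wilcoxon_signed_rank(c(1, 1, 2, 3), c(1, 1, 3, 4))$n, 2)
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
})

test_that("summarize_corpus reports model-dependent counts and type-7 quantiles", {
  s_m <- summarize_corpus(toy$corpus, "merged")
  s_s <- summarize_corpus(toy$corpus, "studywise")
  # D1: merged 3, studywise 4, 3 studies; I1-I3 single study
  expect_equal(s_m$mean_annotations_per_item, mean(c(2, 2, 1, 3)))
  expect_equal(s_s$mean_annotations_per_item, mean(c(2, 2, 1, 4)))
  expect_equal(s_m$mean_studies_per_item, mean(c(1, 1, 1, 3)))
  expect_equal(s_s$mean_annotations_per_study, mean(c(2, 2, 1, 1, 2, 1)))
  # single-study corpus: merged and studywise sizes coincide
  one <- structure(list(items = toy$corpus$items[c("I1", "I2")],
                        dropped = 0L), class = "study_corpus")
  expect_equal(summarize_corpus(one, "merged")$mean_annotations_per_item,
               summarize_corpus(one, "studywise")$mean_annotations_per_item)
  # type-7 quantiles
  sizes <- structure(list(items = stats::setNames(lapply(1:100, function(i)
    list(s1 = paste0("C", seq_len(i)))), paste0("it", 1:100)),
    dropped = 0L), class = "study_corpus")
  s <- summarize_corpus(sizes, "merged")
  expect_equal(s$q05_annotations, unname(quantile(1:100, 0.05, type = 7)))
  expect_equal(s$q95_annotations, unname(quantile(1:100, 0.95, type = 7)))
  expect_equal(s$q05_annotations, 5.95)
  expect_equal(s$q95_annotations, 95.05)
})

test_that("groups round-trip through TSV", {
  groups <- list(G1 = c("a", "b"), G2 = c("c", "d", "e"))
  path <- tempfile(fileext = ".tsv")
  write_groups(groups, path)
  expect_equal(load_groups(path), groups)
  expect_error(load_groups({p <- tempfile(); writeLines("only_one_col", p); p}),
               "malformed")
})
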