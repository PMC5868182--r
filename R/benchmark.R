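#' @title Group-recovery benchmark
#' @description
#' Evaluates annotation model / similarity measure combinations by their
#' ability to recover known groupings (OMIM phenotypic series, KEGG pathway
#' membership): each retained member of each retained group is used as a
#' query once, all other items are ranked by similarity to it, and the
#' ranks of the sought fellow members are recorded.  Pooled (score, label)
#' pairs feed a precision-recall curve; rank distributions of two
#' configurations are compared with a one-sided paired Wilcoxon signed-rank
#' test.
#' @name benchmark
NULL

#' Load a grouping table from 2-column TSV (group_id, item_id)
#' @param path TSV file; `#` lines are comments.
#' @return named list: group id -> character vector of item ids.
#' @export
load_groups <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2)
  if (length(bad) > 0)
    stop("malformed group row at line ", bad[1], call. = FALSE)
  gid <- vapply(fields, `[[`, "", 1)
  iid <- vapply(fields, `[[`, "", 2)
  lapply(split(iid, gid), unique)
}

#' Write a grouping table as 2-column TSV
#' @param groups named list of item id vectors.
#' @param path output file.
#' @export
write_groups <- function(groups, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#group_id\titem_id", con)
  for (g in names(groups))
    writeLines(paste(g, groups[[g]], sep = "\t"), con)
  invisible(path)
}

# ---- vectorized scoring engine ---------------------------------------------
#
# The per-pair score() path is the reference implementation; this engine
# computes the same scores in dense-matrix form so that benchmarks over a
# few hundred items stay fast.  Tests assert the two routes agree.

propagate_matrix <- function(profiles, ont) {
  ids <- ont$ids
  P <- matrix(0, length(profiles), length(ids),
              dimnames = list(names(profiles), ids))
  for (r in seq_along(profiles)) {
    counts <- as_count_vector(profiles[[r]])
    for (cl in names(counts)) {
      a <- ont$ancestors[[cl]]
      P[r, a] <- pmax(P[r, a], counts[[cl]])
    }
  }
  P
}

pairwise_cosine <- function(A, B) {
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  na[na == 0] <- Inf; nb[nb == 0] <- Inf   # all-zero profiles score 0
  tcrossprod(A / na, B / nb)
}

pairwise_jaccard <- function(A, B) {
  m <- nrow(B)
  sb <- rowSums(B)
  S <- matrix(0, nrow(A), m, dimnames = list(rownames(A), rownames(B)))
  for (r in seq_len(nrow(A))) {
    a <- A[r, ]
    num <- rowSums(pmin(B, matrix(a, m, length(a), byrow = TRUE)))
    den <- sum(a) + sb - num
    s <- num / den
    s[den == 0] <- 0
    S[r, ] <- s
  }
  S
}

pairwise_resnik <- function(Q_profiles, I_profiles, M) {
  S <- matrix(0, length(Q_profiles), length(I_profiles),
              dimnames = list(names(Q_profiles), names(I_profiles)))
  qc <- lapply(Q_profiles, as_count_vector)
  ic_ <- lapply(I_profiles, as_count_vector)
  for (r in seq_along(qc)) {
    q <- qc[[r]]
    if (length(q) == 0) next
    w <- unname(q)
    for (s in seq_along(ic_)) {
      i <- ic_[[s]]
      if (length(i) == 0) next
      sub <- M[names(q), names(i), drop = FALSE]
      S[r, s] <- sum(w * apply(sub, 1, max)) / sum(w)
    }
  }
  S
}

#' Score matrix of query items against all items of a corpus
#'
#' Dense matrix equivalent of calling [score()] for every (query, item)
#' pair; used by [rank_candidates()] and [run_group_recovery()].
#'
#' @param corpus a `study_corpus` (already filtered).
#' @param queries item ids to use as rows (default: all items).
#' @param model,measure as in [score()].
#' @param ont,ic as in [score()].
#' @return numeric matrix, rows = queries, columns = all corpus items.
#' @export
score_matrix <- function(corpus, model, measure, ont, ic,
                         queries = names(corpus$items)) {
  model <- match.arg(model,
                     c("merged", "weighted", "studywise", "studywise_shuffled"))
  measure <- match.arg(measure, c("resnik", "cosine", "jaccard"))
  items <- names(corpus$items)
  stopifnot(all(queries %in% items))
  if (model %in% c("merged", "weighted")) {
    profs <- if (model == "merged") {
      lapply(corpus$items, function(st) unique(unlist(st, use.names = FALSE)))
    } else {
      stats::setNames(lapply(items, function(it) to_weighted(corpus, it)), items)
    }
    if (measure == "resnik") {
      M <- mica_ic_matrix(ont, ic)
      return(pairwise_resnik(profs[queries], profs, M))
    }
    P <- propagate_matrix(profs, ont)
    if (measure == "cosine") return(pairwise_cosine(P[queries, , drop = FALSE], P))
    return(pairwise_jaccard(P[queries, , drop = FALSE], P))
  }
  # study-wise: build one profile row per study, then aggregate per item by
  # best-matching-study average (normalized by the query's study count)
  study_item <- character(0)
  study_sets <- list()
  for (it in items) {
    for (s in corpus$items[[it]]) {
      study_item <- c(study_item, it)
      study_sets[[length(study_sets) + 1L]] <- unique(s)
    }
  }
  names(study_sets) <- sprintf("s%06d", seq_along(study_sets))
  q_rows <- which(study_item %in% queries)
  SS <- if (measure == "resnik") {
    M <- mica_ic_matrix(ont, ic)
    pairwise_resnik(study_sets[q_rows], study_sets, M)
  } else {
    P <- propagate_matrix(study_sets, ont)
    if (measure == "cosine") pairwise_cosine(P[q_rows, , drop = FALSE], P)
    else pairwise_jaccard(P[q_rows, , drop = FALSE], P)
  }
  q_owner <- study_item[q_rows]
  col_groups <- split(seq_along(study_item), study_item)
  # best-matching item study per query study, then average per query item
  best <- matrix(0, length(q_rows), length(items),
                 dimnames = list(NULL, items))
  for (it in items) {
    cols <- col_groups[[it]]
    best[, it] <- if (length(cols) == 1) SS[, cols]
                  else do.call(pmax, asplit(SS[, cols, drop = FALSE], 2))
  }
  sums <- rowsum(best, q_owner)
  S <- sums / as.vector(table(q_owner)[rownames(sums)])
  S[queries, , drop = FALSE]
}

#' Rank all candidate items against one query
#'
#' Candidates are every corpus item except the query itself, ordered by
#' descending score; tied scores receive the mean rank of their tied block
#' by default (`tie = "worst"` assigns the maximum rank instead).
#'
#' @param query item id; must be present in the (already filtered) corpus.
#' @param corpus a `study_corpus`.
#' @param model,measure,ont,ic as in [score()].
#' @param tie `"average"` (default) or `"worst"`.
#' @return data frame with columns `item`, `score`, `rank`, sorted by
#'   descending score.
#' @export
rank_candidates <- function(query, corpus, model, measure, ont, ic,
                            tie = c("average", "worst")) {
  tie <- match.arg(tie)
  if (!query %in% names(corpus$items))
    stop("query item '", query, "' is not in the corpus (removed by ",
         "filtering?)", call. = FALSE)
  S <- score_matrix(corpus, model, measure, ont, ic, queries = query)
  scores <- S[1, setdiff(colnames(S), query)]
  rk <- rank(-scores, ties.method = if (tie == "average") "average" else "max")
  out <- data.frame(item = names(scores), score = unname(scores),
                    rank = unname(rk))
  out[order(-out$score, out$item), , drop = FALSE]
}

#' Run the full group-recovery benchmark
#'
#' Applies the item filter (>= `min_annotations` merged annotations AND
#' >= `min_studies` studies), drops groups with fewer than two retained
#' members or more than `max_group_size` members, then uses every retained
#' member of every retained group as a query once.  For each query the
#' ranks of its fellow group members are recorded, and every
#' (query, candidate) score is pooled with a binary same-group label for
#' the precision-recall analysis.
#'
#' @param corpus a `study_corpus` (unfiltered; filtering happens here).
#' @param groups named list of item id vectors (see [load_groups()]).
#' @param model,measure,ont,ic as in [score()].
#' @param min_annotations,min_studies item filter thresholds (defaults 5, 4).
#' @param max_group_size drop groups larger than this after filtering
#'   (default `Inf`; pathway-style runs use 15).
#' @param tie rank tie policy, see [rank_candidates()].
#' @return list with `ranks` (data frame: group, query, sought, rank,
#'   n_candidates), `pairs` (data frame: score, label), `n_groups`,
#'   `n_items`.
#' @export
run_group_recovery <- function(corpus, groups, model, measure, ont, ic,
                               min_annotations = 5, min_studies = 4,
                               max_group_size = Inf,
                               tie = c("average", "worst")) {
  tie <- match.arg(tie)
  fc <- filter_items(corpus, min_annotations, min_studies)
  items <- names(fc$items)
  groups <- lapply(groups, intersect, items)
  groups <- groups[vapply(groups, length, 1L) >= 2 &
                   vapply(groups, length, 1L) <= max_group_size]
  if (length(groups) == 0)
    stop("no group retains >= 2 members after filtering", call. = FALSE)
  queries <- sort(unique(unlist(groups, use.names = FALSE)))
  S <- score_matrix(fc, model, measure, ont, ic, queries = queries)
  ranks <- list(); pairs_score <- list(); pairs_label <- list()
  for (g in names(groups)) {
    members <- groups[[g]]
    for (q in members) {
      cand <- setdiff(items, q)
      scores <- S[q, cand]
      rk <- rank(-scores,
                 ties.method = if (tie == "average") "average" else "max")
      sought <- setdiff(members, q)
      ranks[[length(ranks) + 1L]] <- data.frame(
        group = g, query = q, sought = sought,
        rank = unname(rk[sought]), n_candidates = length(cand))
      pairs_score[[length(pairs_score) + 1L]] <- unname(scores)
      pairs_label[[length(pairs_label) + 1L]] <-
        as.integer(cand %in% members)
    }
  }
  list(ranks = do.call(rbind, ranks),
       pairs = data.frame(score = unlist(pairs_score),
                          label = unlist(pairs_label)),
       n_groups = length(groups), n_items = length(items))
}

#' Precision-recall curve and AU-PRC from pooled (score, label) pairs
#'
#' Pairs are sorted by descending score; one PR point is emitted after each
#' distinct score threshold.  The area is the trapezoidal integral over the
#' stored points with a leading point at recall 0 carrying the precision of
#' the first threshold block.
#'
#' @param scores numeric vector.
#' @param labels binary vector (1 = positive), same length.
#' @return a `pr_curve`: list with `points` (data frame: threshold, recall,
#'   precision) and `auprc`.
#' @export
precision_recall <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  P <- sum(labels == 1)
  if (P == 0) stop("precision-recall undefined without positive labels",
                   call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  cum_tp <- cumsum(l)
  cum_n <- seq_along(l)
  last <- which(diff(c(s, -Inf)) != 0)   # last index of each threshold block
  recall <- cum_tp[last] / P
  precision <- cum_tp[last] / cum_n[last]
  pts <- data.frame(threshold = s[last], recall = recall,
                    precision = precision)
  r <- c(0, recall); p <- c(precision[1], precision)
  auprc <- sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
  structure(list(points = pts, auprc = auprc), class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat("<pr_curve> ", nrow(x$points), " points, AU-PRC = ",
      format(x$auprc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' One-sided paired Wilcoxon signed-rank test
#'
#' Tests whether the paired differences `x - y` are stochastically negative
#' (alternative "less": `x` tends to be smaller — lower ranks are better).
#' Zero differences are dropped.  With `n <= 25` remaining pairs and no
#' ties among the absolute differences the p-value comes from the exact
#' signed-rank distribution (dynamic-programming enumeration); otherwise
#' from the normal approximation with continuity correction and tie
#' correction, matching R's `wilcox.test(..., paired = TRUE,
#' alternative = "less", correct = TRUE)`.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param alternative `"less"` (default), `"greater"` or `"two.sided"`.
#' @return list with `statistic` (W+, rank sum of positive differences),
#'   `p.value`, `n` (pairs after dropping zeros), `exact` (logical).
#' @export
wilcoxon_signed_rank <- function(x, y, alternative = c("less", "greater",
                                                       "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y), length(x) >= 1)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    stop("all paired differences are zero; test carries no information",
         call. = FALSE)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) {
    # exact enumeration of all 2^n sign assignments; average ranks for tied
    # |d| give half-integer support, so work on doubled ranks
    counts <- exact_signrank_counts(round(2 * r))
    W2 <- round(2 * W)
    tot <- 2^n
    p_le <- sum(counts[seq_len(W2 + 1)]) / tot
    p_ge <- sum(counts[seq(W2 + 1, length(counts))]) / tot
    p <- switch(alternative,
      less = p_le,
      greater = p_ge,
      two.sided = min(1, 2 * min(p_le, p_ge)))
    return(list(statistic = W, p.value = p, n = n, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                sum(tie_tab^3 - tie_tab) / 48)
  z <- W - mu
  p <- switch(alternative,
    less = stats::pnorm((z + 0.5) / sigma),
    greater = stats::pnorm((z - 0.5) / sigma, lower.tail = FALSE),
    two.sided = {
      zc <- (z - sign(z) * 0.5) / sigma
      min(1, 2 * min(stats::pnorm(zc), stats::pnorm(zc, lower.tail = FALSE)))
    })
  list(statistic = W, p.value = p, n = n, exact = FALSE)
}

# Null distribution of W+ = sum of ranks of positive differences over all
# 2^n sign assignments, by polynomial convolution.  `ranks2` are integer
# (doubled) ranks; counts[w + 1] = number of assignments with 2*W+ == w.
exact_signrank_counts <- function(ranks2) {
  counts <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), counts)
    counts <- c(counts, rep(0, r)) + shifted
  }
  counts
}

#' Summary statistics of a corpus under one annotation model
#'
#' Reports the mean annotation count per item (unique classes under
#' `"merged"`, total study mentions under `"studywise"`), the mean number
#' of studies per item, the mean annotations per study, and the 5% / 95%
#' quantiles (R default type 7) of the per-item annotation-set size.
#'
#' @param corpus a `study_corpus`.
#' @param model `"merged"` or `"studywise"`.
#' @return one-row data frame.
#' @export
summarize_corpus <- function(corpus, model = c("merged", "studywise")) {
  model <- match.arg(model)
  if (length(corpus$items) == 0) stop("empty corpus", call. = FALSE)
  sizes <- vapply(corpus$items, function(st) {
    if (model == "merged") length(unique(unlist(st, use.names = FALSE)))
    else sum(lengths(st))
  }, numeric(1))
  n_studies <- vapply(corpus$items, length, numeric(1))
  per_study <- unlist(lapply(corpus$items, lengths), use.names = FALSE)
  q <- stats::quantile(sizes, c(0.05, 0.95), type = 7, names = FALSE)
  data.frame(model = model,
             n_items = length(sizes),
             mean_annotations_per_item = mean(sizes),
             mean_studies_per_item = mean(n_studies),
             mean_annotations_per_study = mean(per_study),
             q05_annotations = q[1],
             q95_annotations = q[2])
}
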