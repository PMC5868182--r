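#' @title Semantic similarity measures
#' @description
#' Three base measures compare two annotation profiles \eqn{Q} (query) and
#' \eqn{I} (item):
#' \itemize{
#'   \item Resnik best-match-average (BMA):
#'     \eqn{\frac{1}{|Q|}\sum_{c_1 \in Q} \max_{c_2 \in I} IC(MICA(c_1,c_2))},
#'     where \eqn{|Q|} counts multiplicity in the weighted case.
#'   \item Cosine: angle between ancestor-propagated count vectors
#'     \eqn{q \cdot i / (\|q\|\,\|i\|)}.
#'   \item Jaccard: \eqn{\sum_j \min(q_j,i_j) / \sum_j \max(q_j,i_j)}.
#' }
#' A study-wise meta-measure lifts any base measure to lists of per-study
#' class sets: each query study is matched to its best-scoring item study
#' and the matches are averaged over the query's studies.
#' @name similarity
NULL

#' Ancestor-propagate a (multi)set of classes into a profile vector
#'
#' Every class in the closure receives an aggregate over the multiplicities
#' of the annotated classes in its descendant-or-self set: the maximum under
#' the default rule (so in the unweighted case every entry is 1, and a
#' directly annotated class keeps its own multiplicity unless an annotated
#' descendant exceeds it), or the sum under `rule = "sum"`.  See the methods
#' vignette for why `max` is the default.
#'
#' @param classes character vector of class ids (repeats encode
#'   multiplicity) or a named numeric vector of counts.
#' @param ont an `ontology`.
#' @param rule `"max"` (default) or `"sum"`.
#' @return named numeric vector: class id -> propagated count (empty input
#'   gives an empty vector).
#' @export
propagate <- function(classes, ont, rule = c("max", "sum")) {
  rule <- match.arg(rule)
  counts <- as_count_vector(classes)
  if (length(counts) == 0) return(stats::setNames(numeric(0), character(0)))
  unknown <- setdiff(names(counts), ont$ids)
  if (length(unknown) > 0)
    stop("unknown class id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- new.env(parent = emptyenv())
  for (cl in names(counts)) {
    val <- counts[[cl]]
    for (a in ont$ancestors[[cl]]) {
      prev <- out[[a]]
      out[[a]] <- if (is.null(prev)) {
        val
      } else if (rule == "max") max(prev, val) else prev + val
    }
  }
  nm <- sort(ls(out))
  stats::setNames(vapply(nm, function(k) out[[k]], numeric(1)), nm)
}

as_count_vector <- function(classes) {
  if (is.numeric(classes)) {
    stopifnot(!is.null(names(classes)), all(classes > 0))
    return(classes)
  }
  if (length(classes) == 0) return(stats::setNames(numeric(0), character(0)))
  tab <- table(classes)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Resnik best-match-average similarity
#'
#' Query-directed (one-sided): normalizes by the query size only, exactly as
#' the measure is defined — no symmetrized variant.  `Q` and `I` may carry
#' multiplicities (weighted model): a class present in k studies contributes
#' k terms to the sum and k to \eqn{|Q|}.
#'
#' @param Q,I class id vectors (repeats = multiplicity) or named count
#'   vectors.
#' @param ont an `ontology`.
#' @param ic an `ic_table`.
#' @return non-negative real; 0 if `I` is empty.  Empty `Q` is an error
#'   (undefined normalization).
#' @export
resnik_bma <- function(Q, I, ont, ic) {
  q <- as_count_vector(Q); i <- as_count_vector(I)
  if (length(q) == 0)
    stop("Resnik BMA is undefined for an empty query profile", call. = FALSE)
  if (length(i) == 0) return(0)
  total <- 0
  for (c1 in names(q)) {
    best <- max(vapply(names(i), function(c2) mica(ont, ic, c1, c2)$ic,
                       numeric(1)))
    total <- total + q[[c1]] * best
  }
  total / sum(q)
}

#' Cosine similarity of two propagated profile vectors
#' @param q,i named numeric vectors from [propagate()].
#' @return value in `[0, 1]`; 0 if either vector is empty or all-zero.
#' @export
cosine_sim <- function(q, i) {
  if (length(q) == 0 || length(i) == 0) return(0)
  shared <- intersect(names(q), names(i))
  dot <- sum(q[shared] * i[shared])
  den <- sqrt(sum(q^2)) * sqrt(sum(i^2))
  if (den == 0) return(0)
  dot / den
}

#' Jaccard similarity of two propagated profile vectors
#'
#' \eqn{\sum_j \min(q_j, i_j) / \sum_j \max(q_j, i_j)} over the union of
#' supports.  Two empty vectors give 0 with a warning (the measure is
#' undefined; filtered corpora never produce this case).
#' @inheritParams cosine_sim
#' @return value in `[0, 1]`.
#' @export
jaccard_sim <- function(q, i) {
  if (length(q) == 0 && length(i) == 0) {
    warning("Jaccard of two empty profiles is undefined; returning 0",
            call. = FALSE)
    return(0)
  }
  if (length(q) == 0 || length(i) == 0) return(0)
  u <- union(names(q), names(i))
  qv <- stats::setNames(numeric(length(u)), u); qv[names(q)] <- q
  iv <- stats::setNames(numeric(length(u)), u); iv[names(i)] <- i
  sum(pmin(qv, iv)) / sum(pmax(qv, iv))
}

base_measure_fun <- function(measure, ont, ic, weighted = FALSE) {
  switch(measure,
    resnik = function(Q, I) resnik_bma(Q, I, ont, ic),
    cosine = function(Q, I) cosine_sim(propagate(Q, ont), propagate(I, ont)),
    jaccard = function(Q, I) jaccard_sim(propagate(Q, ont), propagate(I, ont)),
    stop("unknown measure '", measure, "' (use resnik, cosine or jaccard)",
         call. = FALSE))
}

#' Study-wise similarity (best-matching-study average)
#'
#' For each study in the query, finds the most similar study of the item
#' under the chosen base measure and averages those best matches over the
#' query's studies:
#' \eqn{\frac{1}{|Q_s|}\sum_{s_q \in Q_s}\max_{s_i \in I_s} Sim(s_q, s_i)}.
#' Study class lists are treated as unweighted sets by the base measure.
#' Normalization is by the query's study count only, so the measure need
#' not be symmetric.
#'
#' @param Qs,Is lists of character vectors (one per study).
#' @param measure `"resnik"`, `"cosine"` or `"jaccard"`.
#' @param ont an `ontology`.
#' @param ic an `ic_table` (needed for `"resnik"`).
#' @return non-negative real; 0 if `Is` is empty; error if `Qs` is empty.
#' @export
studywise_sim <- function(Qs, Is, measure, ont, ic = NULL) {
  if (length(Qs) == 0)
    stop("study-wise similarity is undefined for an empty query study list",
         call. = FALSE)
  if (length(Is) == 0) return(0)
  f <- base_measure_fun(measure, ont, ic)
  per_study <- vapply(Qs, function(sq) {
    sq <- unique(sq)
    max(vapply(Is, function(si) f(sq, unique(si)), numeric(1)))
  }, numeric(1))
  mean(per_study)
}

#' Score one item against a query under a model / measure combination
#'
#' Dispatcher binding the annotation models to the similarity measures:
#' `merged` applies the unweighted measure to flat profiles, `weighted`
#' applies the weighted measure (study-occurrence counts), `studywise` and
#' `studywise_shuffled` apply the study-wise meta-measure with an unweighted
#' base.  For `studywise_shuffled` pass a corpus that has already been run
#' through [shuffle_studywise()].
#'
#' @param query_item,target_item item ids in `corpus`.
#' @param corpus a `study_corpus`.
#' @param model `"merged"`, `"weighted"`, `"studywise"` or
#'   `"studywise_shuffled"`.
#' @param measure `"resnik"`, `"cosine"` or `"jaccard"`.
#' @param ont an `ontology`.
#' @param ic an `ic_table`.
#' @return similarity score (real).
#' @export
score <- function(query_item, target_item, corpus, model, measure, ont, ic) {
  model <- match.arg(model,
                     c("merged", "weighted", "studywise", "studywise_shuffled"))
  f <- base_measure_fun(measure, ont, ic)
  if (model == "merged") {
    f(to_merged(corpus, query_item), to_merged(corpus, target_item))
  } else if (model == "weighted") {
    f(to_weighted(corpus, query_item), to_weighted(corpus, target_item))
  } else {
    studywise_sim(corpus_item(corpus, query_item),
                  corpus_item(corpus, target_item), measure, ont, ic)
  }
}
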