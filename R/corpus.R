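#' @title Study-structured annotation corpora
#' @description
#' A `study_corpus` stores, per item (disease or gene), an ordered list of
#' studies, each an ordered vector of ontology class ids.  For HPO-style
#' data a "study" is a paragraph of the full-text disease description; for
#' GO-style data it is a PubMed reference.  The same class may appear in
#' several studies of one item; within one study a class appears at most
#' once (duplicate mentions collapse).  From this single representation the
#' four annotation models are derived: merged (flat unique set), weighted
#' (class counted once per study mentioning it), study-wise (the structure
#' itself) and study-wise shuffled (a null model that randomly exchanges
#' annotations between an item's studies).
#' @name study_corpus
NULL

new_study_corpus <- function(items, dropped = 0L) {
  structure(list(items = items, dropped = dropped), class = "study_corpus")
}

#' @export
print.study_corpus <- function(x, ...) {
  ns <- vapply(x$items, length, integer(1))
  cat("<study_corpus> ", length(x$items), " items, ",
      sum(ns), " studies", sep = "")
  if (x$dropped > 0) cat(" (", x$dropped, " rows dropped at load)", sep = "")
  cat("\n")
  invisible(x)
}

#' Load an annotation corpus from 3-column TSV
#'
#' Expected columns: `item_id`, `study_id`, `class_id`, one mention per row;
#' lines starting with `#` are comments.  Rows whose class id falls outside
#' the ontology root's subgraph are dropped (their count is recorded in the
#' corpus and reported via a warning); duplicate mentions of a class within
#' one (item, study) pair collapse to one.
#'
#' @param path TSV file path.
#' @param ont an `ontology`; mentions are filtered against it.
#' @return a `study_corpus`.
#' @export
load_corpus <- function(path, ont) {
  stopifnot(inherits(ont, "ontology"))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) return(new_study_corpus(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0)
    stop("malformed corpus row at line ", bad[1], ": expected 3 tab-separated",
         " columns (item_id, study_id, class_id)", call. = FALSE)
  df <- data.frame(item = vapply(fields, `[[`, "", 1),
                   study = vapply(fields, `[[`, "", 2),
                   class = vapply(fields, `[[`, "", 3))
  corpus_from_mentions(df, ont)
}

# Shared constructor from a (item, study, class) data frame.
corpus_from_mentions <- function(df, ont) {
  inside <- df$class %in% ont$ids
  dropped <- sum(!inside)
  if (dropped > 0)
    warning(dropped, " mention(s) with class ids outside the ontology dropped",
            call. = FALSE)
  df <- df[inside, , drop = FALSE]
  items <- list()
  for (it in unique(df$item)) {
    sub <- df[df$item == it, , drop = FALSE]
    studies <- list()
    for (s in unique(sub$study)) {
      studies[[s]] <- unique(sub$class[sub$study == s])
    }
    items[[it]] <- studies
  }
  new_study_corpus(items, dropped = as.integer(dropped))
}

#' Write a corpus back to 3-column TSV
#' @param corpus a `study_corpus`.
#' @param path output file.
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#item_id\tstudy_id\tclass_id", con)
  for (it in names(corpus$items)) {
    studies <- corpus$items[[it]]
    for (s in names(studies)) {
      writeLines(paste(it, s, studies[[s]], sep = "\t"), con)
    }
  }
  invisible(path)
}

corpus_item <- function(corpus, item) {
  x <- corpus$items[[item]]
  if (is.null(x)) stop("unknown item '", item, "'", call. = FALSE)
  x
}

#' Merged annotation profile of an item (flat unique class set)
#' @param corpus a `study_corpus`.
#' @param item item id.
#' @return character vector of class ids (sorted).
#' @export
to_merged <- function(corpus, item) {
  sort(unique(unlist(corpus_item(corpus, item), use.names = FALSE)))
}

#' Weighted annotation profile: class counted once per study mentioning it
#' @inheritParams to_merged
#' @return named integer vector, count per class id.
#' @export
to_weighted <- function(corpus, item) {
  studies <- corpus_item(corpus, item)
  tab <- table(unlist(lapply(studies, unique), use.names = FALSE))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(names(counts))]
}

#' Shuffled null model: exchange annotations between an item's studies
#'
#' For each item, performs `n_swaps` iterations; each iteration draws two
#' studies uniformly with replacement and one random class position within
#' each, then exchanges the two classes.  The number of studies per item,
#' the length of each study's class list and the item-level multiset of
#' class mentions are all preserved.  Drawing the same study twice is a
#' counted no-op; a swap may place a class into a study already containing
#' it (the list keeps both slots; measures reading a study as a set collapse
#' them).  Items with fewer than two studies are left unchanged.  Items are
#' processed in sorted id order under a single seeded generator, so results
#' are reproducible.
#'
#' @param corpus a `study_corpus`.
#' @param n_swaps swap iterations per item (default 1000).
#' @param seed integer seed.
#' @return a new `study_corpus`.
#' @export
shuffle_studywise <- function(corpus, n_swaps = 1000, seed) {
  stopifnot(inherits(corpus, "study_corpus"), is.numeric(seed))
  out <- corpus$items
  with_seed(seed, {
    for (it in sort(names(out))) {
      studies <- out[[it]]
      k <- length(studies)
      if (k < 2) next
      lens <- lengths(studies)
      for (sw in seq_len(n_swaps)) {
        ab <- sample.int(k, 2, replace = TRUE)
        if (ab[1] == ab[2]) next
        i <- sample.int(lens[ab[1]], 1)
        j <- sample.int(lens[ab[2]], 1)
        tmp <- studies[[ab[1]]][i]
        studies[[ab[1]]][i] <- studies[[ab[2]]][j]
        studies[[ab[2]]][j] <- tmp
      }
      out[[it]] <- studies
    }
  })
  new_study_corpus(out, dropped = corpus$dropped)
}

#' Filter items by annotation and study counts
#'
#' The default (`policy = "and_keep"`) keeps an item only if it has at least
#' `min_annotations` distinct merged classes AND at least `min_studies`
#' studies.  `policy = "literal"` implements the alternative reading of the
#' removal rule "removed items with <a annotations and <s studies": an item
#' is removed only when BOTH counts fall below their thresholds.
#'
#' @param corpus a `study_corpus`.
#' @param min_annotations minimum merged annotation count (default 5).
#' @param min_studies minimum number of studies (default 4).
#' @param policy `"and_keep"` (default) or `"literal"`.
#' @return filtered `study_corpus`.
#' @export
filter_items <- function(corpus, min_annotations = 5, min_studies = 4,
                         policy = c("and_keep", "literal")) {
  policy <- match.arg(policy)
  keep <- vapply(corpus$items, function(studies) {
    n_ann <- length(unique(unlist(studies, use.names = FALSE)))
    n_stu <- length(studies)
    if (policy == "and_keep") {
      n_ann >= min_annotations && n_stu >= min_studies
    } else {
      !(n_ann < min_annotations && n_stu < min_studies)
    }
  }, logical(1))
  new_study_corpus(corpus$items[keep], dropped = corpus$dropped)
}

#' Export all four annotation models of an item as a list (JSON-ready)
#' @inheritParams to_merged
#' @param seed seed for the shuffled view of this item.
#' @return list with elements `merged`, `weighted`, `studywise`,
#'   `studywise_shuffled`.
#' @export
export_models <- function(corpus, item, seed = 1) {
  one <- new_study_corpus(corpus$items[item])
  sh <- shuffle_studywise(one, seed = seed)
  list(merged = to_merged(corpus, item),
       weighted = as.list(to_weighted(corpus, item)),
       studywise = corpus_item(corpus, item),
       studywise_shuffled = sh$items[[item]])
}

# Run code with a temporary RNG state seeded deterministically.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(code))
}
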