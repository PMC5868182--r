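# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals: ancestor
# closure by repeated edge relaxation, IC by explicit item counting, MICA
# by exhaustive enumeration of the ancestor-set intersection.

# edges: data.frame(child, parent).  Returns ancestors-or-self of `cl`.
oracle_ancestors <- function(edges, ids, cl) {
  anc <- cl
  repeat {
    nxt <- unique(c(anc, edges$parent[edges$child %in% anc]))
    nxt <- nxt[nxt %in% ids]
    if (length(nxt) == length(anc)) return(sort(anc))
    anc <- nxt
  }
}

# item_sets: named list item -> character vector of direct classes.
oracle_ic <- function(edges, ids, item_sets, base = exp(1)) {
  n <- length(item_sets)
  sapply(ids, function(cl) {
    hits <- sum(vapply(item_sets, function(cls) {
      closure <- unique(unlist(lapply(cls, oracle_ancestors,
                                      edges = edges, ids = ids)))
      cl %in% closure
    }, logical(1)))
    -log(hits / n, base = base)
  })
}

oracle_mica <- function(edges, ids, icv, c1, c2) {
  common <- intersect(oracle_ancestors(edges, ids, c1),
                      oracle_ancestors(edges, ids, c2))
  vals <- icv[common]
  vals[!is.finite(vals)] <- -Inf
  best <- max(vals)
  cand <- common[vals == best]
  if (length(cand) > 1) {
    # same tie-break as the implementation: most specific tied class first,
    # then smallest id — recomputed here from the oracle closure
    proper_anc <- vapply(cand, function(cc)
      any(vapply(setdiff(cand, cc), function(dd)
        cc %in% oracle_ancestors(edges, ids, dd), logical(1))), logical(1))
    if (!all(proper_anc)) cand <- cand[!proper_anc]
  }
  list(class = sort(cand)[1], ic = unname(best))
}

oracle_resnik_bma <- function(Q, I, edges, ids, icv) {
  best <- vapply(Q, function(c1)
    max(vapply(I, function(c2)
      oracle_mica(edges, ids, icv, c1, c2)$ic, numeric(1))), numeric(1))
  mean(best)
}

# Random rooted DAG as an edge list plus a parsed ontology object, built by
# writing OBO text and loading it through the public parser.
random_dag <- function(n = 20, seed = 1, multi_p = 0.3) {
  set.seed(seed)
  ids <- sprintf("T%02d", seq_len(n))
  edges <- data.frame(child = character(0), parent = character(0))
  for (i in 2:n) {
    p <- sample(i - 1, 1)
    edges <- rbind(edges, data.frame(child = ids[i], parent = ids[p]))
    if (stats::runif(1) < multi_p && i > 2) {
      p2 <- sample(setdiff(seq_len(i - 1), p), 1)
      edges <- rbind(edges, data.frame(child = ids[i], parent = ids[p2]))
    }
  }
  obo <- tempfile(fileext = ".obo")
  lines <- "format-version: 1.2"
  for (id in ids) {
    lines <- c(lines, "", "[Term]", paste0("id: ", id),
               paste0("name: class ", id),
               paste0("is_a: ", edges$parent[edges$child == id]))
  }
  writeLines(lines, obo)
  list(ids = ids, edges = edges, ont = parse_obo(obo, root = ids[1]))
}

# Random item annotation sets over a DAG's classes.
random_item_sets <- function(ids, n_items = 6, max_classes = 4, seed = 1) {
  set.seed(seed + 7)
  sets <- lapply(seq_len(n_items), function(i)
    sample(ids, sample(max_classes, 1)))
  names(sets) <- sprintf("I%02d", seq_len(n_items))
  sets
}

item_sets_to_corpus <- function(item_sets, ont, path = tempfile()) {
  rows <- unlist(lapply(names(item_sets), function(it)
    paste(it, "s1", item_sets[[it]], sep = "\t")))
  writeLines(rows, path)
  load_corpus(path, ont)
}

# The fixed toy used throughout the docs, fetched once per test file.
toy <- make_paper_toy()
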