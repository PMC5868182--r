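#' @title Ontology objects
#' @description
#' An `ontology` is a rooted directed acyclic graph of classes connected by
#' `is_a` edges only, as used by the Human Phenotype Ontology (HPO) and the
#' Gene Ontology (GO).  Classes not reachable from the designated root (e.g.
#' the HPO sub-ontology root "Phenotypic abnormality") are dropped at load
#' time, as are obsolete terms.  The reflexive-transitive ancestor closure of
#' every class is precomputed because every downstream operation (information
#' content, MICA, profile propagation) is a query against it.
#'
#' @name ontology
NULL

new_ontology <- function(ids, names, synonyms, parents, root) {
  stopifnot(!anyDuplicated(ids), root %in% ids)
  names(names) <- ids
  names(synonyms) <- ids
  names(parents) <- ids
  ont <- structure(
    list(ids = ids, names = names, synonyms = synonyms,
         parents = parents, root = root),
    class = "ontology")
  ont$children <- invert_parent_map(parents, ids)
  ont$ancestors <- ancestor_closure(ont)
  ont
}

invert_parent_map <- function(parents, ids) {
  ch <- rep(list(character(0)), length(ids))
  names(ch) <- ids
  for (id in ids) {
    for (p in parents[[id]]) {
      if (p %in% ids) ch[[p]] <- c(ch[[p]], id)
    }
  }
  ch
}

# Reflexive-transitive closure over is_a, computed by memoized DFS.
# Detects cycles on the way (a class on the active DFS stack seen again).
ancestor_closure <- function(ont) {
  ids <- ont$ids
  anc <- vector("list", length(ids))
  names(anc) <- ids
  state <- new.env(parent = emptyenv())   # "active" or "done"
  visit <- function(id) {
    st <- state[[id]]
    if (identical(st, "done")) return(anc[[id]])
    if (identical(st, "active"))
      stop("cycle detected in is_a graph involving class '", id, "'",
           call. = FALSE)
    state[[id]] <- "active"
    ps <- ont$parents[[id]]
    res <- id
    for (p in ps) {
      if (p %in% ids) res <- c(res, visit(p))
    }
    res <- sort(unique(res))
    anc[[id]] <<- res
    state[[id]] <- "done"
    res
  }
  for (id in ids) visit(id)
  anc
}

#' Parse an OBO flat file into an ontology restricted to one root
#'
#' Reads OBO 1.2/1.4 `[Term]` stanzas honoring the tags `id`, `name`,
#' `synonym`, `is_a` and `is_obsolete`; every other tag is ignored.  Only
#' `is_a` edges are retained (the go-basic convention; `part_of` and other
#' relations are never considered).  Obsolete terms are dropped, then the
#' graph is restricted to the root's descendants-or-self, so that e.g.
#' `root = "HP:0000118"` yields the "Phenotypic abnormality" sub-ontology.
#'
#' @param path path to an OBO flat file.
#' @param root class id to use as root of the retained sub-ontology.
#' @return an `ontology` object.
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("[Term]", "id: R", "name: root",
#'              "[Term]", "id: A", "name: a", "is_a: R ! root"), obo)
#' ont <- parse_obo(obo, root = "R")
#' ancestors(ont, "A")
#' @export
parse_obo <- function(path, root) {
  lines <- readLines(path, warn = FALSE)
  terms <- split_obo_stanzas(lines)
  ids <- character(0); nms <- character(0)
  syns <- list(); pars <- list(); obs <- logical(0)
  for (tm in terms) {
    id <- obo_tag(tm, "id")[1]
    if (is.na(id)) next
    ids <- c(ids, id)
    nm <- obo_tag(tm, "name")[1]
    nms <- c(nms, if (is.na(nm)) id else nm)
    syn_raw <- obo_tag(tm, "synonym")
    syns[[length(syns) + 1L]] <-
      regmatches(syn_raw, regexpr('(?<=^")[^"]*', syn_raw, perl = TRUE))
    isa <- obo_tag(tm, "is_a")
    pars[[length(pars) + 1L]] <- sub("\\s*!.*$", "", isa)
    ob <- obo_tag(tm, "is_obsolete")
    obs <- c(obs, length(ob) > 0 && grepl("true", ob[1], fixed = TRUE))
  }
  if (anyDuplicated(ids))
    stop("duplicate class ids in OBO file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  keep <- !obs
  ids <- ids[keep]; nms <- nms[keep]; syns <- syns[keep]; pars <- pars[keep]
  if (!root %in% ids)
    stop("root class '", root, "' not found in OBO file", call. = FALSE)
  names(pars) <- ids
  # drop edges to classes that no longer exist (obsolete parents)
  pars <- lapply(pars, function(p) p[p %in% ids])
  # restrict to descendants-or-self of root: a class is kept iff root is in
  # its ancestor closure.  Build a provisional closure first (also catches
  # cycles anywhere in the file).
  prov <- new_ontology(ids, nms, syns, pars, root)
  keep2 <- vapply(prov$ancestors, function(a) root %in% a, logical(1))
  ids2 <- ids[keep2]
  pars2 <- lapply(pars[keep2], function(p) p[p %in% ids2])
  pars2[[root]] <- character(0)   # root has no parents inside the subgraph
  new_ontology(ids2, nms[keep2], syns[keep2], pars2, root)
}

split_obo_stanzas <- function(lines) {
  lines <- sub("^\\s+|\\s+$", "", lines)
  hdr <- grepl("^\\[.*\\]$", lines)
  grp <- cumsum(hdr)
  is_term <- lines == "[Term]"
  term_groups <- grp[is_term]
  out <- list()
  for (g in term_groups) out[[length(out) + 1L]] <- lines[grp == g & !hdr]
  out
}

obo_tag <- function(stanza_lines, tag) {
  pat <- paste0("^", tag, ":\\s*")
  hit <- grepl(pat, stanza_lines)
  if (!any(hit)) return(if (tag %in% c("id", "name")) NA_character_ else character(0))
  sub(pat, "", stanza_lines[hit])
}

#' @export
print.ontology <- function(x, ...) {
  cat("<ontology> ", length(x$ids), " classes, root ", x$root, "\n", sep = "")
  invisible(x)
}

#' Ancestors of a class (reflexive-transitive is_a closure)
#'
#' Includes the class itself and the root; deterministic (sorted).
#'
#' @param ont an `ontology`.
#' @param class_id a class id present in `ont`.
#' @return character vector of class ids.
#' @export
ancestors <- function(ont, class_id) {
  stopifnot(inherits(ont, "ontology"))
  a <- ont$ancestors[[class_id]]
  if (is.null(a)) stop("unknown class id '", class_id, "'", call. = FALSE)
  a
}

#' Information content from item-level annotation frequencies
#'
#' For each class \eqn{c}, \eqn{IC(c) = -\log(p_c)} where \eqn{p_c} is the
#' fraction of annotated items carrying \eqn{c} directly or via a descendant
#' (true-path rule: an annotation propagates to all ancestors).  The item
#' population is the merged (item-level) view of the corpus; study
#' multiplicity never affects frequencies.  Classes annotated to no item get
#' an `Inf` sentinel and are never returned as a MICA.
#'
#' @param ont an `ontology`.
#' @param corpus a `study_corpus` (see [load_corpus()]).
#' @param base logarithm base; default `exp(1)` (IC in nats).
#' @return an `ic_table`: list with `ic` (named numeric, `ic[root] == 0`
#'   whenever every item has an annotation under root), `n_items`, `base`.
#' @export
compute_ic <- function(ont, corpus, base = exp(1)) {
  stopifnot(inherits(ont, "ontology"), inherits(corpus, "study_corpus"))
  if (length(corpus$items) == 0)
    stop("cannot compute information content from an empty corpus",
         call. = FALSE)
  counts <- integer(length(ont$ids))
  names(counts) <- ont$ids
  n_items <- 0L
  for (item in corpus$items) {
    direct <- unique(unlist(item, use.names = FALSE))
    direct <- direct[direct %in% ont$ids]
    if (length(direct) == 0) next
    n_items <- n_items + 1L
    closure <- unique(unlist(ont$ancestors[direct], use.names = FALSE))
    counts[closure] <- counts[closure] + 1L
  }
  if (n_items == 0)
    stop("no item has any annotation inside the ontology", call. = FALSE)
  ic <- -log(counts / n_items, base = base)   # count 0 -> Inf sentinel
  structure(list(ic = ic, n_items = n_items, base = base),
            class = "ic_table")
}

#' @export
print.ic_table <- function(x, ...) {
  fin <- is.finite(x$ic)
  cat("<ic_table> ", sum(fin), " classes with finite IC (of ", length(x$ic),
      "), from ", x$n_items, " items\n", sep = "")
  invisible(x)
}

#' Write / read an IC table as 2-column TSV (class_id, ic)
#' @param ic an `ic_table`.
#' @param path output file.
#' @export
write_ic_table <- function(ic, path) {
  utils::write.table(
    data.frame(class_id = names(ic$ic), ic = ic$ic),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Most informative common ancestor of two classes
#'
#' Among all classes subsuming both inputs (common ancestors are reflexive:
#' a class subsumes itself) returns the one with the highest finite IC.
#' IC ties are broken deterministically: candidates that are proper
#' ancestors of another tied candidate are dropped first (the most specific
#' tied class wins, so `mica(c, c)` returns `c` itself even when an
#' ancestor has equal IC), then the lexicographically smallest id is taken.
#' The root is always a common ancestor, so a result always exists.
#'
#' @param ont an `ontology`.
#' @param ic an `ic_table` from [compute_ic()].
#' @param c1,c2 class ids.
#' @return list with `class` (the MICA id) and `ic` (its IC value).
#' @export
mica <- function(ont, ic, c1, c2) {
  common <- intersect(ancestors(ont, c1), ancestors(ont, c2))
  vals <- ic$ic[common]
  vals[!is.finite(vals)] <- -Inf        # unannotated classes can't be MICA
  best <- max(vals)
  if (!is.finite(best)) {               # nothing annotated: fall back to root
    return(list(class = ont$root, ic = 0))
  }
  cand <- common[vals == best]
  if (length(cand) > 1) {
    is_proper_anc <- vapply(cand, function(cc)
      any(vapply(setdiff(cand, cc),
                 function(dd) cc %in% ont$ancestors[[dd]], logical(1))),
      logical(1))
    if (!all(is_proper_anc)) cand <- cand[!is_proper_anc]
  }
  list(class = sort(cand)[1], ic = unname(best))
}

# Dense class x class matrix of IC(MICA(c1, c2)) used by the vectorized
# benchmark engine.  O(n^2) intersections; intended for ontologies of a few
# hundred classes (synthetic benchmarks, toy fixtures).
mica_ic_matrix <- function(ont, ic) {
  ids <- ont$ids
  n <- length(ids)
  icv <- ic$ic[ids]
  icv[!is.finite(icv)] <- -Inf
  # ancestor indicator matrix (class x class): A[i, j] = j is ancestor of i
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) A[i, ont$ancestors[[ids[i]]]] <- TRUE
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    Ai <- A[i, ]
    # common ancestors of i and every j: A[j, ] & Ai; take max IC over them
    W <- A[, Ai, drop = FALSE]
    vals <- icv[Ai]
    # row-wise max of vals over TRUE positions
    M[i, ] <- apply(W, 1, function(r) {
      m <- suppressWarnings(max(vals[r]))
      if (is.finite(m)) m else 0
    })
  }
  M
}
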