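#' @title Synthetic ontologies, corpora and groupings
#' @description
#' Generates the three artifact kinds every other module consumes — a
#' rooted is_a DAG, a study-structured annotation corpus and a grouping
#' table — so the whole pipeline is testable without external downloads.
#' The corpus generator emulates the statistical structure the study-wise
#' model assumes: a study is a topically coherent bundle of classes, and
#' items in the same group share a topic (a subtree of the ontology), so
#' group members share per-study signal that a flat merged profile dilutes
#' with the off-topic studies.
#' @name synthetic
NULL

#' Generator configuration
#'
#' @param n_classes number of ontology classes including the root.
#' @param max_children maximum children drawn per internal class.
#' @param depth maximum depth of the class tree (root = depth 0).
#' @param multi_parent_frac fraction of non-root classes receiving a second
#'   parent (exercises multi-parent MICA paths).
#' @param n_items total items; the first `n_groups * group_size` belong to
#'   groups, the rest are ungrouped background.
#' @param n_groups number of groups.
#' @param group_size items per group.
#' @param studies_per_item integer range (length-2) of studies per item.
#' @param classes_per_study integer range of classes per study.
#' @param coherence probability that a group member's study draws all its
#'   classes from the group's topic block.
#' @param noise_rate probability that a class inside a coherent study is
#'   replaced by a uniformly random ontology class.
#' @param seed integer seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_classes = 150, max_children = 4, depth = 4,
                             multi_parent_frac = 0.1,
                             n_items = 360, n_groups = 40, group_size = 4,
                             studies_per_item = c(4, 8),
                             classes_per_study = c(2, 6),
                             coherence = 0.9, noise_rate = 0.1, seed = 1) {
  cfg <- list(n_classes = n_classes, max_children = max_children,
              depth = depth, multi_parent_frac = multi_parent_frac,
              n_items = n_items, n_groups = n_groups,
              group_size = group_size,
              studies_per_item = studies_per_item,
              classes_per_study = classes_per_study,
              coherence = coherence, noise_rate = noise_rate, seed = seed)
  stopifnot(n_classes >= 2, depth >= 1, max_children >= 1,
            n_items >= n_groups * group_size,
            coherence >= 0, coherence <= 1,
            noise_rate >= 0, noise_rate <= 1,
            length(studies_per_item) == 2, length(classes_per_study) == 2)
  structure(cfg, class = "generator_config")
}

#' Generate a random rooted is_a DAG
#'
#' Classes are laid out level by level: each class at depth d attaches to a
#' uniformly random parent at depth d-1; afterwards a fraction of non-root
#' classes receive a second parent from a strictly shallower level, making
#' the graph a DAG rather than a tree.  Deterministic per seed.
#'
#' @param cfg a `generator_config`.
#' @return an `ontology`.
#' @export
generate_ontology <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_classes
    ids <- sprintf("SYN:%04d", seq_len(n))
    root <- ids[1]
    level <- integer(n); level[1] <- 0L
    parents <- rep(list(character(0)), n)
    names(parents) <- ids
    # assign each subsequent class to a parent among already-placed classes
    # of depth < cfg$depth, preferring breadth via max_children
    open_slots <- rep(cfg$max_children, n)   # remaining child slots
    for (i in 2:n) {
      placed <- seq_len(i - 1)
      elig <- placed[level[placed] < cfg$depth & open_slots[placed] > 0]
      if (length(elig) == 0) elig <- placed[level[placed] < cfg$depth]
      p <- if (length(elig) == 1) elig else sample(elig, 1)
      parents[[i]] <- ids[p]
      level[i] <- level[p] + 1L
      open_slots[p] <- open_slots[p] - 1L
    }
    # second parents from strictly shallower levels keep the graph acyclic
    n_multi <- floor(cfg$multi_parent_frac * (n - 1))
    if (n_multi > 0) {
      cand <- sample(2:n, n_multi)
      for (i in cand) {
        shallower <- which(level < level[i] & ids != parents[[i]][1])
        shallower <- setdiff(shallower, i)
        if (length(shallower) == 0) next
        p2 <- if (length(shallower) == 1) shallower else sample(shallower, 1)
        parents[[i]] <- unique(c(parents[[i]], ids[p2]))
      }
    }
    nms <- paste("synthetic class", seq_len(n))
    ont <- new_ontology(ids, nms, rep(list(character(0)), n), parents, root)
    attr(ont, "level") <- stats::setNames(level, ids)
    ont
  })
}

#' Generate a study-structured corpus and grouping table
#'
#' Each group is assigned a topic block: the descendant-or-self set of a
#' depth-2 class (topic subtrees at depth 2 are broad enough to contain
#' several classes yet specific enough that MICA-based measures see them as
#' related).  For a group member, each study is coherent with probability
#' `coherence`: its classes are drawn from the group's topic block, each
#' then replaced by a uniformly random class with probability `noise_rate`.
#' Non-coherent studies and all studies of background items draw uniformly
#' random classes, so only group members share per-study signal.
#'
#' @param ont an `ontology` from [generate_ontology()].
#' @param cfg the same `generator_config`.
#' @return list with `corpus` (a `study_corpus`) and `groups` (named list).
#' @export
generate_corpus <- function(ont, cfg) {
  stopifnot(inherits(ont, "ontology"), inherits(cfg, "generator_config"))
  level <- attr(ont, "level")
  if (is.null(level))
    stop("ontology lacks level information; use generate_ontology()",
         call. = FALSE)
  pool <- setdiff(ont$ids, ont$root)
  topic_roots <- names(level)[level == 2]
  if (length(topic_roots) == 0) topic_roots <- names(level)[level == 1]
  with_seed(cfg$seed + 1L, {
    blocks <- lapply(topic_roots, function(tr) {
      desc <- names(level)[vapply(ont$ancestors, function(a) tr %in% a,
                                  logical(1))]
      desc
    })
    names(blocks) <- topic_roots
    blocks <- blocks[lengths(blocks) >= 2]
    group_topics <- sample(names(blocks), cfg$n_groups, replace = TRUE)
    items <- list()
    groups <- list()
    draw_study <- function(topic_block) {
      k <- sample(cfg$classes_per_study[1]:cfg$classes_per_study[2], 1)
      cls <- if (is.null(topic_block)) {
        sample(pool, min(k, length(pool)))
      } else {
        sample(topic_block, min(k, length(topic_block)),
               replace = length(topic_block) < k)
      }
      if (!is.null(topic_block) && cfg$noise_rate > 0) {
        flip <- stats::runif(length(cls)) < cfg$noise_rate
        if (any(flip)) cls[flip] <- sample(pool, sum(flip), replace = TRUE)
      }
      unique(cls)
    }
    make_item <- function(topic_block) {
      ns <- sample(cfg$studies_per_item[1]:cfg$studies_per_item[2], 1)
      studies <- lapply(seq_len(ns), function(s) {
        coherent <- !is.null(topic_block) &&
          stats::runif(1) < cfg$coherence
        draw_study(if (coherent) topic_block else NULL)
      })
      stats::setNames(studies, as.character(seq_len(ns)))
    }
    idx <- 0L
    for (g in seq_len(cfg$n_groups)) {
      gid <- sprintf("G%03d", g)
      block <- blocks[[group_topics[g]]]
      member_ids <- character(cfg$group_size)
      for (m in seq_len(cfg$group_size)) {
        idx <- idx + 1L
        iid <- sprintf("ITEM%04d", idx)
        items[[iid]] <- make_item(block)
        member_ids[m] <- iid
      }
      groups[[gid]] <- member_ids
    }
    while (idx < cfg$n_items) {
      idx <- idx + 1L
      iid <- sprintf("ITEM%04d", idx)
      items[[iid]] <- make_item(NULL)
    }
    list(corpus = new_study_corpus(items), groups = groups)
  })
}

#' Fixed toy ontology and corpus used throughout the documentation
#'
#' Six classes — root `R`; `A`, `B` below it; leaves `A1`, `A2` under `A`
#' and `B1` under `B` — with a reference population of three annotated
#' items (`I1`: A1, A2; `I2`: A1, B1; `I3`: B, one study each) and one
#' query disease `D1` whose annotations are organized in three studies
#' `[A1]`, `[A1, A2]`, `[B1]`.  Information content is computed from the
#' three reference items only (`D1` is the illustration's query, not part
#' of the annotated reference population), giving e.g.
#' `IC(A) = -ln(2/3)`.
#'
#' @return list with `ontology`, `corpus` (items I1, I2, I3, D1),
#'   `ic_corpus` (items I1, I2, I3 only) and `ic` (an `ic_table` computed
#'   from `ic_corpus`).
#' @export
make_paper_toy <- function() {
  ids <- c("R", "A", "B", "A1", "A2", "B1")
  parents <- list(R = character(0), A = "R", B = "R",
                  A1 = "A", A2 = "A", B1 = "B")
  ont <- new_ontology(ids, ids, rep(list(character(0)), 6), parents, "R")
  ref_items <- list(
    I1 = list(s1 = c("A1", "A2")),
    I2 = list(s1 = c("A1", "B1")),
    I3 = list(s1 = "B"))
  ic_corpus <- new_study_corpus(ref_items)
  corpus <- new_study_corpus(c(ref_items, list(
    D1 = list(`1` = "A1", `2` = c("A1", "A2"), `3` = "B1"))))
  list(ontology = ont, corpus = corpus, ic_corpus = ic_corpus,
       ic = compute_ic(ont, ic_corpus))
}

#' Write the generated artifacts of one configuration to a directory
#'
#' Emits `ontology.obo`, `corpus.tsv` and `groups.tsv`.
#'
#' @param cfg a `generator_config`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
generate_to_dir <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ont <- generate_ontology(cfg)
  gen <- generate_corpus(ont, cfg)
  write_obo(ont, file.path(dir, "ontology.obo"))
  write_corpus(gen$corpus, file.path(dir, "corpus.tsv"))
  write_groups(gen$groups, file.path(dir, "groups.tsv"))
  invisible(dir)
}

#' Write an ontology back to OBO flat format (names + is_a only)
#' @param ont an `ontology`.
#' @param path output file.
#' @export
write_obo <- function(ont, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (id in ont$ids) {
    writeLines(c("", "[Term]", paste0("id: ", id),
                 paste0("name: ", ont$names[[id]])), con)
    for (s in ont$synonyms[[id]])
      writeLines(sprintf('synonym: "%s" EXACT []', s), con)
    for (p in ont$parents[[id]])
      writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}
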