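#' @title Dictionary-based concept recognition in sectioned disease texts
#' @description
#' Converts full-text disease descriptions into study-wise annotation rows
#' under the assumption that each paragraph roughly corresponds to one
#' study.  Recognition is a deterministic, offline longest-match dictionary
#' scan over ontology class names and synonyms (a reproducible stand-in for
#' web-service annotators): case-insensitive, whitespace-normalized,
#' non-overlapping, left-to-right on word boundaries.
#'
#' Input dialect: section headers are lines of the form `## <name>`;
#' paragraphs are separated by one or more blank lines; text before the
#' first header forms the unnamed introductory section.
#' @name text_mining
NULL

#' Default section whitelist for OMIM-style disease descriptions
#'
#' The phenotype-bearing sections retained for mining, plus the unnamed
#' introductory section (always kept).  Sections such as "molecular
#' genetics" are excluded to avoid false-positive phenotype associations.
#' @export
default_sections <- function() {
  c("description", "other features", "biochemical features",
    "diagnosis", "clinical features")
}

#' Parse a sectioned plain-text document
#'
#' @param text document text (single string or character vector of lines).
#' @param item item id (e.g. an OMIM number).
#' @return a `document`: list with `item` and `sections`, each section a
#'   list with `name` (lowercase; `""` for the introductory section) and
#'   `paragraphs` (character vector; empty paragraphs dropped).
#' @export
parse_document <- function(text, item) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  sections <- list()
  cur_name <- ""
  cur_lines <- character(0)
  flush <- function() {
    paras <- split_paragraphs(cur_lines)
    sections[[length(sections) + 1L]] <<-
      list(name = cur_name, paragraphs = paras)
  }
  seen_any <- FALSE
  for (ln in lines) {
    m <- regmatches(ln, regexec("^##\\s+(.*\\S)\\s*$", ln))[[1]]
    if (length(m) == 2) {
      if (seen_any || length(cur_lines) > 0 || cur_name != "") flush()
      cur_name <- tolower(m[2])
      cur_lines <- character(0)
      seen_any <- TRUE
    } else {
      cur_lines <- c(cur_lines, ln)
    }
  }
  flush()
  # drop sections with zero paragraphs, except keep order of the rest
  sections <- Filter(function(s) length(s$paragraphs) > 0, sections)
  structure(list(item = item, sections = sections), class = "document")
}

split_paragraphs <- function(lines) {
  if (length(lines) == 0) return(character(0))
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(blank)
  paras <- vapply(split(lines[!blank], grp[!blank]),
                  function(x) paste(trimws(x), collapse = " "), "")
  unname(paras[nzchar(paras)])
}

#' Keep only whitelisted sections (plus the introductory section)
#'
#' Paragraph indices are implicitly reassigned: after filtering, paragraphs
#' are numbered 1..N in reading order over the retained document, which is
#' the numbering [mine_corpus()] and [annotate_document()] report.
#'
#' @param doc a `document`.
#' @param whitelist lowercase section names to keep; defaults to
#'   [default_sections()].
#' @return filtered `document`.
#' @export
filter_sections <- function(doc, whitelist = default_sections()) {
  keep <- vapply(doc$sections,
                 function(s) s$name == "" || s$name %in% tolower(whitelist),
                 logical(1))
  structure(list(item = doc$item, sections = doc$sections[keep]),
            class = "document")
}

#' Build a longest-match dictionary matcher from an ontology
#'
#' Surface forms are class names plus exact synonyms, lowercased with
#' whitespace collapsed; forms shorter than 3 characters are dropped.  Two
#' classes sharing a surface form are both reported at match time
#' (ambiguity is preserved; a message notes the collisions).
#'
#' @param ont an `ontology` with names and synonyms.
#' @return a `concept_matcher`.
#' @export
build_dictionary <- function(ont) {
  forms <- new.env(parent = emptyenv())   # normalized form -> class ids
  add <- function(form, id) {
    key <- normalize_form(form)
    if (nchar(gsub(" ", "", key, fixed = TRUE)) < 3) return()
    forms[[key]] <- unique(c(forms[[key]], id))
  }
  for (id in ont$ids) {
    add(ont$names[[id]], id)
    for (s in ont$synonyms[[id]]) add(s, id)
  }
  keys <- ls(forms)
  ids_per_form <- lapply(keys, function(k) forms[[k]])
  n_ambig <- sum(lengths(ids_per_form) > 1)
  if (n_ambig > 0)
    message(n_ambig, " surface form(s) shared by multiple classes")
  tok_lens <- lengths(strsplit(keys, " ", fixed = TRUE))
  structure(list(forms = forms, max_tokens = max(c(tok_lens, 1L))),
            class = "concept_matcher")
}

normalize_form <- function(x) {
  tolower(paste(tokenize_words(x)$token, collapse = " "))
}

# Split text into word tokens, keeping the original surface of each token.
# Word characters are letters, digits, apostrophes and hyphens; everything
# else is a boundary, so "cerebral-amyloid angiopathy." tokenizes cleanly.
tokenize_words <- function(text) {
  m <- gregexpr("[A-Za-z0-9'-]+", text)[[1]]
  if (m[1] == -1) return(data.frame(token = character(0)))
  data.frame(token = regmatches(text, list(m))[[1]])
}

#' Recognize ontology concepts in one paragraph
#'
#' Longest-match-wins, non-overlapping, scanning left to right over word
#' tokens.  Each (class, paragraph) pair is emitted at most once.  The
#' matched-text column is the matched surface uppercased with internal
#' whitespace removed (e.g. `NEUROFIBRILLARYTANGLES`).
#'
#' @param text paragraph text.
#' @param matcher a `concept_matcher` from [build_dictionary()].
#' @param item item id.
#' @param paragraph_index 1-based global paragraph index.
#' @return data frame with columns `item`, `class_id`, `matched_text`,
#'   `paragraph` (zero rows if nothing matches).
#' @export
annotate_paragraph <- function(text, matcher, item, paragraph_index) {
  stopifnot(paragraph_index >= 1)
  toks <- tokenize_words(text)$token
  low <- tolower(toks)
  n <- length(toks)
  rows <- list()
  pos <- 1L
  while (pos <= n) {
    matched <- FALSE
    for (len in seq(min(matcher$max_tokens, n - pos + 1L), 1L)) {
      key <- paste(low[pos:(pos + len - 1L)], collapse = " ")
      ids <- matcher$forms[[key]]
      if (!is.null(ids)) {
        surface <- toupper(paste0(toks[pos:(pos + len - 1L)], collapse = ""))
        for (id in ids) {
          rows[[length(rows) + 1L]] <-
            data.frame(item = item, class_id = id, matched_text = surface,
                       paragraph = paragraph_index)
        }
        pos <- pos + len
        matched <- TRUE
        break
      }
    }
    if (!matched) pos <- pos + 1L
  }
  if (length(rows) == 0)
    return(data.frame(item = character(0), class_id = character(0),
                      matched_text = character(0), paragraph = integer(0)))
  out <- do.call(rbind, rows)
  out[!duplicated(out[c("class_id", "paragraph")]), , drop = FALSE]
}

#' Annotate every retained paragraph of a document
#'
#' Paragraphs are numbered 1..N globally across the (already
#' section-filtered) document in reading order.
#'
#' @param doc a `document` (apply [filter_sections()] first).
#' @param matcher a `concept_matcher`.
#' @return data frame of mention rows (see [annotate_paragraph()]).
#' @export
annotate_document <- function(doc, matcher) {
  paras <- unlist(lapply(doc$sections, `[[`, "paragraphs"), use.names = FALSE)
  rows <- lapply(seq_along(paras), function(i)
    annotate_paragraph(paras[i], matcher, doc$item, i))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(item = character(0), class_id = character(0),
                      matched_text = character(0), paragraph = integer(0))
  rownames(out) <- NULL
  out
}

#' Mine a set of documents into a study-wise corpus
#'
#' Each paragraph with at least one recognized concept becomes a study
#' whose id is the paragraph index; documents with zero mentions are absent
#' from the corpus.
#'
#' @param docs list of `document`s (already section-filtered).
#' @param matcher a `concept_matcher`.
#' @return a `study_corpus` (loadable/writable via the corpus TSV round
#'   trip).
#' @export
mine_corpus <- function(docs, matcher) {
  items <- list()
  for (doc in docs) {
    rows <- annotate_document(doc, matcher)
    if (nrow(rows) == 0) next
    studies <- list()
    for (p in sort(unique(rows$paragraph))) {
      studies[[as.character(p)]] <- unique(rows$class_id[rows$paragraph == p])
    }
    items[[doc$item]] <- studies
  }
  new_study_corpus(items)
}

#' Write mention rows as 4-column TSV
#' @param rows data frame from [annotate_document()].
#' @param path output file.
#' @export
write_mentions <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
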