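#' Parse MEDLINE/PubMed XML into abstract records
#'
#' Reads `PubmedArticle` elements; articles with at least one non-empty
#' `AbstractText` yield one record each, with structured-abstract
#' sections concatenated in document order.  Articles without an
#' abstract are skipped (only abstracts are mined); articles without a
#' PMID are skipped with a warning.  Titles are not indexed by default,
#' matching the whole-abstract co-occurrence granularity of the method.
#'
#' @param path Path to a MEDLINE XML file (plain or gzip-compressed).
#' @param include_titles If `TRUE`, the `ArticleTitle` text is prepended
#'   to the abstract before stemming.
#' @return A list with elements `pmid` (character vector) and `stems`
#'   (list of stemmed token vectors, parallel to `pmid`), of class
#'   `abstract_corpus`.
#' @export
parse_pubmed_xml <- function(path, include_titles = FALSE) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) {
      stop(sprintf("malformed MEDLINE XML in '%s': %s",
                   path, conditionMessage(e)), call. = FALSE)
    })
  articles <- xml2::xml_find_all(doc, ".//PubmedArticle")
  pmids <- character(0)
  stems <- list()
  for (art in articles) {
    abst <- xml2::xml_find_all(art, ".//Abstract/AbstractText")
    if (!length(abst)) next
    sections <- xml2::xml_text(abst)
    sections <- sections[nzchar(trimws(sections))]
    if (!length(sections)) next
    pmid_node <- xml2::xml_find_first(art, ".//MedlineCitation/PMID")
    if (inherits(pmid_node, "xml_missing")) {
      pmid_node <- xml2::xml_find_first(art, ".//PMID")
    }
    pmid <- if (inherits(pmid_node, "xml_missing")) "" else
      trimws(xml2::xml_text(pmid_node))
    if (!nzchar(pmid)) {
      warning("skipping PubmedArticle without PMID", call. = FALSE)
      next
    }
    text <- paste(sections, collapse = " ")
    if (include_titles) {
      title <- xml2::xml_find_first(art, ".//ArticleTitle")
      if (!inherits(title, "xml_missing")) {
        text <- paste(xml2::xml_text(title), text)
      }
    }
    st <- stem_tokens(tokenize_text(text))
    if (!length(st)) next
    pmids <- c(pmids, pmid)
    stems[[length(stems) + 1L]] <- st
  }
  structure(list(pmid = pmids, stems = stems), class = "abstract_corpus")
}

#' @export
print.abstract_corpus <- function(x, ...) {
  cat(sprintf("<abstract_corpus> %d abstracts, median length %s tokens\n",
              length(x$pmid),
              if (length(x$stems)) stats::median(lengths(x$stems)) else 0))
  invisible(x)
}

#' Contiguous phrase match between stem sequences
#'
#' `TRUE` iff `term_stems` occurs as a contiguous subsequence of
#' `abstract_stems`.  Both sides must be stemmed under the same stemmer
#' configuration; single-token terms reduce to membership.
#'
#' @param abstract_stems Character vector of abstract stems.
#' @param term_stems Non-empty character vector of term stems.
#' @return Logical scalar.
#' @examples
#' match_phrase(c("Main", "Proteas", "Inhibitor"), c("Main", "Proteas"))
#' @export
match_phrase <- function(abstract_stems, term_stems) {
  m <- length(term_stems)
  if (m == 0L) stop("invalid term: empty stem sequence")
  n <- length(abstract_stems)
  if (n < m) return(FALSE)
  if (m == 1L) return(term_stems %in% abstract_stems)
  starts <- which(abstract_stems == term_stems[1L])
  starts <- starts[starts <= n - m + 1L]
  for (s in starts) {
    if (all(abstract_stems[s:(s + m - 1L)] == term_stems)) return(TRUE)
  }
  FALSE
}

#' Build the term -> abstract inverted index
#'
#' For every distinct stemmed term of the dictionary, records the set of
#' PMIDs whose abstract contains the term as a contiguous stem phrase.
#' Posting sets are sorted, so intersections and serialization are
#' deterministic; repeated occurrences within one abstract count once.
#'
#' @param corpus An `abstract_corpus` from [parse_pubmed_xml()] (or the
#'   synthetic generator).
#' @param dictionary A `term_dictionary`.
#' @return An `inverted_index`: list with `postings` (named list of
#'   sorted PMID character vectors, keyed by the `"|"`-joined stem
#'   sequence) and `doc_count`.
#' @export
build_index <- function(corpus, dictionary) {
  keys <- unique(dictionary$stems)
  term_list <- strsplit(keys, "|", fixed = TRUE)
  n <- length(corpus$pmid)

  # single-token postings first: one pass over the corpus
  tok_counts <- lengths(corpus$stems)
  all_tokens <- unlist(corpus$stems, use.names = FALSE)
  doc_of <- rep.int(seq_len(n), tok_counts)
  first_toks <- vapply(term_list, `[`, character(1L), 1L)
  keep <- all_tokens %in% unique(first_toks)
  tok_docs <- split(doc_of[keep], all_tokens[keep])

  postings <- vector("list", length(keys))
  names(postings) <- keys
  for (i in seq_along(keys)) {
    ts <- term_list[[i]]
    cand <- tok_docs[[ts[1L]]]
    if (is.null(cand)) {
      postings[[i]] <- character(0)
      next
    }
    cand <- unique(cand)
    if (length(ts) > 1L) {
      hit <- vapply(cand, function(d) match_phrase(corpus$stems[[d]], ts),
                    logical(1L))
      cand <- cand[hit]
    }
    postings[[i]] <- .sort_pmids(corpus$pmid[cand])
  }
  structure(list(postings = postings, doc_count = n),
            class = "inverted_index")
}

# numeric-aware deterministic PMID ordering
.sort_pmids <- function(x) {
  x <- unique(x)
  num <- suppressWarnings(as.numeric(x))
  if (anyNA(num)) x[order(x)] else x[order(num)]
}

#' @export
print.inverted_index <- function(x, ...) {
  f <- lengths(x$postings)
  cat(sprintf("<inverted_index> %d terms over %d abstracts (max f = %d)\n",
              length(x$postings), x$doc_count,
              if (length(f)) max(f) else 0L))
  invisible(x)
}

#' Term frequency from an inverted index
#'
#' @param index An `inverted_index`.
#' @param stems_key A `"|"`-joined stem sequence (a `stems` value of the
#'   dictionary).
#' @return Number of abstracts containing the term.
#' @export
term_frequency <- function(index, stems_key) {
  p <- index$postings[[stems_key]]
  if (is.null(p)) 0L else length(p)
}

#' Serialize / reload an inverted index
#'
#' TSV layout: a `#doc_count=N` header comment, then one row per term
#' with the posting list as a comma-joined sorted PMID list.
#'
#' @param index An `inverted_index`.
#' @param path Output/input TSV path.
#' @return `read_index()` returns an `inverted_index`; `write_index()`
#'   returns `path` invisibly.
#' @export
write_index <- function(index, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#doc_count=%d", index$doc_count), con)
  writeLines("term\tpmids", con)
  keys <- sort(names(index$postings))
  for (k in keys) {
    writeLines(paste0(k, "\t", paste(index$postings[[k]], collapse = ",")),
               con)
  }
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines) || !grepl("^#doc_count=", lines[1L])) {
    stop("not an inverted-index file: missing #doc_count header")
  }
  doc_count <- as.integer(sub("^#doc_count=", "", lines[1L]))
  body <- lines[-(1:2)]
  postings <- list()
  for (ln in body) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    key <- parts[1L]
    pm <- if (length(parts) < 2L || !nzchar(parts[2L])) character(0) else
      strsplit(parts[2L], ",", fixed = TRUE)[[1L]]
    postings[[key]] <- pm
  }
  structure(list(postings = postings, doc_count = doc_count),
            class = "inverted_index")
}
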