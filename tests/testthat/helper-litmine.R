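# Shared fixtures and independent oracles, built in code.

# --- small KEGG flat-file fixture -------------------------------------

kegg_fixture_lines <- function() {
  c("ENTRY       D11472                      Drug",
    "NAME        Remdesivir (JAN/USAN);",
    "            Veklury (TN)",
    "///",
    "ENTRY       D02366                      Drug",
    "NAME        Chloroquine (USP/INN)",
    "///",
    "ENTRY       D03469                      Drug",
    "NAME        Chloroquine hydrochloride (USP);",
    "            Aralen hydrochloride (TN)",
    "///",
    "ENTRY       H02398                      Disease",
    "NAME        Coronavirus disease 2019 (COVID-19)",
    "DEFINITION  A viral infectious disease caused by",
    "            severe acute respiratory syndrome coronavirus 2",
    "///",
    "ENTRY       K09581                      KO",
    "NAME        angiotensin-converting enzyme 2",
    "///")
}

# --- small MEDLINE XML fixture ----------------------------------------

medline_fixture <- function(path, articles) {
  # articles: list of list(pmid =, abstract = character() of sections,
  # title =)
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             "<PubmedArticleSet>")
  for (a in articles) {
    lines <- c(lines,
               "  <PubmedArticle>",
               "    <MedlineCitation>",
               if (!is.null(a$pmid)) sprintf("      <PMID>%s</PMID>", a$pmid),
               "      <Article>",
               sprintf("        <ArticleTitle>%s</ArticleTitle>",
                       a$title %||% "t"),
               if (!is.null(a$abstract)) c(
                 "        <Abstract>",
                 sprintf("          <AbstractText>%s</AbstractText>",
                         a$abstract),
                 "        </Abstract>"),
               "      </Article>",
               "    </MedlineCitation>",
               "  </PubmedArticle>")
  }
  writeLines(c(lines, "</PubmedArticleSet>"), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- random toy corpus + dictionary in stem space ---------------------

# Tokens are chosen to be stemmer fixed points, so corpus and dictionary
# live directly in stem space and index behaviour can be compared with
# string-level oracles.
toy_vocab <- function(n) {
  stopifnot(n <= 25)
  paste0("V", LETTERS[seq_len(n)])
}

random_toy_corpus <- function(n_docs, vocab, n_terms, max_len = 12L) {
  stems <- lapply(seq_len(n_docs), function(i) {
    sample(vocab, sample(3:max_len, 1L), replace = TRUE)
  })
  corpus <- structure(list(pmid = as.character(seq_len(n_docs)),
                           stems = stems),
                      class = "abstract_corpus")
  terms <- unique(lapply(seq_len(n_terms), function(i) {
    sample(vocab, sample(1:2, 1L), replace = TRUE)
  }))
  dictionary <- data.frame(
    code = sprintf("C%05d", seq_along(terms)),
    kind = "C",
    term = vapply(terms, paste, character(1L), collapse = " "),
    stems = vapply(terms, paste, character(1L), collapse = "|"),
    stringsAsFactors = FALSE)
  class(dictionary) <- c("term_dictionary", "data.frame")
  list(corpus = corpus, dictionary = dictionary)
}

# independent containment oracle: contiguous token subsequence as
# substring match on space-joined strings
oracle_contains <- function(doc_stems, term_stems) {
  grepl(paste0(" ", paste(term_stems, collapse = " "), " "),
        paste0(" ", paste(doc_stems, collapse = " "), " "),
        fixed = TRUE)
}

oracle_frequency <- function(corpus, term_stems) {
  sum(vapply(corpus$stems, oracle_contains, logical(1L),
             term_stems = term_stems))
}

oracle_joint <- function(corpus, stems_a, stems_b) {
  sum(vapply(corpus$stems, function(d) {
    oracle_contains(d, stems_a) && oracle_contains(d, stems_b)
  }, logical(1L)))
}

# --- random weighted graphs + shortest-path oracle --------------------

random_edge_graph <- function(n_nodes, n_edges) {
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pick <- function() sort(sample(nodes, 2L))
  pairs <- unique(t(replicate(n_edges, pick())))
  data.frame(code_x = pairs[, 1L], code_y = pairs[, 2L],
             distance = round(stats::runif(nrow(pairs), 0.1, 5), 3),
             stringsAsFactors = FALSE) |>
    transform(distance_yx = distance)
}

igraph_distances_from <- function(edges, root) {
  g <- igraph::graph_from_data_frame(
    edges[, c("code_x", "code_y")], directed = FALSE)
  d <- igraph::distances(g, v = root, weights = edges$distance)
  drop(d)
}
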