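#' Merged direct/indirect comparison table
#'
#' Formats the first `top_n` ranked candidates the way the method's
#' published tables are laid out: columns `Code`, `D_id(depth)` (e.g.
#' `"2.939(2)"`), `D_d` and `Name`, with an absent distance rendered as
#' an em dash.
#'
#' @param records A `candidate_table` from [rank_candidates()].
#' @param top_n Number of rows to keep (> 0).
#' @return A data.frame with character columns `Code`, `D_id(depth)`,
#'   `D_d`, `Name`.
#' @export
merged_table <- function(records, top_n = 50L) {
  if (top_n <= 0L) stop("top_n must be positive")
  rec <- utils::head(records, top_n)
  fmt_did <- ifelse(
    is.finite(rec$indirect_distance),
    sprintf("%.3f(%d)", rec$indirect_distance, rec$indirect_depth),
    "—")
  fmt_dd <- ifelse(is.na(rec$direct_distance), "—",
                   sprintf("%.3f", rec$direct_distance))
  out <- data.frame(Code = rec$code, D_id = fmt_did, D_d = fmt_dd,
                    Name = rec$name, stringsAsFactors = FALSE,
                    check.names = FALSE)
  names(out)[2L] <- "D_id(depth)"
  out
}

#' Direct vs indirect agreement statistics
#'
#' Quantifies how well indirect (tree-concatenated) distances reproduce
#' direct (co-occurrence) distances over the `first_k` ranked candidates
#' that possess both.  With `s = sd(D_d)` (sample standard deviation,
#' n-1 denominator), each item's normalized difference is
#' `(D_id - D_d) / s`; the mean and standard deviation of these
#' normalized differences summarise the additivity of the distance
#' model, and are the statistic used to compare coefficient methods.
#'
#' @param records A `candidate_table`.
#' @param first_k Number of leading ranked rows to consider (>= 2); rows
#'   lacking either distance are skipped, not counted.
#' @return A list with `n_items`, `mean_norm_diff`, `sd_norm_diff`,
#'   `sd_direct`.
#' @export
agreement_statistics <- function(records, first_k = 100L) {
  if (first_k < 2L) stop("first_k must be >= 2")
  both <- records[!is.na(records$direct_distance) &
                    is.finite(records$indirect_distance), , drop = FALSE]
  both <- utils::head(both, first_k)
  if (nrow(both) < 2L) {
    stop("need at least 2 candidates with both direct and indirect distances")
  }
  s <- stats::sd(both$direct_distance)
  if (s == 0) stop("degenerate direct distances: zero standard deviation")
  nd <- (both$indirect_distance - both$direct_distance) / s
  list(n_items = nrow(both),
       mean_norm_diff = mean(nd),
       sd_norm_diff = stats::sd(nd),
       sd_direct = s)
}

#' Run the full mining pipeline
#'
#' KEGG flat files and MEDLINE XML in; ranked repositioning candidates
#' out.  Convenience wrapper over [parse_kegg_flatfile()],
#' [build_dictionary()], [parse_pubmed_xml()], [build_index()],
#' [build_edge_set()], [build_tree()] and [rank_candidates()].
#'
#' @param kegg_files Character vector of KEGG flat-file paths.
#' @param pubmed_files Character vector of MEDLINE XML paths.
#' @param root Root disease code (e.g. `"H02398"`).
#' @param method Coefficient method (see [code_pair_distance()]).
#' @param kinds Code kinds to rank (default drugs, `"D"`).
#' @param min_support Minimum best-pair co-occurrence for an edge.
#' @param tree_method Tree growth rule (see [build_tree()]).
#' @param out_dir If non-`NULL`, writes `dictionary.tsv`, `index.tsv`,
#'   `edges.tsv`, `tree.tsv`, `tree.nwk`, `candidates.tsv` and
#'   `stats.json` there.
#' @param top_n Rows of the merged table written to `candidates.tsv`.
#' @param first_k Items used for [agreement_statistics()] (skipped when
#'   fewer than 2 rows qualify).
#' @param verbose Log record counts at each stage.
#' @return A list with `dictionary`, `corpus`, `index`, `edges`, `tree`,
#'   `candidates`, `stats`.
#' @export
run_pipeline <- function(kegg_files, pubmed_files, root,
                         method = c("otsuka_ochiai", "dice", "conditional"),
                         kinds = "D", min_support = 1L,
                         tree_method = c("cumulative", "edge"),
                         out_dir = NULL, top_n = 50L, first_k = 100L,
                         verbose = FALSE) {
  method <- match.arg(method)
  tree_method <- match.arg(tree_method)
  say <- function(...) if (verbose) message(sprintf(...))

  recs <- do.call(rbind, lapply(kegg_files, parse_kegg_flatfile))
  say("parsed %d KEGG records", nrow(recs))
  dictionary <- build_dictionary(recs)
  say("dictionary: %d terms / %d codes", nrow(dictionary),
      length(unique(dictionary$code)))
  if (!root %in% dictionary$code) {
    stop(sprintf("root code '%s' has no terms in the dictionary", root))
  }

  corpora <- lapply(pubmed_files, parse_pubmed_xml)
  corpus <- structure(
    list(pmid = unlist(lapply(corpora, `[[`, "pmid")),
         stems = do.call(c, lapply(corpora, `[[`, "stems"))),
    class = "abstract_corpus")
  if (anyDuplicated(corpus$pmid)) {
    stop("duplicate PMIDs across input files")
  }
  say("corpus: %d abstracts", length(corpus$pmid))

  index <- build_index(corpus, dictionary)
  say("index: %d terms with f > 0", sum(lengths(index$postings) > 0))
  edges <- build_edge_set(index = index, dictionary = dictionary,
                          method = method, min_support = min_support)
  say("edges: %d code pairs with support >= %d", nrow(edges), min_support)
  tree <- build_tree(root, edges, method = tree_method)
  say("tree: %d nodes, max depth %d", nrow(tree),
      if (nrow(tree)) max(tree$depth) else 0L)
  candidates <- rank_candidates(tree, edges, dictionary, kinds = kinds)
  say("candidates: %d of kinds {%s}", nrow(candidates),
      paste(kinds, collapse = ","))
  stats <- tryCatch(agreement_statistics(candidates, first_k = first_k),
                    error = function(e) NULL)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_dictionary(dictionary, file.path(out_dir, "dictionary.tsv"))
    write_index(index, file.path(out_dir, "index.tsv"))
    write_edges(edges, file.path(out_dir, "edges.tsv"))
    write_tree_tsv(tree, file.path(out_dir, "tree.tsv"))
    write_tree_newick(tree, file.path(out_dir, "tree.nwk"))
    utils::write.table(merged_table(candidates, top_n),
                       file.path(out_dir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    if (!is.null(stats)) {
      jsonlite::write_json(stats, file.path(out_dir, "stats.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  list(dictionary = dictionary, corpus = corpus, index = index,
       edges = edges, tree = tree, candidates = candidates, stats = stats)
}

#' Compare coefficient methods on one corpus
#'
#' Runs edge construction, tree growth, ranking and
#' [agreement_statistics()] once per coefficient method on a fixed
#' index, and tabulates the agreement between direct and indirect
#' distances.  A smaller normalized-difference spread means the method's
#' distances concatenate more consistently.
#'
#' @param index An `inverted_index`.
#' @param dictionary A `term_dictionary`.
#' @param root Root code.
#' @param methods Methods to compare.
#' @param kinds Candidate kinds.
#' @param first_k Items per method for the statistic.
#' @param min_support Minimum edge support.
#' @return data.frame with one row per method: `method`, `n_items`,
#'   `mean_norm_diff`, `sd_norm_diff`, `sd_direct`.
#' @export
compare_methods <- function(index, dictionary, root,
                            methods = c("otsuka_ochiai", "dice",
                                        "conditional"),
                            kinds = "D", first_k = 100L,
                            min_support = 1L) {
  rows <- lapply(methods, function(m) {
    edges <- build_edge_set(index = index, dictionary = dictionary,
                            method = m, min_support = min_support)
    tree <- build_tree(root, edges)
    cand <- rank_candidates(tree, edges, dictionary, kinds = kinds)
    st <- tryCatch(agreement_statistics(cand, first_k = first_k),
                   error = function(e) {
                     warning(sprintf("method %s: %s", m,
                                     conditionMessage(e)), call. = FALSE)
                     list(n_items = NA_integer_,
                          mean_norm_diff = NA_real_,
                          sd_norm_diff = NA_real_, sd_direct = NA_real_)
                   })
    data.frame(method = m, n_items = st$n_items,
               mean_norm_diff = st$mean_norm_diff,
               sd_norm_diff = st$sd_norm_diff,
               sd_direct = st$sd_direct, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
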