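#' Pairwise co-occurrence counts
#'
#' Container for the document frequencies a coefficient operates on:
#' `f_a` and `f_b` are the numbers of abstracts containing term a and
#' term b, `f_ab` the number containing both, `n_docs` the corpus size.
#'
#' @param f_a,f_b,f_ab,n_docs Non-negative counts with
#'   `0 <= f_ab <= min(f_a, f_b) <= n_docs`.
#' @return A named list of validated counts.
#' @export
pair_counts <- function(f_a, f_b, f_ab, n_docs = NA_integer_) {
  if (f_a < 0 || f_b < 0 || f_ab < 0) stop("counts must be non-negative")
  if (f_ab > min(f_a, f_b)) {
    stop("f_ab must not exceed min(f_a, f_b)")
  }
  if (!is.na(n_docs) && max(f_a, f_b) > n_docs) {
    stop("marginal frequencies must not exceed n_docs")
  }
  list(f_a = f_a, f_b = f_b, f_ab = f_ab, n_docs = n_docs)
}

#' Association coefficients between two terms
#'
#' Three measures of the association between terms a and b from their
#' document frequencies:
#' * `conditional_probability()`: `f_ab / f_a`, the probability that b
#'   occurs in an abstract given that a does (asymmetric);
#' * `dice_coefficient()`: `2 * f_ab / (f_a + f_b)` (symmetric);
#' * `otsuka_ochiai()`: `f_ab / sqrt(f_a * f_b)`, equal to the cosine
#'   similarity of the binary document-incidence vectors (symmetric).
#'
#' All lie in `[0, 1]`, and `dice <= otsuka_ochiai` with equality iff
#' `f_a == f_b` (AM-GM inequality).
#'
#' @param counts A [pair_counts()] list (or any list with `f_a`, `f_b`,
#'   `f_ab`).
#' @return A number in `[0, 1]`.
#' @examples
#' conditional_probability(pair_counts(8, 5, 2)) # 0.25
#' dice_coefficient(pair_counts(4, 6, 2))        # 0.4
#' otsuka_ochiai(pair_counts(4, 9, 3))           # 0.5
#' @export
conditional_probability <- function(counts) {
  if (counts$f_a <= 0) stop("conditional probability undefined for f_a = 0")
  counts$f_ab / counts$f_a
}

#' @rdname conditional_probability
#' @export
dice_coefficient <- function(counts) {
  if (counts$f_a + counts$f_b <= 0) {
    stop("Dice coefficient undefined for f_a = f_b = 0")
  }
  2 * counts$f_ab / (counts$f_a + counts$f_b)
}

#' @rdname conditional_probability
#' @export
otsuka_ochiai <- function(counts) {
  if (counts$f_a <= 0 || counts$f_b <= 0) {
    stop("Otsuka-Ochiai coefficient undefined for zero marginal frequency")
  }
  counts$f_ab / sqrt(counts$f_a * counts$f_b)
}

.assoc_methods <- c("otsuka_ochiai", "dice", "conditional")

.coefficient <- function(f_a, f_b, f_ab, method) {
  switch(method,
         otsuka_ochiai = f_ab / sqrt(f_a * f_b),
         dice = 2 * f_ab / (f_a + f_b),
         conditional = f_ab / f_a,
         stop("unknown method: ", method))
}

#' Distance between two KEGG codes
#'
#' Evaluates the chosen coefficient for every (term of x) x (term of y)
#' pair with non-zero marginal frequencies and takes the maximum; the
#' code-pair distance is `-ln(max coeff)` (`+Inf` when no term pair
#' co-occurs).  The arg-max term pair, its co-occurrence support and the
#' supporting PMIDs are recorded so single-paper links can be audited.
#' Ties among term pairs at the maximal coefficient are broken by
#' lexicographic term order.
#'
#' For the asymmetric `conditional` method the coefficient is reported
#' in both directions (`coefficient` for x given y's presence is
#' direction x -> y, i.e. `f_ab / f_x`; `coefficient_yx` the reverse);
#' direction is chosen at tree-growth time.
#'
#' @param code_x,code_y KEGG codes present in `dictionary`.
#' @param index An `inverted_index` built from the same dictionary.
#' @param dictionary A `term_dictionary`.
#' @param method One of `"otsuka_ochiai"` (default), `"dice"`,
#'   `"conditional"`.
#' @return One-row data.frame with columns `code_x`, `code_y`, `f_a`,
#'   `f_b`, `f_ab`, `coefficient`, `coefficient_yx`, `distance`,
#'   `distance_yx`, `best_term_x`, `best_term_y`, `pmids`
#'   (comma-joined).
#' @export
code_pair_distance <- function(code_x, code_y, index, dictionary,
                               method = c("otsuka_ochiai", "dice",
                                          "conditional")) {
  method <- match.arg(method)
  tx <- .dict_code_terms(dictionary, code_x)
  ty <- .dict_code_terms(dictionary, code_y)
  best <- NULL
  co_yx <- 0
  for (kx in sort(names(tx))) {
    fa <- term_frequency(index, kx)
    if (fa == 0L) next
    pa <- index$postings[[kx]]
    for (ky in sort(names(ty))) {
      fb <- term_frequency(index, ky)
      if (fb == 0L) next
      inter <- intersect(pa, index$postings[[ky]])
      fab <- length(inter)
      co <- .coefficient(fa, fb, fab, method)
      if (is.null(best) || co > best$co + 1e-15) {
        best <- list(kx = kx, ky = ky, fa = fa, fb = fb, fab = fab,
                     co = co, pmids = inter)
      }
      # reverse direction maximised independently (conditional only)
      co_rev <- if (method == "conditional") fab / fb else co
      if (co_rev > co_yx) co_yx <- co_rev
    }
  }
  if (is.null(best)) {
    best <- list(kx = NA_character_, ky = NA_character_,
                 fa = 0L, fb = 0L, fab = 0L, co = 0, pmids = character(0))
  }
  data.frame(
    code_x = code_x, code_y = code_y,
    f_a = best$fa, f_b = best$fb, f_ab = best$fab,
    coefficient = best$co, coefficient_yx = co_yx,
    distance = if (best$co > 0) -log(best$co) else Inf,
    distance_yx = if (co_yx > 0) -log(co_yx) else Inf,
    best_term_x = best$kx, best_term_y = best$ky,
    pmids = paste(.sort_pmids(best$pmids), collapse = ","),
    stringsAsFactors = FALSE)
}

#' Build the sparse association edge set
#'
#' Enumerates candidate code pairs by joining the inverted index — only
#' codes whose terms co-occur in at least one abstract are paired, never
#' by dense all-pairs scanning — then scores each candidate with
#' [code_pair_distance()] and keeps edges whose best-pair support
#' `f_ab` is at least `min_support`.
#'
#' @param codes Character vector of codes to connect (default: all codes
#'   of the dictionary).
#' @param index An `inverted_index`.
#' @param dictionary A `term_dictionary`.
#' @param method Coefficient method (see [code_pair_distance()]).
#' @param min_support Minimum co-occurrence count for an edge (>= 1).
#' @return An `association_edges` data.frame sorted by
#'   `(code_x, code_y)`; one row per unordered code pair.
#' @export
build_edge_set <- function(codes = NULL, index, dictionary,
                           method = c("otsuka_ochiai", "dice",
                                      "conditional"),
                           min_support = 1L) {
  method <- match.arg(method)
  if (min_support < 1L) stop("min_support must be >= 1")
  if (is.null(codes)) codes <- unique(dictionary$code)
  dict <- dictionary[dictionary$code %in% codes, , drop = FALSE]

  # pmid -> codes present, via term postings
  code_of_key <- split(dict$code, dict$stems)
  pm2codes <- new.env(parent = emptyenv())
  for (key in names(code_of_key)) {
    pm <- index$postings[[key]]
    if (is.null(pm) || !length(pm)) next
    for (p in pm) {
      pm2codes[[p]] <- c(pm2codes[[p]], code_of_key[[key]])
    }
  }
  pairs <- new.env(parent = emptyenv())
  for (p in ls(pm2codes)) {
    cs <- sort(unique(pm2codes[[p]]))
    if (length(cs) < 2L) next
    for (i in seq_len(length(cs) - 1L)) {
      for (j in (i + 1L):length(cs)) {
        pairs[[paste(cs[i], cs[j], sep = "\r")]] <- TRUE
      }
    }
  }
  keys <- sort(ls(pairs))
  rows <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    cp <- strsplit(keys[i], "\r", fixed = TRUE)[[1L]]
    edge <- code_pair_distance(cp[1L], cp[2L], index, dictionary, method)
    if (edge$f_ab >= min_support) rows[[i]] <- edge
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  out <- if (length(rows)) do.call(rbind, rows) else {
    code_pair_distance_empty()
  }
  out <- out[order(out$code_x, out$code_y), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "method") <- method
  class(out) <- c("association_edges", "data.frame")
  out
}

code_pair_distance_empty <- function() {
  data.frame(code_x = character(0), code_y = character(0),
             f_a = integer(0), f_b = integer(0), f_ab = integer(0),
             coefficient = numeric(0), coefficient_yx = numeric(0),
             distance = numeric(0), distance_yx = numeric(0),
             best_term_x = character(0), best_term_y = character(0),
             pmids = character(0), stringsAsFactors = FALSE)
}

#' @export
print.association_edges <- function(x, ...) {
  cat(sprintf("<association_edges> %d edges (method: %s)\n", nrow(x),
              attr(x, "method") %||% "?"))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize / reload an association edge set
#'
#' @param edges An `association_edges` data.frame.
#' @param path TSV path.
#' @return `read_edges()` returns `association_edges`; `write_edges()`
#'   returns `path` invisibly.
#' @export
write_edges <- function(edges, path) {
  df <- as.data.frame(edges)
  df$method <- attr(edges, "method") %||% NA_character_
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  df <- utils::read.delim(path, quote = "", fileEncoding = "UTF-8",
                          colClasses = c(pmids = "character"))
  method <- unique(df$method)[1L]
  df$method <- NULL
  df$best_term_x <- as.character(df$best_term_x)
  df$best_term_y <- as.character(df$best_term_y)
  attr(df, "method") <- method
  class(df) <- c("association_edges", "data.frame")
  df
}
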