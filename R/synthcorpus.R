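#' Specification of a synthetic literature corpus
#'
#' Describes a toy KEGG-style dictionary plus an abstract corpus with
#' planted co-occurrence structure, so the whole mining pipeline can run
#' and be validated without any database download.
#'
#' The sampling model is a mixture over abstract-level events: each
#' abstract mentions either one planted code pair (with the stated joint
#' probability), one single code (topping its marginal up), or only
#' background noise.  Marginal and pairwise mention probabilities are
#' therefore *exact* by construction, and code pairs without an entry in
#' `pair_probs` never co-occur — which is what lets a planted
#' disease-protein-drug chain have strictly no direct disease-drug
#' co-occurrence.  The price is that an abstract never mentions more
#' than two planted codes; background vocabulary fills the rest.
#'
#' @param n_abstracts Number of abstracts to generate.
#' @param codes data.frame with columns `code`, `kind`.
#' @param synonyms Named list (one entry per code): named numeric vector
#'   of synonym-usage weights, e.g. `c("covira syndrome" = 0.8, COVIRA
#'   = 0.2)`.  Weights must sum to 1; the synonym used for a mention is
#'   drawn with these weights.
#' @param marginal_probs Named numeric vector: probability that an
#'   abstract mentions each code.
#' @param pair_probs data.frame with columns `x`, `y`, `p`: probability
#'   that an abstract mentions both codes of the pair.
#' @param chain Character vector of codes, root disease first, drug
#'   last: the planted repositioning path.
#' @param noise_vocab_size Size of the background vocabulary.
#' @param abstract_len Integer range (min, max) of noise tokens per
#'   abstract.
#' @param inflect If `TRUE` (default), inserted mentions are randomly
#'   pluralised and case-flipped (stem-safely) to exercise the stemmer.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A validated `corpus_spec` object.
#' @export
corpus_spec <- function(n_abstracts, codes, synonyms, marginal_probs,
                        pair_probs, chain = NULL,
                        noise_vocab_size = 400L,
                        abstract_len = c(25L, 60L),
                        inflect = TRUE, seed = 1L) {
  stopifnot(is.data.frame(codes), all(c("code", "kind") %in% names(codes)))
  cs <- codes$code
  if (anyDuplicated(cs)) stop("duplicate codes in spec")
  if (!setequal(names(synonyms), cs)) {
    stop("synonyms must be named by exactly the spec codes")
  }
  for (cd in cs) {
    w <- synonyms[[cd]]
    if (is.null(names(w)) || any(!nzchar(names(w)))) {
      stop("synonym vectors must be named by the synonym strings")
    }
    if (abs(sum(w) - 1) > 1e-8 || any(w <= 0)) {
      stop(sprintf("synonym weights for %s must be positive and sum to 1", cd))
    }
  }
  if (!setequal(names(marginal_probs), cs)) {
    stop("marginal_probs must be named by exactly the spec codes")
  }
  if (any(marginal_probs <= 0 | marginal_probs >= 1)) {
    stop("marginal probabilities must lie strictly in (0, 1)")
  }
  stopifnot(is.data.frame(pair_probs),
            all(c("x", "y", "p") %in% names(pair_probs)))
  if (any(!pair_probs$x %in% cs) || any(!pair_probs$y %in% cs)) {
    stop("pair_probs refers to unknown codes")
  }
  if (any(pair_probs$p < 0 | pair_probs$p > 1)) {
    stop("pair probabilities must lie in [0, 1]")
  }
  for (i in seq_len(nrow(pair_probs))) {
    lim <- min(marginal_probs[[pair_probs$x[i]]],
               marginal_probs[[pair_probs$y[i]]])
    if (pair_probs$p[i] > lim + 1e-12) {
      stop(sprintf("pair probability %s-%s exceeds a marginal",
                   pair_probs$x[i], pair_probs$y[i]))
    }
  }
  # per-code joint mass must fit inside the marginal; total event mass <= 1
  jsum <- stats::setNames(rep(0, length(cs)), cs)
  for (i in seq_len(nrow(pair_probs))) {
    jsum[pair_probs$x[i]] <- jsum[pair_probs$x[i]] + pair_probs$p[i]
    jsum[pair_probs$y[i]] <- jsum[pair_probs$y[i]] + pair_probs$p[i]
  }
  if (any(jsum > marginal_probs[cs] + 1e-12)) {
    stop("sum of pair probabilities exceeds a code's marginal probability")
  }
  if (sum(marginal_probs) - sum(pair_probs$p) > 1 + 1e-12) {
    stop("total event probability exceeds 1; lower marginals or joints")
  }
  if (!is.null(chain)) {
    if (any(!chain %in% cs)) stop("chain refers to unknown codes")
    if (length(chain) < 2L) stop("chain needs at least two codes")
  }
  # synonym stems must not collide across codes
  stem_key <- function(term) paste(stem_phrase(term), collapse = "|")
  keys <- lapply(cs, function(cd) {
    vapply(names(synonyms[[cd]]), stem_key, character(1L))
  })
  flat <- data.frame(code = rep(cs, lengths(keys)),
                     key = unlist(keys), stringsAsFactors = FALSE)
  by_key <- split(flat$code, flat$key)
  clash <- vapply(by_key, function(x) length(unique(x)) > 1L, logical(1L))
  if (any(clash)) {
    stop("synonyms of different codes share a stem: ",
         paste(names(by_key)[clash], collapse = ", "))
  }
  structure(list(n_abstracts = as.integer(n_abstracts), codes = codes,
                 synonyms = synonyms,
                 marginal_probs = marginal_probs[cs],
                 pair_probs = pair_probs, chain = chain,
                 noise_vocab_size = as.integer(noise_vocab_size),
                 abstract_len = as.integer(abstract_len),
                 inflect = isTRUE(inflect), seed = as.integer(seed)),
            class = "corpus_spec")
}

#' @export
print.corpus_spec <- function(x, ...) {
  cat(sprintf(
    "<corpus_spec> %d abstracts, %d codes, %d planted pairs, seed %d\n",
    x$n_abstracts, nrow(x$codes), nrow(x$pair_probs), x$seed))
  invisible(x)
}

# stem-level synonym weights of one code (colliding raw variants merge)
.spec_stem_weights <- function(spec, code) {
  w <- spec$synonyms[[code]]
  keys <- vapply(names(w), function(t) paste(stem_phrase(t), collapse = "|"),
                 character(1L))
  tapply(unname(w), keys, sum)
}

.spec_pair_prob <- function(spec, x, y) {
  pp <- spec$pair_probs
  sel <- (pp$x == x & pp$y == y) | (pp$x == y & pp$y == x)
  if (any(sel)) sum(pp$p[sel]) else 0
}

#' Population coefficient implied by a corpus spec
#'
#' Closed-form expected value of the code-level (max-pooled) coefficient
#' between two codes: the coefficient is evaluated at the population
#' term-level probabilities (code marginal times synonym weight; joint
#' times both weights) for every synonym-stem pair, and the maximum is
#' returned — mirroring exactly what the pipeline estimates from counts.
#'
#' @param spec A `corpus_spec`.
#' @param x,y Codes in the spec.
#' @param method Coefficient method.
#' @return Expected coefficient in `[0, 1]`.
#' @export
expected_coefficient <- function(spec, x, y,
                                 method = c("otsuka_ochiai", "dice",
                                            "conditional")) {
  method <- match.arg(method)
  m_x <- unname(spec$marginal_probs[x])
  m_y <- unname(spec$marginal_probs[y])
  if (is.na(m_x) || is.na(m_y) || m_x <= 0 || m_y <= 0) {
    stop("expected_coefficient undefined for missing or zero marginal ",
         "probability")
  }
  j <- .spec_pair_prob(spec, x, y)
  if (j == 0) return(0)
  wx <- .spec_stem_weights(spec, x)
  wy <- .spec_stem_weights(spec, y)
  best <- 0
  for (a in wx) {
    for (b in wy) {
      v <- switch(method,
                  otsuka_ochiai = (j * a * b) / sqrt(m_x * a * m_y * b),
                  dice = 2 * j * a * b / (m_x * a + m_y * b),
                  conditional = (j * a * b) / (m_x * a))
      if (v > best) best <- v
    }
  }
  best
}

#' Delta-method standard error of the estimated log coefficient
#'
#' Conservative sampling standard deviation of `-ln(K-hat)` for one
#' planted pair at the spec's corpus size, from the binomial variances
#' of the joint and both term-level marginal counts (covariances, which
#' only reduce the variance, are dropped).  Used to set statistical
#' tolerance bands for end-to-end recovery checks.
#'
#' @inheritParams expected_coefficient
#' @return Standard deviation of the estimated edge distance.
#' @export
expected_distance_se <- function(spec, x, y,
                                 method = c("otsuka_ochiai", "dice",
                                            "conditional")) {
  method <- match.arg(method)
  n <- spec$n_abstracts
  wx <- .spec_stem_weights(spec, x)
  wy <- .spec_stem_weights(spec, y)
  # probabilities at the dominant (max-weight) stem pair
  a <- max(wx)
  b <- max(wy)
  j <- .spec_pair_prob(spec, x, y) * a * b
  mx <- spec$marginal_probs[[x]] * a
  my <- spec$marginal_probs[[y]] * b
  if (j <= 0) stop("no planted joint probability for this pair")
  v <- (1 - j) / (n * j)
  v <- v + switch(method,
                  otsuka_ochiai = 0.25 * (1 - mx) / (n * mx) +
                    0.25 * (1 - my) / (n * my),
                  dice = (mx * (1 - mx) + my * (1 - my)) /
                    (n * (mx + my)^2),
                  conditional = (1 - mx) / (n * mx))
  sqrt(v)
}

#' Expected indirect distance along the planted chain
#'
#' Sum of `-ln(expected coefficient)` over consecutive chain pairs, with
#' its conservative sampling standard deviation.
#'
#' @param spec A `corpus_spec` with a chain.
#' @param method Coefficient method.
#' @return List with `distance` and `se`.
#' @export
expected_chain_distance <- function(spec,
                                    method = c("otsuka_ochiai", "dice",
                                               "conditional")) {
  method <- match.arg(method)
  if (is.null(spec$chain)) stop("spec has no planted chain")
  d <- 0
  v <- 0
  for (i in seq_len(length(spec$chain) - 1L)) {
    x <- spec$chain[i]
    y <- spec$chain[i + 1L]
    k <- expected_coefficient(spec, x, y, method)
    if (k <= 0) stop("chain link has zero expected coefficient")
    d <- d - log(k)
    v <- v + expected_distance_se(spec, x, y, method)^2
  }
  list(distance = d, se = sqrt(v))
}

# deterministic pseudo-word noise vocabulary, disjoint in stem space
# from every synonym token
.noise_vocab <- function(spec) {
  syll <- c("ba", "ce", "di", "fo", "gu", "ha", "ki", "lo", "mu", "ne",
            "pa", "qui", "ro", "sa", "te", "vu", "wa", "xe", "yo", "zi",
            "bra", "cle", "dri", "flo", "gru", "pla", "ste", "tri")
  banned <- unique(unlist(lapply(names(spec$synonyms), function(cd) {
    unlist(lapply(names(spec$synonyms[[cd]]), function(t) {
      stem_tokens(tokenize_text(t))
    }))
  })))
  out <- character(0)
  tries <- 0L
  while (length(out) < spec$noise_vocab_size && tries < 50L) {
    tries <- tries + 1L
    need <- spec$noise_vocab_size - length(out)
    cand <- vapply(seq_len(need * 2L), function(i) {
      paste(sample(syll, sample(2:4, 1L), replace = TRUE), collapse = "")
    }, character(1L))
    cand <- setdiff(unique(cand), out)
    st <- stem_tokens(cand)
    cand <- cand[!st %in% banned]
    out <- c(out, cand)
  }
  utils::head(out, spec$noise_vocab_size)
}

# stem-safe plural: only applied when the inflected surface stems back
# to the same key
.inflect_mention <- function(toks) {
  if (stats::runif(1L) < 0.25) {
    last <- toks[length(toks)]
    if (!grepl("s$", last)) {
      plural <- paste0(last, "s")
      if (identical(stem_word(plural), stem_word(last))) {
        toks[length(toks)] <- plural
      }
    }
  }
  if (stats::runif(1L) < 0.25) {
    first <- toks[1L]
    if (!is_protected_token(first) && grepl("^[A-Za-z]", first)) {
      ch <- substr(first, 1L, 1L)
      flipped <- if (ch %in% letters) toupper(ch) else tolower(ch)
      toks[1L] <- paste0(flipped, substring(first, 2L))
    }
  }
  toks
}

#' Generate the synthetic corpus files
#'
#' Writes a MEDLINE-dialect XML corpus, the matching KEGG-dialect flat
#' file, and a ground-truth TSV of planted probabilities with the
#' coefficients they imply.  Byte-identical output for identical specs.
#'
#' @param spec A `corpus_spec`.
#' @param dir Output directory (created if needed).
#' @return List with paths `pubmed_xml`, `kegg_flat`, `truth_tsv` and
#'   the ground-truth data.frame `truth`.
#' @export
generate_corpus <- function(spec, dir) {
  stopifnot(inherits(spec, "corpus_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed)

  noise <- .noise_vocab(spec)
  cs <- spec$codes$code

  # abstract-level event mixture: planted pairs, singleton top-ups, none
  ev_lab <- list()
  ev_p <- numeric(0)
  for (i in seq_len(nrow(spec$pair_probs))) {
    ev_lab[[length(ev_lab) + 1L]] <- c(spec$pair_probs$x[i],
                                       spec$pair_probs$y[i])
    ev_p <- c(ev_p, spec$pair_probs$p[i])
  }
  jsum <- stats::setNames(rep(0, length(cs)), cs)
  for (i in seq_len(nrow(spec$pair_probs))) {
    jsum[spec$pair_probs$x[i]] <- jsum[spec$pair_probs$x[i]] +
      spec$pair_probs$p[i]
    jsum[spec$pair_probs$y[i]] <- jsum[spec$pair_probs$y[i]] +
      spec$pair_probs$p[i]
  }
  for (cd in cs) {
    ev_lab[[length(ev_lab) + 1L]] <- cd
    ev_p <- c(ev_p, spec$marginal_probs[[cd]] - jsum[[cd]])
  }
  ev_lab[[length(ev_lab) + 1L]] <- character(0)
  ev_p <- c(ev_p, 1 - sum(ev_p))

  xml_lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
                 "<PubmedArticleSet>")
  events <- sample.int(length(ev_p), spec$n_abstracts, replace = TRUE,
                       prob = ev_p)
  for (i in seq_len(spec$n_abstracts)) {
    len <- sample(spec$abstract_len[1L]:spec$abstract_len[2L], 1L)
    toks <- sample(noise, len, replace = TRUE)
    for (cd in ev_lab[[events[i]]]) {
      w <- spec$synonyms[[cd]]
      term <- names(w)[sample.int(length(w), 1L, prob = unname(w))]
      mt <- tokenize_text(term)
      if (spec$inflect) mt <- .inflect_mention(mt)
      pos <- sample.int(length(toks) + 1L, 1L)
      toks <- append(toks, mt, after = pos - 1L)
    }
    xml_lines <- c(xml_lines, .medline_article(i, paste(toks, collapse = " ")))
  }
  xml_lines <- c(xml_lines, "</PubmedArticleSet>")
  xml_path <- file.path(dir, "pubmed.xml")
  writeLines(xml_lines, xml_path, useBytes = TRUE)

  flat_path <- file.path(dir, "kegg.flat")
  writeLines(unlist(lapply(seq_len(nrow(spec$codes)), function(i) {
    cd <- spec$codes$code[i]
    syn <- names(spec$synonyms[[cd]])
    name_lines <- paste0(syn, c(rep(";", length(syn) - 1L), ""))
    c(sprintf("%-12s%s", "ENTRY", paste(cd, spec$codes$kind[i])),
      sprintf("%-12s%s", "NAME", name_lines[1L]),
      if (length(name_lines) > 1L) paste0(strrep(" ", 12L), name_lines[-1L]),
      "///")
  })), flat_path, useBytes = TRUE)

  truth <- do.call(rbind, lapply(seq_len(nrow(spec$pair_probs)), function(i) {
    x <- spec$pair_probs$x[i]
    y <- spec$pair_probs$y[i]
    data.frame(x = x, y = y,
               m_x = spec$marginal_probs[[x]],
               m_y = spec$marginal_probs[[y]],
               joint = spec$pair_probs$p[i],
               k_otsuka_ochiai = expected_coefficient(spec, x, y,
                                                      "otsuka_ochiai"),
               k_dice = expected_coefficient(spec, x, y, "dice"),
               k_conditional = expected_coefficient(spec, x, y,
                                                    "conditional"),
               stringsAsFactors = FALSE)
  }))
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  list(pubmed_xml = xml_path, kegg_flat = flat_path,
       truth_tsv = truth_path, truth = truth)
}

.medline_article <- function(pmid, text) {
  c("  <PubmedArticle>",
    "    <MedlineCitation>",
    sprintf("      <PMID>%d</PMID>", pmid),
    "      <Article>",
    "        <ArticleTitle>Synthetic record</ArticleTitle>",
    "        <Abstract>",
    sprintf("          <AbstractText>%s</AbstractText>", text),
    "        </Abstract>",
    "      </Article>",
    "    </MedlineCitation>",
    "  </PubmedArticle>")
}
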