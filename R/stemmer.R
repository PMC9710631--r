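#' Biomedical token stemming
#'
#' A wrapper around the Snowball English (Porter2) stemming algorithm that
#' preserves biomedical specificity.  Three modifications are layered on
#' top of the base algorithm:
#'
#' 1. **Protected abbreviations.** Tokens recognised by the protection
#'    predicate (by default: at least two characters, all upper-case
#'    letters or digits, e.g. `"SARS"`, `"ACE2"`) are returned unchanged.
#' 2. **Case preservation.** For all other tokens the first character is
#'    converted to upper case; no other character changes case in either
#'    direction.  The base algorithm is applied to a lower-cased copy to
#'    decide *what* to excise, and the excision boundary is then applied
#'    to the original-case token, so internal capitals survive.
#' 3. **Protected suffix regions.** Suffix excision never removes or cuts
#'    into a terminal `-ase`, `-ose`, `-ine` or `-sis` region: when the
#'    base excision would reach past the end of such a region, excision
#'    stops at the region's end (a plural `-s` after `-ase` is removed,
#'    the `-ase` itself is kept).
#'
#' Stemming is applied to a fixed point, so the transform is idempotent:
#' `stem_word(stem_word(w))` equals `stem_word(w)` for every token.
#' Tokens containing non-ASCII characters (e.g. Greek letters) and
#' all-digit tokens pass through unchanged apart from first-letter
#' capitalisation of ASCII letters.
#'
#' @param word A single whitespace-free token.
#' @param protected_suffixes Character vector of terminal regions that
#'   excision must not cut into (case-insensitive).
#' @param is_protected Predicate `function(word) -> logical(1)` deciding
#'   whether a token is a protected abbreviation.
#' @return The stemmed token (a single string).
#' @examples
#' stem_word("SARS")      # "SARS"   (protected abbreviation)
#' stem_word("kinases")   # "Kinase" (plural removed, -ase preserved)
#' stem_word("binding")   # "Bind"
#' @seealso [stem_phrase()] for whole phrases, [is_protected_token()] for
#'   the default protection predicate.
#' @export
stem_word <- function(word,
                      protected_suffixes = c("ase", "ose", "ine", "sis"),
                      is_protected = is_protected_token) {
  if (!is.character(word) || length(word) != 1L || is.na(word)) {
    stop("`word` must be a single character string")
  }
  if (!nzchar(word) || grepl("\\s", word)) {
    stop("invalid token: must be a non-empty, whitespace-free string")
  }
  if (is_protected(word)) return(word)
  # non-ASCII tokens (Greek letters etc.) pass through
  if (grepl("[^\\x01-\\x7f]", word, perl = TRUE)) return(word)

  cur <- word
  for (iter in 1:10) {
    nxt <- .stem_word_once(cur, protected_suffixes)
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  cur
}

.stem_word_once <- function(word, protected_suffixes) {
  low <- tolower(word)
  stem_low <- porter2_stem(low)

  # restore case: keep the original spelling over the common prefix,
  # capitalising the first letter; algorithm-introduced characters
  # (e.g. the -e of "hoping" -> "hope") are appended in lower case
  k <- .common_prefix_len(low, stem_low)
  out <- paste0(substr(word, 1L, k), substring(stem_low, k + 1L))

  # protected terminal regions: if excision cut into the rightmost
  # -ase/-ose/-ine/-sis region, stop excision at the region's end
  if (length(protected_suffixes)) {
    pat <- paste0("(", paste(protected_suffixes, collapse = "|"), ")")
    m <- gregexpr(pat, low, perl = TRUE)[[1L]]
    if (m[1L] != -1L) {
      ends <- m + attr(m, "match.length") - 1L
      e <- max(ends)
      if (k < e) out <- substr(word, 1L, e)
    }
  }

  first <- substr(out, 1L, 1L)
  paste0(toupper(first), substring(out, 2L))
}

.common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(substr(a, 1L, n), "", fixed = TRUE)[[1L]]
  bv <- strsplit(substr(b, 1L, n), "", fixed = TRUE)[[1L]]
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}

#' Default protected-abbreviation predicate
#'
#' A token is protected when it has at least two characters, all of which
#' are upper-case ASCII letters or digits.  Mixed-case tokens such as
#' `"CoV"` are not protected (their internal capitals still survive
#' stemming through the case-preservation rule).
#'
#' @param word A single non-empty token.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_protected_token("SARS") # TRUE
#' is_protected_token("ACE2") # TRUE
#' is_protected_token("CoV")  # FALSE
#' @export
is_protected_token <- function(word) {
  nchar(word) >= 2L && grepl("^[A-Z0-9]+$", word)
}

#' Tokenize and stem a phrase
#'
#' Splits text on any character that is not a letter or digit (hyphens
#' split, so hyphen-variant spellings match) and applies [stem_word()] to
#' each token.
#'
#' @param phrase Arbitrary text (a single string).
#' @inheritParams stem_word
#' @return Character vector of stems, in order; `character(0)` for empty
#'   input.
#' @examples
#' stem_phrase("angiotensin-converting enzyme 2")
#' @export
stem_phrase <- function(phrase,
                        protected_suffixes = c("ase", "ose", "ine", "sis"),
                        is_protected = is_protected_token) {
  if (!is.character(phrase) || length(phrase) != 1L || is.na(phrase)) {
    stop("`phrase` must be a single character string")
  }
  toks <- tokenize_text(phrase)
  if (!length(toks)) return(character(0))
  stem_tokens(toks, protected_suffixes = protected_suffixes,
              is_protected = is_protected)
}

#' Split text into alphanumeric tokens
#'
#' @param text A single string.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize_text <- function(text) {
  toks <- strsplit(text, "[^\\p{L}\\p{N}]+", perl = TRUE)[[1L]]
  toks[nzchar(toks)]
}

#' Stem a vector of tokens
#'
#' Vectorised, cached version of [stem_word()]: each distinct surface
#' form is stemmed once.
#'
#' @param tokens Character vector of whitespace-free tokens.
#' @inheritParams stem_word
#' @return Character vector of stems, same length as `tokens`.
#' @export
stem_tokens <- function(tokens,
                        protected_suffixes = c("ase", "ose", "ine", "sis"),
                        is_protected = is_protected_token) {
  if (!length(tokens)) return(character(0))
  use_cache <- missing(protected_suffixes) && missing(is_protected)
  u <- unique(tokens)
  if (use_cache) {
    stems <- character(length(u))
    for (i in seq_along(u)) {
      hit <- .stem_cache[[u[i]]]
      if (is.null(hit)) {
        hit <- stem_word(u[i])
        assign(u[i], hit, envir = .stem_cache)
      }
      stems[i] <- hit
    }
  } else {
    stems <- vapply(u, stem_word, character(1L),
                    protected_suffixes = protected_suffixes,
                    is_protected = is_protected, USE.NAMES = FALSE)
  }
  stems[match(tokens, u)]
}

# process-wide memo for default-configuration stems
.stem_cache <- new.env(parent = emptyenv())
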