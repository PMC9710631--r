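# Snowball English (Porter2) stemming engine.
#
# Implemented from the published algorithm description (regions R1/R2,
# steps 0-5, exceptional forms).  Operates on a single lowercase ASCII
# token; the biomedical wrapper in stemmer.R handles case preservation,
# protected abbreviations and protected suffix regions.  No stemming
# library exists in this toolchain, hence the from-scratch engine; it is
# cross-validated against a frozen oracle table in the test suite.

.p2_vowels <- c("a", "e", "i", "o", "u", "y")
.p2_doubles <- c("bb", "dd", "ff", "gg", "mm", "nn", "pp", "rr", "tt")
.p2_li_endings <- c("c", "d", "e", "g", "h", "k", "m", "n", "r", "t")

.p2_exceptions <- c(
  skis = "ski", skies = "sky", dying = "die", lying = "lie", tying = "tie",
  idly = "idl", gently = "gentl", ugly = "ugli", early = "earli",
  only = "onli", singly = "singl",
  sky = "sky", news = "news", howe = "howe", atlas = "atlas",
  cosmos = "cosmos", bias = "bias", andes = "andes"
)

.p2_stopset <- c(
  "inning", "outing", "canning", "herring", "earring",
  "proceed", "exceed", "succeed"
)

# 'ch' is a single character; "Y" is a marked consonant y
.p2_is_vowel <- function(ch) ch %in% .p2_vowels

# index of the first character of R1/R2, or n+1 when the region is null
.p2_region <- function(chs, from) {
  n <- length(chs)
  if (from > n - 1L) return(n + 1L)
  for (k in from:(n - 1L)) {
    if (.p2_is_vowel(chs[k]) && !.p2_is_vowel(chs[k + 1L])) return(k + 2L)
  }
  n + 1L
}

# suffix characters are memoised; element-wise tail comparison avoids
# re-pasting the word at every probe
.p2_sufcache <- new.env(parent = emptyenv())

.p2_sufchars <- function(suf) {
  hit <- .p2_sufcache[[suf]]
  if (is.null(hit)) {
    hit <- strsplit(suf, "", fixed = TRUE)[[1L]]
    assign(suf, hit, envir = .p2_sufcache)
  }
  hit
}

.p2_ends_with <- function(chs, suf) {
  n <- length(chs)
  sc <- .p2_sufchars(suf)
  m <- length(sc)
  if (n < m || chs[n] != sc[m]) return(FALSE)
  if (m == 1L) return(TRUE)
  all(chs[(n - m + 1L):(n - 1L)] == sc[-m])
}

# TRUE when the word ends in a short syllable
.p2_ends_short_syllable <- function(chs) {
  n <- length(chs)
  if (n == 2L) {
    return(.p2_is_vowel(chs[1L]) && !.p2_is_vowel(chs[2L]))
  }
  if (n < 3L) return(FALSE)
  .p2_is_vowel(chs[n - 1L]) &&
    !.p2_is_vowel(chs[n]) && !(chs[n] %in% c("w", "x", "Y")) &&
    !.p2_is_vowel(chs[n - 2L])
}

# Longest-match lookup used by steps 2-4: returns the first (longest)
# suffix in `sufs` that the word ends with, or NA.  `sufs` must be
# ordered by decreasing length.  A last-character pre-filter skips most
# probes.
.p2_longest_suffix <- function(chs, sufs) {
  lc <- chs[length(chs)]
  for (s in sufs) {
    sc <- .p2_sufchars(s)
    if (sc[length(sc)] != lc) next
    if (.p2_ends_with(chs, s)) return(s)
  }
  NA_character_
}

.p2_step2_map <- c(
  ization = "ize", ational = "ate", fulness = "ful", ousness = "ous",
  iveness = "ive",
  tional = "tion", biliti = "ble", lessli = "less",
  entli = "ent", ation = "ate", alism = "al", aliti = "al",
  ousli = "ous", iviti = "ive", fulli = "ful",
  enci = "ence", anci = "ance", abli = "able", izer = "ize",
  ator = "ate", alli = "al",
  bli = "ble", ogi = "og",
  li = ""
)

.p2_step3_map <- c(
  ational = "ate", tional = "tion",
  alize = "al", icate = "ic", iciti = "ic", ative = "",
  ical = "ic", ness = "", ful = ""
)

.p2_step4_sufs <- c(
  "ement",
  "ance", "ence", "able", "ible", "ment",
  "ant", "ent", "ism", "ate", "iti", "ous", "ive", "ize", "ion",
  "al", "er", "ic"
)

# Stem one lowercase token by the Snowball English algorithm.
porter2_stem <- function(word) {
  if (!is.character(word) || length(word) != 1L || is.na(word)) {
    stop("`word` must be a single character string")
  }
  # remove initial apostrophe before anything else
  word <- sub("^'", "", word)
  if (nchar(word) <= 2L) return(word)

  ex <- .p2_exceptions[word]
  if (!is.na(ex)) return(unname(ex))

  chs <- strsplit(word, "", fixed = TRUE)[[1L]]
  n <- length(chs)

  # mark y as consonant Y at word start or after a vowel
  if (chs[1L] == "y") chs[1L] <- "Y"
  if (n >= 2L) {
    for (k in 2:n) {
      if (chs[k] == "y" && .p2_is_vowel(chs[k - 1L])) chs[k] <- "Y"
    }
  }

  # R1, with the special prefixes that pin it past the prefix
  pre <- regexpr("^(gener|commun|arsen)", word)
  r1 <- if (pre > 0L) {
    attr(pre, "match.length") + 1L
  } else {
    .p2_region(chs, 1L)
  }
  r2 <- .p2_region(chs, r1)

  len <- function() length(chs)
  drop_last <- function(k) chs[seq_len(length(chs) - k)]

  # Step 0: longest of 's' / 's / '
  if (.p2_ends_with(chs, "'s'")) chs <- drop_last(3L)
  else if (.p2_ends_with(chs, "'s")) chs <- drop_last(2L)
  else if (.p2_ends_with(chs, "'")) chs <- drop_last(1L)

  # Step 1a
  if (.p2_ends_with(chs, "sses")) {
    chs <- drop_last(2L)
  } else if (.p2_ends_with(chs, "ied") || .p2_ends_with(chs, "ies")) {
    chs <- if (len() > 4L) drop_last(2L) else drop_last(1L)
  } else if (.p2_ends_with(chs, "us") || .p2_ends_with(chs, "ss")) {
    # do nothing
  } else if (.p2_ends_with(chs, "s")) {
    stem_part <- chs[seq_len(len() - 2L)]
    if (any(vapply(stem_part, .p2_is_vowel, logical(1L)))) chs <- drop_last(1L)
  }

  w <- paste(chs, collapse = "")
  if (tolower(w) %in% .p2_stopset) return(tolower(w))

  # Step 1b
  s1b <- .p2_longest_suffix(chs, c("ingly", "eedly", "edly", "ing", "eed", "ed"))
  if (!is.na(s1b)) {
    if (s1b %in% c("eed", "eedly")) {
      if (len() - nchar(s1b) + 1L >= r1) {
        chs <- c(drop_last(nchar(s1b)), "e", "e")
      }
    } else {
      stem_part <- chs[seq_len(len() - nchar(s1b))]
      if (any(vapply(stem_part, .p2_is_vowel, logical(1L)))) {
        chs <- stem_part
        if (.p2_ends_with(chs, "at") || .p2_ends_with(chs, "bl") ||
            .p2_ends_with(chs, "iz")) {
          chs <- c(chs, "e")
        } else if (!is.na(.p2_longest_suffix(chs, .p2_doubles))) {
          chs <- drop_last(1L)
        } else if (.p2_ends_short_syllable(chs) && r1 > len()) {
          chs <- c(chs, "e")
        }
      }
    }
  }

  # Step 1c: y/Y -> i when preceded by a non-vowel that is not the first letter
  if (len() >= 3L && chs[len()] %in% c("y", "Y") &&
      !.p2_is_vowel(chs[len() - 1L])) {
    chs[len()] <- "i"
  }

  # Step 2 (condition: suffix wholly in R1)
  s2 <- .p2_longest_suffix(chs, names(.p2_step2_map))
  if (!is.na(s2) && (len() - nchar(s2) + 1L) >= r1) {
    ok <- TRUE
    if (s2 == "ogi") ok <- len() > 3L && chs[len() - 3L] == "l"
    if (s2 == "li") ok <- len() > 2L && chs[len() - 2L] %in% .p2_li_endings
    if (ok) {
      chs <- c(drop_last(nchar(s2)),
               strsplit(.p2_step2_map[[s2]], "", fixed = TRUE)[[1L]])
    }
  }

  # Step 3 (in R1; "ative" additionally requires R2)
  s3 <- .p2_longest_suffix(chs, names(.p2_step3_map))
  if (!is.na(s3) && (len() - nchar(s3) + 1L) >= r1) {
    ok <- TRUE
    if (s3 == "ative") ok <- (len() - nchar(s3) + 1L) >= r2
    if (ok) {
      chs <- c(drop_last(nchar(s3)),
               strsplit(.p2_step3_map[[s3]], "", fixed = TRUE)[[1L]])
    }
  }

  # Step 4 (in R2)
  s4 <- .p2_longest_suffix(chs, .p2_step4_sufs)
  if (!is.na(s4) && (len() - nchar(s4) + 1L) >= r2) {
    ok <- TRUE
    if (s4 == "ion") {
      ok <- len() > nchar(s4) && chs[len() - nchar(s4)] %in% c("s", "t")
    }
    if (ok) chs <- drop_last(nchar(s4))
  }

  # Step 5
  if (len() >= 1L && chs[len()] == "e") {
    in_r2 <- len() >= r2
    in_r1 <- len() >= r1
    if (in_r2 ||
        (in_r1 && !.p2_ends_short_syllable(chs[seq_len(len() - 1L)]))) {
      chs <- drop_last(1L)
    }
  } else if (len() >= 2L && chs[len()] == "l" && len() >= r2 &&
             chs[len() - 1L] == "l") {
    chs <- drop_last(1L)
  }

  chartr("Y", "y", paste(chs, collapse = ""))
}
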