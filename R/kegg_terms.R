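#' Parse KEGG flat-file records
#'
#' Reads the KEGG flat-file dialect: records separated by `///`, fields
#' keyed by a leading keyword (`ENTRY`, `NAME`, `DEFINITION`, ...) with
#' continuation lines indented.  Only the ENTRY identifier and the NAME
#' and DEFINITION fields are retained; multi-line fields are joined with
#' a single space.
#'
#' @param path Path to a flat file, or a character vector of lines when
#'   `text = TRUE`.
#' @param text If `TRUE`, `path` is interpreted as the lines themselves.
#' @return A data.frame with columns `code`, `kind`, `name`, `definition`
#'   (one row per record that has an ENTRY line; records without one are
#'   skipped with a warning).
#' @examples
#' rec <- parse_kegg_flatfile(c(
#'   "ENTRY       D11472                      Drug",
#'   "NAME        Remdesivir (JAN/USAN);",
#'   "            Veklury (TN)",
#'   "///"), text = TRUE)
#' rec$name
#' @export
parse_kegg_flatfile <- function(path, text = FALSE) {
  lines <- if (text) path else readLines(path, warn = FALSE)
  recs <- list()
  cur <- character(0)
  flush_record <- function(block) {
    if (!length(block)) return(NULL)
    keys <- sub("^([A-Z_]+).*$", "\\1", block)
    is_key <- grepl("^[A-Z_]+", block)
    # assign each continuation line to the last seen keyword
    field <- character(length(block))
    last <- NA_character_
    for (i in seq_along(block)) {
      if (is_key[i]) last <- keys[i]
      field[i] <- last
    }
    if (!any(field == "ENTRY", na.rm = TRUE)) {
      warning("skipping KEGG record without ENTRY line", call. = FALSE)
      return(NULL)
    }
    get_field <- function(key) {
      sel <- which(field == key)
      if (!length(sel)) return("")
      vals <- sub("^[A-Z_]+\\s*", "", block[sel[1L]])
      if (length(sel) > 1L) {
        vals <- c(vals, trimws(block[sel[-1L]]))
      }
      trimws(paste(vals, collapse = " "))
    }
    entry <- get_field("ENTRY")
    code <- strsplit(entry, "\\s+")[[1L]][1L]
    data.frame(code = code,
               kind = kegg_code_kind(code),
               name = get_field("NAME"),
               definition = get_field("DEFINITION"),
               stringsAsFactors = FALSE)
  }
  for (ln in lines) {
    if (grepl("^///", ln)) {
      r <- flush_record(cur)
      if (!is.null(r)) recs[[length(recs) + 1L]] <- r
      cur <- character(0)
    } else if (nzchar(trimws(ln))) {
      cur <- c(cur, ln)
    }
  }
  if (length(cur)) {
    stop("truncated KEGG flat file: record without terminating '///'")
  }
  if (!length(recs)) {
    return(data.frame(code = character(0), kind = character(0),
                      name = character(0), definition = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, recs)
}

#' Kind of a KEGG code
#'
#' Derives the code kind (D drug, H disease, C compound, K ortholog,
#' EC enzyme, G glycan, R reaction, DG drug group, E crude drug) from the
#' identifier's prefix.
#'
#' @param code Character vector of KEGG identifiers.
#' @return Character vector of kinds; `NA` where the prefix is not
#'   recognised.
#' @examples
#' kegg_code_kind(c("D11472", "H02398", "EC1.1.1.1", "DG01234"))
#' @export
kegg_code_kind <- function(code) {
  kind <- rep(NA_character_, length(code))
  kind[grepl("^EC[0-9.]", code)] <- "EC"
  kind[grepl("^DG[0-9]", code)] <- "DG"
  for (k in c("D", "H", "C", "K", "G", "R", "E")) {
    sel <- is.na(kind) & grepl(paste0("^", k, "[0-9]"), code)
    kind[sel] <- k
  }
  kind
}

#' Default stop-words for KEGG term extraction
#'
#' Frequent salt/form words in KEGG NAME/DEFINITION fields that carry no
#' referential specificity on their own.
#'
#' @return Character vector of lower-case stop-words.
#' @export
kegg_stop_words <- function() {
  c("hydrochloride", "hydrate", "sodium", "monohydrate", "dihydrate",
    "sulfate", "sulphate", "phosphate", "mesilate", "mesylate",
    "maleate", "tartrate", "citrate", "acetate", "potassium", "calcium")
}

#' Default annotation tags dropped from KEGG name fields
#' @return Character vector of registry-label tags.
#' @export
kegg_annotation_tags <- function() {
  c("JAN", "USAN", "INN", "TN", "USP", "JP17", "JP18", "NF", "BAN", "DCF")
}

#' Default leading configuration markers stripped from terms
#' @return Character vector of stereochemistry/configuration prefixes.
#' @export
kegg_config_markers <- function() {
  c("D-", "L-", "DL-", "(R)-", "(S)-", "(+)-", "(-)-", "(−)-",
    "alpha-", "beta-", "cis-", "trans-")
}

#' Extract search terms from KEGG NAME/DEFINITION fields
#'
#' Splits the concatenated fields at punctuation (`;`, `,`, `:`) and
#' parentheses, discards fragments that are empty, pure annotation tags
#' (JAN, USAN, TN, ...) or stop-words, and strips leading configuration
#' markers (`D-`, `(S)-`, `alpha-`, ...).  Every transformation is
#' additive: both the transformed fragment and the fragment it was
#' derived from are retained, so the abstract search misses nothing.
#'
#' @param name_field,definition_field Field strings as returned by
#'   [parse_kegg_flatfile()].
#' @param stop_words Words removed when they are a trailing token or a
#'   whole fragment (lower-case comparison).
#' @param annotation_tags Registry labels discarded as fragments.
#' @param config_markers Leading markers stripped (additively).
#' @return Character vector of unique raw terms.
#' @examples
#' extract_terms("Veklury (TN), Remdesivir (JAN/USAN)", "")
#' extract_terms("Chloroquine hydrochloride (USP)", "")
#' @export
extract_terms <- function(name_field, definition_field = "",
                          stop_words = kegg_stop_words(),
                          annotation_tags = kegg_annotation_tags(),
                          config_markers = kegg_config_markers()) {
  full <- paste(name_field, definition_field, sep = "; ")
  frags <- strsplit(full, "[;,:()]+")[[1L]]
  frags <- trimws(frags)
  frags <- frags[nzchar(frags)]
  stop_low <- tolower(stop_words)
  is_tag <- function(x) {
    # pure annotation fragments, possibly slash-joined: "JAN/USAN"
    parts <- strsplit(x, "/", fixed = TRUE)[[1L]]
    all(toupper(trimws(parts)) %in% toupper(annotation_tags))
  }
  out <- character(0)
  for (fr in frags) {
    if (is_tag(fr)) next
    if (tolower(fr) %in% stop_low) next
    variants <- fr
    # strip trailing stop-words (salt/form words), additively
    toks <- strsplit(fr, "\\s+")[[1L]]
    while (length(toks) > 1L && tolower(toks[length(toks)]) %in% stop_low) {
      toks <- toks[-length(toks)]
      variants <- c(variants, paste(toks, collapse = " "))
    }
    # strip leading configuration markers, additively
    for (v in variants) {
      for (mk in config_markers) {
        if (startsWith(v, mk) && nchar(v) > nchar(mk)) {
          variants <- c(variants, substring(v, nchar(mk) + 1L))
        }
      }
    }
    out <- c(out, variants)
  }
  unique(out)
}

#' Build a term dictionary from parsed KEGG records
#'
#' Maps each KEGG code to its extracted search terms, each paired with
#' its stemmed token sequence.  Duplicate codes are merged by term-set
#' union; terms whose stemmed sequence is empty, or that are shorter than
#' `min_chars` after stemming (and not protected abbreviations), are
#' dropped.
#'
#' @param records data.frame from [parse_kegg_flatfile()].
#' @param min_chars Minimum length of a single-token stemmed term; short
#'   terms match ubiquitously and are dropped by default.
#' @inheritParams extract_terms
#' @return A `term_dictionary`: data.frame with columns `code`, `kind`,
#'   `term` (raw), `stems` (tokens joined by `"|"`), of class
#'   `term_dictionary`.
#' @examples
#' rec <- data.frame(code = "D11472", kind = "D",
#'                   name = "Remdesivir (JAN/USAN); Veklury (TN)",
#'                   definition = "")
#' build_dictionary(rec)
#' @export
build_dictionary <- function(records,
                             stop_words = kegg_stop_words(),
                             annotation_tags = kegg_annotation_tags(),
                             config_markers = kegg_config_markers(),
                             min_chars = 3L) {
  rows <- list()
  for (i in seq_len(nrow(records))) {
    terms <- extract_terms(records$name[i], records$definition[i],
                           stop_words = stop_words,
                           annotation_tags = annotation_tags,
                           config_markers = config_markers)
    for (tm in terms) {
      st <- stem_phrase(tm)
      if (!length(st)) {
        warning(sprintf("dropping term with empty stem: '%s' (%s)",
                        tm, records$code[i]), call. = FALSE)
        next
      }
      if (length(st) == 1L && nchar(st) < min_chars &&
          !is_protected_token(tm)) {
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        code = records$code[i], kind = records$kind[i], term = tm,
        stems = paste(st, collapse = "|"), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(code = character(0), kind = character(0),
               term = character(0), stems = character(0),
               stringsAsFactors = FALSE)
  }
  out <- unique(out)
  out <- out[order(out$code, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("term_dictionary", "data.frame")
  out
}

#' @export
print.term_dictionary <- function(x, ...) {
  cat(sprintf("<term_dictionary> %d terms across %d KEGG codes\n",
              nrow(x), length(unique(x$code))))
  if (nrow(x)) print.data.frame(utils::head(x, 10L), ...)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Serialize / reload a term dictionary
#'
#' `write_dictionary()` writes TSV (columns code, kind, term, stems with
#' `"|"` token separator) or JSON; `read_dictionary()` reverses it
#' losslessly.
#'
#' @param dictionary A `term_dictionary`.
#' @param path Output file; format chosen by extension (`.json` for
#'   JSON, otherwise TSV).
#' @return `read_dictionary()` returns a `term_dictionary`;
#'   `write_dictionary()` returns `path` invisibly.
#' @export
write_dictionary <- function(dictionary, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(unclass(dictionary),
                                       stringsAsFactors = FALSE),
                         path, dataframe = "rows")
  } else {
    utils::write.table(dictionary, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                  stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, colClasses = "character", quote = "",
                      fileEncoding = "UTF-8")
  }
  df <- df[order(df$code, df$term), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("term_dictionary", "data.frame")
  df
}

# terms of one code as a list of stem-token vectors, named by stem key
.dict_code_terms <- function(dictionary, code) {
  sel <- dictionary$code == code
  if (!any(sel)) stop(sprintf("code '%s' not present in dictionary", code))
  keys <- unique(dictionary$stems[sel])
  stats::setNames(strsplit(keys, "|", fixed = TRUE), keys)
}
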