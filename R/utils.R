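#' @keywords internal
"_PACKAGE"

## Shared string helpers. Matching keys are trimmed, whitespace-squished,
## case-folded and diacritic-folded so that "Universite de Montreal"
## resolves to the canonical (diacritic-bearing) name.

squish <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Strip diacritics from a character vector
#'
#' Canonical institution names keep their diacritics; matching is done on a
#' diacritic-folded key so ASCII-mangled variants still resolve.
#'
#' @param x character vector
#' @return `x` with accented letters replaced by their base letters
#' @keywords internal
strip_diacritics <- function(x) {
  # chartr covers the common Latin set; iconv transliteration is locale
  # dependent (it may insert apostrophes), so it is only a fallback and its
  # leftover markers are removed
  from <- "àáâãäåèéêëìíîïòóôõöøùúûüçñýÿšžÀÁÂÃÄÅÈÉÊËÌÍÎÏÒÓÔÕÖØÙÚÛÜÇÑÝŠŽ"
  to   <- "aaaaaaeeeeiiiiooooooouuuucnyyszAAAAAAEEEEIIIIOOOOOOUUUUCNYSZ"
  out <- chartr(from, to, x)
  ascii <- !is.na(out) & out == suppressWarnings(
    iconv(out, from = "UTF-8", to = "ASCII", sub = "?"))
  if (any(!ascii)) {
    tr <- suppressWarnings(iconv(out[!ascii], from = "UTF-8",
                                 to = "ASCII//TRANSLIT"))
    tr <- gsub("['`^\"~]", "", tr)
    out[!ascii] <- ifelse(is.na(tr), out[!ascii], tr)
  }
  out
}

## Key used for all table lookups.
fold_key <- function(x) {
  x <- squish(x)
  x <- strip_diacritics(x)
  tolower(x)
}

## Title-case a free-text string (used for pass-through canonicals).
title_case <- function(x) {
  vapply(x, function(s) {
    words <- strsplit(tolower(s), " ", fixed = TRUE)[[1]]
    keep_lower <- c("of", "de", "the", "and", "for", "la", "du", "des", "in")
    words <- vapply(seq_along(words), function(i) {
      w <- words[i]
      if (i > 1 && w %in% keep_lower) return(w)
      paste0(toupper(substring(w, 1, 1)), substring(w, 2))
    }, character(1))
    paste(words, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

## Round half away from zero (public-table integer display).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

is_missing_chr <- function(x) {
  is.null(x) || length(x) == 0 || is.na(x) || !nzchar(trimws(x))
}

#' Sentinel label for unresolvable affiliations
#'
#' Affiliation entries that are absent, vague or unresolvable are credited to
#' a nominal institution named `"Missing"`, which participates in scoring and
#' ranking like any real institution so the cost of incomplete affiliation
#' data is visible in the league table.
#' @return the string `"Missing"`
#' @export
missing_label <- function() "Missing"

## Derive a sub-seed from a master seed; kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 10007) %% 2147483629)
}
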