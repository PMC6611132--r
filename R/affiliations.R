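## Normalization of free-text affiliation strings to canonical institutions.
##
## A keyed lookup (exact names, acronyms, institute consolidations) backed by
## a rule cascade that strips departments, locations and unnecessary
## prefixes. Vague strings ("Faculty of Health") become Missing. All lookups
## use a diacritic-folded, case-folded key so canonical names can keep their
## diacritics while ASCII variants still resolve.

.department_keywords <- paste0(
  "\\b(department|faculty|school|centre|center|division|unit|laboratory|",
  "institute of (?!technology))\\b"
)

#' Build a mapping table for affiliation normalization
#'
#' @param exact named character vector: raw string -> canonical name (exact
#'   matches, including alternate/dual names)
#' @param acronyms named character vector: acronym -> canonical name
#' @param consolidations named character vector: institute name -> parent
#'   university (depth-1, e.g. a hospital consolidated into its university)
#' @param location_exceptions character vector of base names whose trailing
#'   location must be retained to disambiguate (e.g. two universities of the
#'   same name in different countries)
#' @param vague character vector of uninformative strings mapped to
#'   `Missing`
#' @return object of class `mapping_table`
#' @export
mapping_table <- function(exact = character(0), acronyms = character(0),
                          consolidations = character(0),
                          location_exceptions = character(0),
                          vague = character(0)) {
  as_map <- function(x, what) {
    if (length(x) == 0) return(stats::setNames(character(0), character(0)))
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("'", what, "' entries must be a named character vector")
    stats::setNames(as.character(x), fold_key(names(x)))
  }
  tab <- list(
    exact = as_map(exact, "exact"),
    acronyms = as_map(acronyms, "acronyms"),
    consolidations = as_map(consolidations, "consolidations"),
    location_exceptions = fold_key(location_exceptions),
    vague = fold_key(vague)
  )
  keys <- c(names(tab$exact), names(tab$acronyms), names(tab$consolidations))
  vals <- c(tab$exact, tab$acronyms, tab$consolidations)
  clash <- tapply(vals, keys, function(v) length(unique(v)) > 1)
  if (any(clash))
    stop("raw string maps to two canonicals: ",
         paste(names(clash)[clash], collapse = ", "))
  # consolidation graph must be depth 1: no parent is itself consolidated
  if (any(fold_key(tab$consolidations) %in% names(tab$consolidations)))
    stop("consolidation graph must have depth 1")
  structure(tab, class = "mapping_table")
}

#' Read a mapping table from YAML or CSV
#'
#' YAML files use sections `exact`, `acronyms`, `consolidations` (mappings of
#' raw string to canonical), `location_exceptions` and `vague` (lists). CSV
#' files use columns `section`, `raw_string`, `canonical_name`.
#'
#' @param path file path
#' @return a [mapping_table()]
#' @export
read_mapping_table <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    as_vec <- function(x) {
      if (is.null(x)) return(character(0))
      stats::setNames(unlist(x, use.names = FALSE), names(x))
    }
    mapping_table(
      exact = as_vec(y$exact), acronyms = as_vec(y$acronyms),
      consolidations = as_vec(y$consolidations),
      location_exceptions = unlist(y$location_exceptions) %||% character(0),
      vague = unlist(y$vague) %||% character(0)
    )
  } else {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    get <- function(sec) {
      s <- d[d$section == sec, ]
      stats::setNames(s$canonical_name, s$raw_string)
    }
    mapping_table(
      exact = get("exact"), acronyms = get("acronyms"),
      consolidations = get("consolidations"),
      location_exceptions = d$raw_string[d$section == "location_exceptions"],
      vague = d$raw_string[d$section == "vague"]
    )
  }
}

#' Write a mapping table to CSV
#'
#' @param table a [mapping_table()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_mapping_table <- function(table, path) {
  stopifnot(inherits(table, "mapping_table"))
  sec <- function(section, raw, canonical = rep(NA_character_, length(raw))) {
    if (length(raw) == 0) return(NULL)
    data.frame(section = section, raw_string = raw,
               canonical_name = canonical, stringsAsFactors = FALSE)
  }
  rows <- rbind(
    sec("exact", names(table$exact), unname(table$exact)),
    sec("acronyms", names(table$acronyms), unname(table$acronyms)),
    sec("consolidations", names(table$consolidations),
        unname(table$consolidations)),
    sec("location_exceptions", table$location_exceptions),
    sec("vague", table$vague)
  )
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

lookup_key <- function(key, table) {
  if (key %in% names(table$exact)) return(unname(table$exact[key]))
  if (key %in% names(table$consolidations))
    return(unname(table$consolidations[key]))
  if (key %in% names(table$acronyms)) return(unname(table$acronyms[key]))
  NA_character_
}

#' Normalize one affiliation string
#'
#' Applies the cleaning cascade in a fixed order: exact match, institute
#' consolidation, acronym expansion, unnecessary-prefix stripping ("The "),
#' department-segment stripping, location-suffix stripping (honouring the
#' exception list), vague check, then Missing. Unmatched non-vague strings
#' pass through as their own (title-cased) canonical so unmapped
#' institutions are visibly split rather than silently deleted. The result
#' is idempotent: normalizing a canonical output returns it unchanged.
#'
#' @param raw raw affiliation string, or `NA` for a missing entry
#' @param country country of the affiliation entry, or `NA`
#' @param table a [mapping_table()]
#' @return list with `raw`, `canonical` (canonical name or `"Missing"`),
#'   `country` (or `"Missing"`), `rule_applied`
#' @examples
#' tab <- mapping_table(vague = "Faculty of Health")
#' normalize_affiliation("Mansoura University, Urology and Nephrology Center",
#'                       "Egypt", tab)$canonical  # "Mansoura University"
#' normalize_affiliation("Faculty of Health", "Australia", tab)$canonical
#' @export
normalize_affiliation <- function(raw, country = NA_character_,
                                  table = mapping_table()) {
  stopifnot(inherits(table, "mapping_table"))
  country_out <- if (is_missing_chr(country)) missing_label()
                 else squish(country)
  res <- function(canonical, rule) {
    list(raw = if (is_missing_chr(raw)) NA_character_ else raw,
         canonical = canonical,
         country = if (identical(canonical, missing_label()) &&
                       is_missing_chr(raw) && is_missing_chr(country))
           missing_label() else country_out,
         rule_applied = rule)
  }
  if (is_missing_chr(raw)) return(res(missing_label(), "missing"))

  key <- fold_key(raw)
  hit <- lookup_key(key, table)
  if (!is.na(hit)) {
    rule <- if (key %in% names(table$consolidations)) "consolidation"
            else if (key %in% names(table$acronyms)) "acronym"
            else "exact"
    return(res(hit, rule))
  }
  if (key %in% table$vague) return(res(missing_label(), "vague"))

  # segment cascade: split on commas; a segment that resolves on its own
  # (after prefix stripping) wins before any heuristic stripping
  segments <- squish(strsplit(raw, ",", fixed = TRUE)[[1]])
  segments <- segments[nzchar(segments)]
  for (s in sub("^[Tt]he ", "", segments)) {
    k <- fold_key(s)
    hit_s <- lookup_key(k, table)
    if (!is.na(hit_s)) {
      rule <- if (k %in% names(table$consolidations)) "consolidation"
              else if (k %in% names(table$acronyms)) "acronym"
              else if (length(segments) > 1) "location" else "prefix"
      return(res(hit_s, rule))
    }
  }
  kept <- segments[!grepl(.department_keywords, fold_key(segments),
                          perl = TRUE)]
  dropped_dept <- length(kept) < length(segments)
  if (length(kept) == 0) return(res(missing_label(), "department"))

  candidate <- kept[1]
  rule <- if (dropped_dept) "department" else "none"
  stripped <- sub("^[Tt]he ", "", candidate)
  if (!identical(stripped, candidate)) {
    candidate <- stripped
    if (rule == "none") rule <- "prefix"
  }

  # retain the location segment for listed exceptions, else strip it
  if (length(kept) > 1) {
    if (fold_key(candidate) %in% table$location_exceptions) {
      candidate <- paste(candidate, kept[2], sep = ", ")
    } else if (rule == "none") {
      rule <- "location"
    }
  }

  key2 <- fold_key(candidate)
  hit2 <- lookup_key(key2, table)
  if (!is.na(hit2)) return(res(hit2, rule))
  if (key2 %in% table$vague) return(res(missing_label(), "vague"))
  if (grepl(.department_keywords, key2, perl = TRUE))
    return(res(missing_label(), "vague"))
  res(title_case(candidate), if (rule == "none") "passthrough" else rule)
}

#' Normalize every affiliation in a corpus
#'
#' @param papers list of paper records (as produced by [generate_corpus()]
#'   or [read_corpus()]; typically already filtered by [filter_corpus()])
#' @param table a [mapping_table()]
#' @return the papers, each with `affiliations_norm`: a data.frame of
#'   `raw`, `canonical`, `country`, `rule_applied`, one row per entry
#' @export
normalize_corpus <- function(papers, table) {
  lapply(papers, function(p) {
    if (length(p$affiliations) == 0) {
      p$affiliations_norm <- data.frame(
        raw = character(0), canonical = character(0), country = character(0),
        rule_applied = character(0), stringsAsFactors = FALSE)
      return(p)
    }
    rows <- lapply(p$affiliations, function(a)
      normalize_affiliation(a$raw, a$country %||% NA_character_, table))
    p$affiliations_norm <- data.frame(
      raw = vapply(rows, function(r)
        if (is.na(r$raw)) NA_character_ else r$raw, character(1)),
      canonical = vapply(rows, `[[`, character(1), "canonical"),
      country = vapply(rows, `[[`, character(1), "country"),
      rule_applied = vapply(rows, `[[`, character(1), "rule_applied"),
      stringsAsFactors = FALSE
    )
    p
  })
}

#' Missing-affiliation accounting by country
#'
#' One row per country, plus a nominal `"Missing"` country for entries where
#' both the affiliation and the country were absent. Percent missing is
#' reported to one decimal place and rows are ordered by missing count,
#' descending.
#'
#' @param affiliations data.frame of normalized affiliations (columns
#'   `canonical`, `country`), e.g. from [flatten_affiliations()]
#' @return data.frame: `country`, `complete`, `missing`, `percent_missing`
#' @export
missingness_report <- function(affiliations) {
  if (nrow(affiliations) == 0)
    return(data.frame(country = character(0), complete = integer(0),
                      missing = integer(0), percent_missing = numeric(0)))
  is_missing <- affiliations$canonical == missing_label()
  tab <- table(affiliations$country, factor(is_missing, c(FALSE, TRUE)))
  out <- data.frame(
    country = rownames(tab),
    complete = as.integer(tab[, 1]),
    missing = as.integer(tab[, 2]),
    stringsAsFactors = FALSE
  )
  out$percent_missing <- round(100 * out$missing / (out$complete + out$missing),
                               1)
  out[order(-out$missing, out$country), , drop = FALSE]
}

#' Flatten normalized papers to one row per affiliation entry
#'
#' @param papers normalized papers from [normalize_corpus()]
#' @return data.frame: `doi`, `year`, `raw`, `canonical`, `country`,
#'   `rule_applied`
#' @export
flatten_affiliations <- function(papers) {
  pieces <- lapply(papers, function(p) {
    n <- nrow(p$affiliations_norm)
    if (n == 0) return(NULL)
    cbind(data.frame(doi = rep(p$doi %||% NA_character_, n),
                     year = rep(as.integer(p$year), n),
                     stringsAsFactors = FALSE),
          p$affiliations_norm)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(doi = character(0), year = integer(0),
                      raw = character(0), canonical = character(0),
                      country = character(0), rule_applied = character(0))
  rownames(out) <- NULL
  out
}
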