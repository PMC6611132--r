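## Organisational-level fractional counting.
##
## Each paper carries one unit of credit, split over the entries of its
## address list: an institution's credit is its number of entries divided by
## the total entries, so a paper with two affiliations gives 0.5 to each.
## Entries that could not be resolved credit the nominal institution
## "Missing". Scores are the per-year sums of these credits, so the scores
## in a year add up exactly to the number of eligible papers.

#' Fractional credit for one paper's address list
#'
#' @param canonicals character vector of canonical institution names for the
#'   paper's affiliation entries (`"Missing"` for unresolved entries, see
#'   [missing_label()]); an institution listed twice earns double weight. An
#'   empty list credits `"Missing"` with the full unit.
#' @return named numeric vector of credits, summing to exactly 1
#' @examples
#' paper_credits(c("Queensland University of Technology",
#'                 "Ottawa Hospital Research Institute"))  # 0.5 each
#' paper_credits(c("A", "A", "B"))                         # 2/3, 1/3
#' @export
paper_credits <- function(canonicals) {
  if (length(canonicals) == 0)
    return(stats::setNames(1, missing_label()))
  stopifnot(is.character(canonicals), !anyNA(canonicals))
  counts <- table(canonicals)
  stats::setNames(as.numeric(counts) / length(canonicals), names(counts))
}

#' Build the fractional score table
#'
#' Sums per-paper fractional credits by institution and year. Institutions
#' never observed in a year are absent rather than zero-filled. The sum of
#' scores in a year equals that year's paper count.
#'
#' @param papers normalized papers from [normalize_corpus()]
#' @return object of class `score_table`: data.frame with `institution`,
#'   `year`, `score`, plus attributes `n_papers` (named per-year paper
#'   counts), `country_scores` (per-country, per-year credit, with
#'   `"Missing"` kept as a nominal country) and `provenance` (per
#'   institution-year, the contributing paper DOIs)
#' @export
build_score_table <- function(papers) {
  if (length(papers) == 0) stop("no papers to score")
  years <- vapply(papers, function(p) as.integer(p$year), integer(1))
  dois <- vapply(papers, function(p)
    if (is_missing_chr(p$doi)) NA_character_ else p$doi, character(1))
  for (y in unique(years)) {
    d <- dois[years == y]
    dup <- unique(d[duplicated(d) & !is.na(d)])
    if (length(dup))
      stop("duplicate DOI within year ", y, ": ", paste(dup, collapse = ", "))
  }

  rows <- vector("list", length(papers))
  for (i in seq_along(papers)) {
    cr <- paper_credits(papers[[i]]$affiliations_norm$canonical)
    rows[[i]] <- data.frame(
      institution = names(cr), year = years[i], credit = as.numeric(cr),
      doi = dois[i], stringsAsFactors = FALSE)
  }
  credits <- do.call(rbind, rows)

  agg <- stats::aggregate(credit ~ institution + year, credits, sum)
  names(agg)[names(agg) == "credit"] <- "score"
  agg <- agg[order(agg$year, -agg$score, agg$institution), , drop = FALSE]
  rownames(agg) <- NULL

  # country credit follows each entry's own country field
  crows <- lapply(papers, function(p) {
    af <- p$affiliations_norm
    n <- nrow(af)
    if (n == 0)
      return(data.frame(country = missing_label(), year = as.integer(p$year),
                        credit = 1, stringsAsFactors = FALSE))
    data.frame(country = af$country, year = as.integer(p$year),
               credit = rep(1 / n, n), stringsAsFactors = FALSE)
  })
  country <- stats::aggregate(credit ~ country + year, do.call(rbind, crows),
                              sum)
  names(country)[names(country) == "credit"] <- "score"

  prov <- tapply(credits$doi, paste(credits$institution, credits$year),
                 function(d) unique(d[!is.na(d)]), simplify = FALSE)

  structure(agg, class = c("score_table", "data.frame"),
            n_papers = table(years),
            country_scores = country,
            provenance = prov)
}

#' @export
print.score_table <- function(x, n = 10, ...) {
  np <- attr(x, "n_papers")
  cat("Fractional score table:", nrow(x), "institution-years;",
      "papers per year:",
      paste(sprintf("%s=%d", names(np), as.integer(np)), collapse = ", "),
      "\n")
  print.data.frame(utils::head(as.data.frame(x), n), ...)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more rows\n")
  invisible(x)
}

#' Aggregate scores to countries and regions
#'
#' Sums affiliation-entry credit by country and region per year. The nominal
#' `"Missing"` country is excluded from both aggregates; countries absent
#' from the region mapping fall into an `"Unmapped"` region with a warning.
#'
#' @param table a [build_score_table()] result
#' @param regions data.frame with columns `country`, `region` (default
#'   [default_region_table()])
#' @return list with data.frames `country` and `region` (columns
#'   `country`/`region`, `year`, `score`), ordered by year then descending
#'   score
#' @export
aggregate_geography <- function(table, regions = default_region_table()) {
  stopifnot(inherits(table, "score_table"))
  country <- attr(table, "country_scores")
  country <- country[country$country != missing_label(), , drop = FALSE]
  unknown <- setdiff(unique(country$country), regions$country)
  if (length(unknown))
    warning("countries not in region mapping, assigned to 'Unmapped': ",
            paste(unknown, collapse = ", "))
  country$region <- regions$region[match(country$country, regions$country)]
  country$region[is.na(country$region)] <- "Unmapped"

  region <- stats::aggregate(score ~ region + year, country, sum)
  country <- country[order(country$year, -country$score, country$country),
                     c("country", "year", "score")]
  region <- region[order(region$year, -region$score, region$region), ,
                   drop = FALSE]
  rownames(country) <- rownames(region) <- NULL
  list(country = country, region = region)
}
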