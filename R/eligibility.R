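## Eligibility: which papers enter the league table.
##
## Five gates: cites a registered guideline paper; publication type Article
## or Review; DOI present; publication year in scope; title contains a
## design-specific phrase (no restriction for STROBE). A paper citing
## several guideline families is counted once, under a fixed family
## precedence.

.families <- c("CONSORT", "PRISMA", "STROBE")

## Hyphenated phrases are accepted with hyphen, space or concatenated.
hyphen_variants <- function(phrase) {
  if (!grepl("-", phrase, fixed = TRUE)) return(phrase)
  c(phrase,
    gsub("-", " ", phrase, fixed = TRUE),
    gsub("-", "", phrase, fixed = TRUE))
}

.title_phrases <- list(
  CONSORT = c("randomised trial", "randomized trial"),
  PRISMA = unlist(lapply(
    c("systematic search", "systematic review", "systematic literature review",
      "scoping review", "meta-analyses", "meta-analysis"),
    hyphen_variants), use.names = FALSE)
)

#' Default guideline-paper registry
#'
#' A configurable registry mapping guideline-paper identifiers to their
#' reporting-guideline family (CONSORT for randomised trials, PRISMA for
#' systematic reviews and meta-analyses, STROBE for observational studies).
#' Each family lists its original statement papers and updates; citing any
#' of them counts as citing the family.
#'
#' @return data.frame with columns `id`, `family`, `label`
#' @export
default_registry <- function() {
  data.frame(
    id = c("CONSORT-2001", "CONSORT-2010",
           "PRISMA-2009", "PRISMA-2015",
           "STROBE-2007", "STROBE-2014"),
    family = c("CONSORT", "CONSORT", "PRISMA", "PRISMA", "STROBE", "STROBE"),
    label = c("CONSORT statement 2001", "CONSORT 2010 update",
              "PRISMA statement 2009", "PRISMA-P 2015",
              "STROBE statement 2007", "STROBE update"),
    stringsAsFactors = FALSE
  )
}

#' Read a guideline registry from CSV or YAML
#'
#' @param path file with columns/keys `id`, `family` (and optionally `label`)
#' @return registry data.frame as from [default_registry()]
#' @export
read_registry <- function(path) {
  reg <- if (grepl("\\.ya?ml$", path)) {
    do.call(rbind, lapply(yaml::read_yaml(path), function(e)
      data.frame(id = e$id, family = e$family,
                 label = if (is.null(e$label)) NA_character_ else e$label,
                 stringsAsFactors = FALSE)))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  validate_registry(reg)
  reg
}

validate_registry <- function(registry) {
  stopifnot(is.data.frame(registry), all(c("id", "family") %in% names(registry)))
  if (anyDuplicated(registry$id))
    stop("registry identifiers must be unique")
  bad <- setdiff(unique(registry$family), .families)
  if (length(bad))
    stop("unknown guideline family: ", paste(bad, collapse = ", "))
  invisible(registry)
}

#' Does a title pass a family's phrase filter?
#'
#' CONSORT titles must contain "randomised trial", "randomized trial" or the
#' word "RCT"; PRISMA titles must contain one of the systematic-review /
#' meta-analysis phrases (hyphenated, spaced and concatenated variants all
#' accepted); STROBE has no title restriction because observational designs
#' are too varied to enumerate.
#'
#' Matching is case-insensitive substring for multi-word phrases; "RCT" is
#' matched case-insensitively at word boundaries so it cannot fire inside an
#' unrelated word.
#'
#' @param family one of "CONSORT", "PRISMA", "STROBE"
#' @param title paper title (character scalar)
#' @return logical
#' @examples
#' title_matches("PRISMA", "A systematic review of statin trials")  # TRUE
#' title_matches("CONSORT", "Protocol for a cohort study")          # FALSE
#' @export
title_matches <- function(family, title) {
  if (!family %in% .families) stop("unknown guideline family: ", family)
  stopifnot(is.character(title), length(title) == 1, !is.na(title))
  if (family == "STROBE") return(TRUE)
  low <- tolower(title)
  phrases <- .title_phrases[[family]]
  hit <- any(vapply(phrases, function(p) grepl(p, low, fixed = TRUE),
                    logical(1)))
  if (!hit && family == "CONSORT")
    hit <- grepl("\\brct\\b", low)
  hit
}

#' Assess one paper against all eligibility gates
#'
#' Gates are applied in a fixed order and the first failure is recorded as
#' the rejection reason: guideline citation, publication type, DOI, year,
#' then the title filter of the assigned family. When a paper cites papers
#' from several guideline families, exactly one family is assigned using the
#' precedence CONSORT > PRISMA > STROBE, so the paper is counted once.
#'
#' @param paper a paper record (list with `doi`, `year`, `title`, `pub_type`,
#'   `cited_guidelines`, `affiliations`)
#' @param registry guideline registry (see [default_registry()])
#' @param years integer vector of in-scope publication years
#' @return list with `eligible` (logical), `family` (assigned family or
#'   `NA`), `rejection_reason` (`NA` when eligible)
#' @export
assess_paper <- function(paper, registry = default_registry(),
                         years = c(2016L, 2017L)) {
  validate_registry(registry)
  if (nrow(registry) == 0) stop("registry must be non-empty")

  decision <- function(eligible, family = NA_character_,
                       reason = NA_character_) {
    list(eligible = eligible, family = family, rejection_reason = reason)
  }

  cited <- intersect(paper$cited_guidelines, registry$id)
  if (length(cited) == 0)
    return(decision(FALSE, reason = "no_guideline"))
  fams <- unique(registry$family[registry$id %in% cited])
  family <- .families[match(TRUE, .families %in% fams)]  # fixed precedence

  if (!paper$pub_type %in% c("Article", "Review"))
    return(decision(FALSE, reason = "bad_pub_type"))
  if (is_missing_chr(paper$doi))
    return(decision(FALSE, reason = "no_doi"))
  if (!paper$year %in% years)
    return(decision(FALSE, reason = "wrong_year"))
  if (!title_matches(family, paper$title))
    return(decision(FALSE, reason = "title_filter"))
  decision(TRUE, family = family)
}

#' Filter a corpus to eligible papers
#'
#' Applies [assess_paper()] to every record and returns the eligible subset
#' (each record annotated with its assigned `family`) together with a full
#' audit table of decisions.
#'
#' @inheritParams assess_paper
#' @param papers list of paper records
#' @return list with `eligible` (list of paper records) and `decisions`
#'   (data.frame: `doi`, `year`, `eligible`, `family`, `rejection_reason`)
#' @export
filter_corpus <- function(papers, registry = default_registry(),
                          years = c(2016L, 2017L)) {
  decisions <- lapply(papers, assess_paper, registry = registry, years = years)
  audit <- data.frame(
    doi = vapply(papers, function(p)
      if (is_missing_chr(p$doi)) NA_character_ else p$doi, character(1)),
    year = vapply(papers, function(p) as.integer(p$year), integer(1)),
    eligible = vapply(decisions, `[[`, logical(1), "eligible"),
    family = vapply(decisions, `[[`, character(1), "family"),
    rejection_reason = vapply(decisions, `[[`, character(1),
                              "rejection_reason"),
    stringsAsFactors = FALSE
  )
  eligible <- papers[audit$eligible]
  fam <- audit$family[audit$eligible]
  for (i in seq_along(eligible)) eligible[[i]]$family <- fam[i]
  list(eligible = eligible, decisions = audit)
}
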