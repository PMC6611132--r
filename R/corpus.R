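## Synthetic Scopus-like corpus generator with known ground truth.
##
## Every downstream stage (eligibility, normalization, scoring, ranking,
## clustering, agreement) is testable against the truth tables this module
## emits, with no access to a citation database.

# -- name pools ---------------------------------------------------------------

.place_starts <- c(
  "Bel", "Dor", "Fen", "Gal", "Hart", "Kel", "Lor", "Mar", "Nor", "Ost",
  "Pell", "Quin", "Ros", "Sel", "Tarn", "Vel", "Wes", "Yar", "Zel", "Ash",
  "Bram", "Cald", "Eld", "Fair", "Glen", "Hol", "Lund", "Mor", "Stan", "Tre"
)
.place_ends <- c(
  "ford", "mont", "wick", "bury", "stad", "holm", "dale", "field", "grad",
  "port", "ton", "ville", "minster", "bridge", "haven", "mere", "stein",
  "by", "caster", "mouth"
)

.dept_strings <- c(
  "Urology and Nephrology Center", "Department of Epidemiology",
  "School of Public Health", "Faculty of Medicine", "Division of Cardiology",
  "Centre for Clinical Research", "Department of Computer Science",
  "Institute of Population Health"
)

.vague_strings <- c(
  "Faculty of Health", "School of Medicine", "Research Office",
  "Graduate School", "Department of Surgery", "Faculty of Science"
)

.institute_types <- c(
  "General Hospital", "Research Institute", "University Hospital",
  "Medical Center"
)

.topics <- c(
  "statin therapy", "aerobic exercise", "hypertension management",
  "type 2 diabetes", "smoking cessation", "influenza vaccination",
  "chronic low back pain", "stroke rehabilitation", "adolescent depression",
  "asthma control", "telehealth follow-up", "opioid prescribing"
)

.title_templates <- list(
  CONSORT_ok = c(
    "A randomised trial of %s",
    "Effect of %s on %s: a randomized trial",
    "%s versus usual care: an RCT",
    "A pragmatic randomised trial of %s in primary care"
  ),
  CONSORT_bad = c(
    "A pilot evaluation of %s",
    "Effects of %s in hospitalised adults"
  ),
  PRISMA_ok = c(
    "A systematic review of %s",
    "%s and %s: a meta-analysis",
    "A meta analysis of %s",
    "A scoping review of %s",
    "Systematic literature review of %s",
    "A systematic search of studies of %s"
  ),
  PRISMA_bad = c(
    "A narrative overview of %s",
    "Current perspectives on %s"
  ),
  STROBE_ok = c(
    "A cohort study of %s",
    "%s and risk of %s: a case-control study",
    "Cross-sectional associations between %s and %s"
  ),
  irrelevant = c(
    "Advances in %s",
    "Understanding %s: a commentary"
  )
)

# -- configuration ------------------------------------------------------------

#' Noise profile for affiliation-string corruption
#'
#' Flags controlling which corruptions [generate_corpus()] may apply to a
#' canonical institution name. Each corruption is the inverse of one of the
#' cleaning rules applied by [normalize_affiliation()].
#'
#' @param departments add a department/centre segment (prefix or suffix)
#' @param acronyms replace the name by its acronym
#' @param locations append a city suffix
#' @param diacritics strip diacritics from the name
#' @param prefixes prepend an unnecessary "The "
#' @param dual_names swap between "University of X" and "X University" forms
#' @param institutes replace the university by an affiliated institute name
#' @param vague replace the name by an uninformative string (e.g. "Faculty of
#'   Health") that normalization maps to `Missing`
#' @return an object of class `noise_profile` (a named logical list)
#' @seealso [noise_profile_off()] for the all-off identity profile
#' @export
noise_profile <- function(departments = TRUE, acronyms = TRUE,
                          locations = TRUE, diacritics = TRUE,
                          prefixes = TRUE, dual_names = TRUE,
                          institutes = TRUE, vague = TRUE) {
  structure(list(
    departments = isTRUE(departments), acronyms = isTRUE(acronyms),
    locations = isTRUE(locations), diacritics = isTRUE(diacritics),
    prefixes = isTRUE(prefixes), dual_names = isTRUE(dual_names),
    institutes = isTRUE(institutes), vague = isTRUE(vague)
  ), class = "noise_profile")
}

#' @rdname noise_profile
#' @export
noise_profile_off <- function() {
  noise_profile(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
}

#' Configuration for the synthetic corpus generator
#'
#' Defines the study conditions the generator emulates: two cross-sectional
#' years of guideline-citing papers, free-text affiliations averaging 3.3
#' entries per paper, about 0.5% of entries missing, and a latent
#' five-cluster structure of institutional scores.
#'
#' @param n_universities number of institutions in the latent population
#' @param n_papers_per_year papers generated per year
#' @param years integer vector of publication years
#' @param cluster_means five strictly increasing positive reals: the latent
#'   expected scores of the five clusters
#' @param cluster_probs five probabilities (each >= 0.01, summing to 1) of a
#'   university belonging to each cluster
#' @param missing_affil_prob probability an affiliation entry is missing
#' @param mean_affils_per_paper expected affiliation entries per paper
#' @param corrupt_prob probability a non-missing entry is corrupted at all
#'   (given the noise profile enables at least one applicable corruption)
#' @param noise noise profile from [noise_profile()]
#' @param seed integer seed; the corpus is a deterministic function of the
#'   configuration
#' @return an object of class `corpus_config`
#' @export
corpus_config <- function(n_universities = 100,
                          n_papers_per_year = 1000,
                          years = c(2016L, 2017L),
                          cluster_means = c(2, 10, 25, 50, 90),
                          cluster_probs = c(0.45, 0.30, 0.15, 0.07, 0.03),
                          missing_affil_prob = 0.005,
                          mean_affils_per_paper = 3.3,
                          corrupt_prob = 0.65,
                          noise = noise_profile(),
                          seed = 1L) {
  cfg <- list(
    n_universities = n_universities, n_papers_per_year = n_papers_per_year,
    years = as.integer(years), cluster_means = cluster_means,
    cluster_probs = cluster_probs, missing_affil_prob = missing_affil_prob,
    mean_affils_per_paper = mean_affils_per_paper,
    corrupt_prob = corrupt_prob, noise = noise, seed = as.integer(seed)
  )
  validate_corpus_config(cfg)
  structure(cfg, class = "corpus_config")
}

validate_corpus_config <- function(cfg) {
  stopifnot_cfg <- function(ok, field, why) {
    if (!ok) stop("invalid corpus configuration: field '", field, "' ", why,
                  call. = FALSE)
  }
  stopifnot_cfg(is.numeric(cfg$n_universities) && length(cfg$n_universities) == 1 &&
                  cfg$n_universities >= 1 && cfg$n_universities == floor(cfg$n_universities),
                "n_universities", "must be a positive integer")
  max_unis <- length(.place_starts) * length(.place_ends) %/% 2
  stopifnot_cfg(cfg$n_universities <= max_unis, "n_universities",
                paste("must be at most", max_unis))
  stopifnot_cfg(is.numeric(cfg$n_papers_per_year) && cfg$n_papers_per_year >= 1,
                "n_papers_per_year", "must be a positive integer")
  stopifnot_cfg(length(cfg$years) >= 1 && !anyNA(cfg$years), "years",
                "must be a non-empty integer vector")
  stopifnot_cfg(length(cfg$cluster_means) == 5 && all(cfg$cluster_means > 0) &&
                  all(diff(cfg$cluster_means) > 0),
                "cluster_means", "must be 5 strictly increasing positive reals")
  stopifnot_cfg(length(cfg$cluster_probs) == 5 && all(cfg$cluster_probs >= 0.01) &&
                  abs(sum(cfg$cluster_probs) - 1) < 1e-12,
                "cluster_probs", "must be 5 probabilities >= 0.01 summing to 1")
  stopifnot_cfg(is.numeric(cfg$missing_affil_prob) &&
                  cfg$missing_affil_prob >= 0 && cfg$missing_affil_prob <= 1,
                "missing_affil_prob", "must be a probability in [0, 1]")
  stopifnot_cfg(is.numeric(cfg$mean_affils_per_paper) && cfg$mean_affils_per_paper >= 1,
                "mean_affils_per_paper", "must be a positive real >= 1")
  stopifnot_cfg(is.numeric(cfg$corrupt_prob) && cfg$corrupt_prob >= 0 &&
                  cfg$corrupt_prob <= 1, "corrupt_prob",
                "must be a probability in [0, 1]")
  stopifnot_cfg(inherits(cfg$noise, "noise_profile"), "noise",
                "must be a noise_profile object")
  invisible(cfg)
}

# -- corruption ---------------------------------------------------------------

default_acronym <- function(name) {
  words <- strsplit(name, " ", fixed = TRUE)[[1]]
  connectives <- c("of", "de", "the", "and", "for", "du", "des", "la")
  words <- words[!(tolower(words) %in% connectives)]
  if (length(words) < 2) return(NA_character_)
  paste(toupper(substring(words, 1, 1)), collapse = "")
}

dual_name_of <- function(name) {
  if (grepl("^University of .+$", name)) {
    sub("^University of (.+)$", "\\1 University", name)
  } else if (grepl("^[^,]+ University$", name)) {
    sub("^(.+) University$", "University of \\1", name)
  } else {
    NA_character_
  }
}

#' Corrupt a canonical affiliation string
#'
#' Applies one randomly chosen corruption from the enabled, applicable types
#' of the noise profile, producing the kind of free-text variation seen in
#' raw Scopus affiliation data. Uses R's global random number generator;
#' wrap in [set.seed()] for reproducibility.
#'
#' @param canonical canonical institution name (non-empty)
#' @param profile a [noise_profile()]
#' @param acronym acronym to substitute (default: initials of `canonical`)
#' @param city city for the location suffix (no location corruption if `NULL`)
#' @param institute affiliated institute name (no institute corruption if
#'   `NULL`)
#' @return a corrupted string; `canonical` unchanged when no enabled
#'   corruption applies
#' @export
corrupt_affiliation <- function(canonical, profile = noise_profile(),
                                acronym = NULL, city = NULL,
                                institute = NULL) {
  if (is_missing_chr(canonical)) stop("canonical name must be non-empty")
  if (is.null(acronym)) acronym <- default_acronym(canonical)

  types <- character(0)
  weights <- numeric(0)
  add <- function(type, w) {
    types <<- c(types, type)
    weights <<- c(weights, w)
  }
  if (profile$prefixes && !grepl("^The ", canonical)) add("prefix", 1)
  if (profile$departments) add("department", 1.5)
  if (profile$acronyms && !is.na(acronym)) add("acronym", 1)
  if (profile$locations && !is.null(city)) add("location", 1)
  if (profile$diacritics && !identical(strip_diacritics(canonical), canonical))
    add("diacritics", 0.6)
  if (profile$dual_names && !is.na(dual_name_of(canonical))) add("dual", 0.5)
  if (profile$institutes && !is.null(institute)) add("institute", 0.8)
  if (profile$vague) add("vague", 0.03)

  if (length(types) == 0) return(canonical)
  type <- sample(types, 1, prob = weights)
  switch(type,
    prefix = paste0("The ", canonical),
    department = {
      dept <- sample(.dept_strings, 1)
      if (stats::runif(1) < 0.5) paste0(canonical, ", ", dept)
      else paste0(dept, ", ", canonical)
    },
    acronym = acronym,
    location = paste0(canonical, ", ", city),
    diacritics = strip_diacritics(canonical),
    dual = dual_name_of(canonical),
    institute = institute,
    vague = sample(.vague_strings, 1)
  )
}

# -- university population ----------------------------------------------------

make_place_names <- function(n) {
  grid <- expand.grid(s = .place_starts, e = .place_ends,
                      stringsAsFactors = FALSE)
  all_names <- paste0(grid$s, grid$e)
  sample(all_names, n)
}

make_universities <- function(cfg, regions) {
  n <- cfg$n_universities
  places <- make_place_names(2L * n)
  uni_places <- places[seq_len(n)]
  cities <- places[n + seq_len(n)]

  countries <- regions$country
  # research-output-like weights: a few large producers, a long tail
  w <- rep(1, length(countries))
  big <- countries %in% c("United States", "United Kingdom", "China",
                          "Australia", "Canada", "Germany", "Italy",
                          "Netherlands", "Brazil", "Japan", "France", "Spain")
  w[big] <- 8
  country <- sample(countries, n, replace = TRUE, prob = w)

  name <- character(n)
  for (i in seq_len(n)) {
    if (country[i] %in% c("France", "Switzerland", "Belgium") &&
        stats::runif(1) < 0.7) {
      name[i] <- paste0("Université de ", uni_places[i])
    } else if (country[i] %in% c("Germany", "Austria") && stats::runif(1) < 0.6) {
      name[i] <- paste0("Universität ", uni_places[i])
    } else {
      tmpl <- sample(c("University of %s", "%s University",
                       "%s Institute of Technology",
                       "National University of %s", "%s Medical University"),
                     1, prob = c(0.35, 0.3, 0.1, 0.15, 0.1))
      name[i] <- sprintf(tmpl, uni_places[i])
    }
  }

  acronym <- vapply(name, default_acronym, character(1), USE.NAMES = FALSE)
  acronym[duplicated(acronym, incomparables = NA)] <- NA_character_

  institute <- rep(NA_character_, n)
  has_inst <- stats::runif(n) < 0.4
  institute[has_inst] <- paste(cities[has_inst],
                               sample(.institute_types, sum(has_inst),
                                      replace = TRUE))

  cluster <- sample.int(5L, n, replace = TRUE, prob = cfg$cluster_probs)
  data.frame(
    id = seq_len(n), canonical = name, acronym = acronym, city = cities,
    country = country,
    region = regions$region[match(country, regions$country)],
    institute = institute, cluster = cluster,
    expected_score = cfg$cluster_means[cluster],
    stringsAsFactors = FALSE
  )
}

# -- paper generation ---------------------------------------------------------

fill_template <- function(tmpl) {
  k <- lengths(regmatches(tmpl, gregexpr("%s", tmpl, fixed = TRUE)))
  do.call(sprintf, c(list(tmpl), as.list(sample(.topics, k))))
}

draw_title <- function(family) {
  if (is.na(family)) return(fill_template(sample(.title_templates$irrelevant, 1)))
  if (family == "STROBE") return(fill_template(sample(.title_templates$STROBE_ok, 1)))
  u <- stats::runif(1)
  pool <- if (u < 0.85) .title_templates[[paste0(family, "_ok")]]
          else if (u < 0.95) .title_templates[[paste0(family, "_bad")]]
          else .title_templates$irrelevant
  fill_template(sample(pool, 1))
}

#' Generate a synthetic citation corpus with ground truth
#'
#' Produces Scopus-like paper records: publication year, a title drawn from
#' template pools that match or violate the eligibility title filters, a
#' publication type, a DOI (usually), zero or more cited guideline-paper
#' identifiers, and free-text affiliation strings corrupted according to the
#' configured noise profile. Papers arrive per institution as Poisson counts
#' with rate proportional to the institution's latent cluster mean,
#' conditioned on the configured yearly total.
#'
#' @param config a [corpus_config()]
#' @return a list with elements `papers` (list of paper records) and `truth`
#'   (ground truth: the university table, the per-paper organization lists
#'   before corruption, and the generator's own mapping table for
#'   [normalize_affiliation()])
#' @examples
#' corp <- generate_corpus(corpus_config(n_universities = 20,
#'                                       n_papers_per_year = 50, seed = 7))
#' length(corp$papers)
#' head(corp$truth$universities)
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  validate_corpus_config(config)
  set.seed(config$seed)

  regions <- default_region_table()
  unis <- make_universities(config, regions)
  registry <- default_registry()
  fam_ids <- split(registry$id, registry$family)

  papers <- vector("list", length(config$years) * config$n_papers_per_year)
  paper_orgs <- vector("list", length(papers))
  k <- 0L
  for (year in config$years) {
    leads <- rep(unis$id,
                 stats::rmultinom(1, config$n_papers_per_year,
                                  prob = unis$expected_score)[, 1])
    leads <- sample(leads)  # shuffle paper order within year
    for (lead in leads) {
      k <- k + 1L
      m <- 1L + stats::rpois(1, config$mean_affils_per_paper - 1)
      org_ids <- c(lead,
                   if (m > 1) sample(unis$id, m - 1L, replace = TRUE,
                                     prob = unis$expected_score))

      cited <- character(0)
      family <- NA_character_
      if (stats::runif(1) >= 0.08) {
        family <- sample(c("CONSORT", "PRISMA", "STROBE"), 1,
                         prob = c(0.30, 0.40, 0.30))
        cited <- sample(fam_ids[[family]], 1)
        if (stats::runif(1) < 0.06) {
          other <- sample(setdiff(names(fam_ids), family), 1)
          cited <- c(cited, sample(fam_ids[[other]], 1))
        }
      }

      pub_type <- sample(c("Article", "Review", "Editorial", "Commentary",
                           "Correction"), 1,
                         prob = c(0.72, 0.13, 0.06, 0.05, 0.04))
      doi <- if (stats::runif(1) < 0.97)
        sprintf("10.5555/synth.%d.%05d", year, k) else NA_character_

      affils <- vector("list", length(org_ids))
      for (j in seq_along(org_ids)) {
        if (stats::runif(1) < config$missing_affil_prob) {
          affils[[j]] <- list(raw = NA_character_, country = NA_character_)
        } else {
          u <- unis[org_ids[j], ]
          raw <- u$canonical
          if (stats::runif(1) < config$corrupt_prob) {
            raw <- corrupt_affiliation(
              u$canonical, config$noise,
              acronym = u$acronym,  # NA disables the acronym corruption
              city = u$city,
              institute = if (is.na(u$institute)) NULL else u$institute
            )
          }
          affils[[j]] <- list(raw = raw, country = u$country)
        }
      }

      papers[[k]] <- list(
        doi = doi, year = as.integer(year), title = draw_title(family),
        pub_type = pub_type, cited_guidelines = cited, affiliations = affils
      )
      paper_orgs[[k]] <- unis$canonical[org_ids]
    }
  }

  truth <- list(
    universities = unis,
    paper_orgs = paper_orgs,
    mapping = truth_mapping_table(unis),
    config = config
  )
  list(papers = papers, truth = truth)
}

## Mapping table implied by the generator's own population: resolves every
## rule-only corruption back to its canonical name.
truth_mapping_table <- function(unis) {
  exact <- stats::setNames(unis$canonical, unis$canonical)
  duals <- vapply(unis$canonical, dual_name_of, character(1), USE.NAMES = FALSE)
  has_dual <- !is.na(duals) & !(duals %in% unis$canonical)
  exact <- c(exact, stats::setNames(unis$canonical[has_dual], duals[has_dual]))

  has_acr <- !is.na(unis$acronym)
  acronyms <- stats::setNames(unis$canonical[has_acr], unis$acronym[has_acr])
  has_inst <- !is.na(unis$institute)
  consolidations <- stats::setNames(unis$canonical[has_inst],
                                    unis$institute[has_inst])
  mapping_table(exact = exact, acronyms = acronyms,
                consolidations = consolidations,
                location_exceptions = character(0),
                vague = .vague_strings)
}

#' Default country-to-region lookup
#'
#' Ships a world-factbook style region scheme (regions such as "Asia
#' (excluding Near East)", "Near East" and "Baltics") used by the generator
#' and by [aggregate_geography()].
#'
#' @return data.frame with columns `country`, `region`
#' @export
default_region_table <- function() {
  path <- system.file("extdata", "regions.csv", package = "goodrank")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
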