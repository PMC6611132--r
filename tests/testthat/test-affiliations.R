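# Affiliation normalization: the cleaning-rule cascade, vague -> Missing,
# idempotence, recovery on rule-only corruptions, and missingness accounting.

test_that("the documented cleaning-rule examples normalize as stated", {
  tab <- mapping_table(
    exact = c("Mansoura University" = "Mansoura University",
              "University of Sydney" = "University of Sydney",
              "Université de Montréal" = "Université de Montréal"),
    acronyms = c("UCL" = "University College London"),
    consolidations = c("The Ottawa Hospital" = "University of Ottawa"),
    vague = "Faculty of Health")

  norm <- function(x) normalize_affiliation(x, "X", tab)$canonical
  expect_identical(norm("Mansoura University, Urology and Nephrology Center"),
                   "Mansoura University")
  expect_identical(norm("The University of Sydney"), "University of Sydney")
  expect_identical(norm("Faculty of Health"), "Missing")
  expect_identical(norm("University of Sydney"), "University of Sydney")
  expect_identical(norm("UCL"), "University College London")
  expect_identical(norm("The Ottawa Hospital"), "University of Ottawa")
  # diacritic-folded matching recovers the accented canonical
  expect_identical(norm("Universite de Montreal"), "Université de Montréal")
  # location suffix stripped
  expect_identical(norm("University of Sydney, Camperdown"),
                   "University of Sydney")
  # absent input is Missing with Missing country
  na_res <- normalize_affiliation(NA, NA, tab)
  expect_identical(na_res$canonical, "Missing")
  expect_identical(na_res$country, "Missing")
})

test_that("location exceptions retain the disambiguating segment", {
  tab <- mapping_table(
    exact = c("University of Newcastle, Callaghan" =
                "University of Newcastle (Australia)",
              "University of Newcastle, Newcastle upon Tyne" =
                "University of Newcastle (UK)"),
    location_exceptions = "University of Newcastle")
  got <- normalize_affiliation("University of Newcastle, Callaghan",
                               "Australia", tab)
  expect_identical(got$canonical, "University of Newcastle (Australia)")
  # unlisted location passes through with the location retained
  got2 <- normalize_affiliation("University of Newcastle, Ourimbah",
                                "Australia", tab)
  expect_identical(got2$canonical, "University of Newcastle, Ourimbah")
})

test_that("normalization is idempotent on generated corpora", {
  corp <- generate_corpus(corpus_config(n_universities = 40,
                                        n_papers_per_year = 150, seed = 23))
  tab <- corp$truth$mapping
  flat <- flatten_affiliations(normalize_corpus(corp$papers, tab))
  once <- flat$canonical
  twice <- vapply(once, function(x)
    normalize_affiliation(x, "X", tab)$canonical, character(1),
    USE.NAMES = FALSE)
  # Missing is a sentinel, not a string to re-normalize
  keep <- once != "Missing"
  expect_identical(twice[keep], once[keep])
})

test_that("rule-only corruptions are recovered at >= 99%", {
  for (s in c(41, 42)) {
    cfg <- corpus_config(n_universities = 60, n_papers_per_year = 400,
                         seed = s, missing_affil_prob = 0,
                         noise = noise_profile(vague = FALSE))
    corp <- generate_corpus(cfg)
    norm <- normalize_corpus(corp$papers, corp$truth$mapping)
    ok <- 0; tot <- 0
    for (i in seq_along(norm)) {
      got <- norm[[i]]$affiliations_norm$canonical
      want <- corp$truth$paper_orgs[[i]]
      tot <- tot + length(got)
      ok <- ok + sum(got == want)
    }
    expect_gte(ok / tot, 0.99)
  }
})

test_that("missingness report reproduces the printed-percent arithmetic", {
  af <- data.frame(
    canonical = c(rep("U", 8064), rep("Missing", 39), rep("V", 100)),
    country = c(rep("United States", 8064 + 39), rep("Canada", 100)),
    stringsAsFactors = FALSE)
  rep_ <- missingness_report(af)
  us <- rep_[rep_$country == "United States", ]
  expect_identical(us$complete, 8064L)
  expect_identical(us$missing, 39L)
  expect_identical(us$percent_missing, 0.5)
  # ordered by missing count descending; zero-missing row shows 0.0
  expect_identical(rep_$country[1], "United States")
  expect_identical(rep_[rep_$country == "Canada", ]$percent_missing, 0)
  # conservation: counts sum to entries processed
  expect_identical(sum(rep_$complete) + sum(rep_$missing), nrow(af))
  expect_identical(nrow(missingness_report(af[0, ])), 0L)
})

test_that("report separates the nominal Missing country and conserves totals", {
  corp <- generate_corpus(corpus_config(n_universities = 30,
                                        n_papers_per_year = 300,
                                        missing_affil_prob = 0.05, seed = 29))
  flat <- flatten_affiliations(normalize_corpus(corp$papers,
                                                corp$truth$mapping))
  rep_ <- missingness_report(flat)
  expect_true("Missing" %in% rep_$country)
  mrow <- rep_[rep_$country == "Missing", ]
  expect_identical(mrow$complete, 0L)  # both country and affiliation absent
  expect_identical(sum(rep_$complete) + sum(rep_$missing), nrow(flat))
})

test_that("mapping tables reject ambiguous and cyclic entries", {
  expect_error(
    mapping_table(exact = c("X" = "A"), acronyms = c("X" = "B")),
    "two canonicals")
  expect_error(
    mapping_table(consolidations = c("A" = "B", "B" = "C")),
    "depth 1")
})

test_that("mapping tables round-trip through CSV", {
  corp <- generate_corpus(corpus_config(n_universities = 20,
                                        n_papers_per_year = 30, seed = 3))
  f <- tempfile(fileext = ".csv")
  write_mapping_table(corp$truth$mapping, f)
  back <- read_mapping_table(f)
  expect_identical(back$exact, corp$truth$mapping$exact)
  expect_identical(back$acronyms, corp$truth$mapping$acronyms)
  expect_identical(back$consolidations, corp$truth$mapping$consolidations)
  expect_identical(back$vague, corp$truth$mapping$vague)
})
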