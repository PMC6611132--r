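# Fractional counting: per-paper credits, score table conservation,
# geographic aggregation.

test_that("paper credits split one unit over address-list entries", {
  # two entries, two organizations: 0.5 each
  cr <- paper_credits(c("Queensland University of Technology",
                        "Ottawa Hospital Research Institute"))
  expect_identical(unname(cr["Queensland University of Technology"]), 0.5)
  expect_identical(unname(cr["Ottawa Hospital Research Institute"]), 0.5)

  expect_identical(unname(paper_credits("A")), 1)
  cr2 <- paper_credits(c("A", "A", "B"))
  expect_equal(unname(cr2[c("A", "B")]), c(2 / 3, 1 / 3))
  cr3 <- paper_credits(c("A", "Missing", "B", "B"))
  expect_equal(unname(cr3[c("A", "B", "Missing")]), c(0.25, 0.5, 0.25))
  # empty address list credits the nominal Missing institution in full
  expect_identical(paper_credits(character(0)), c(Missing = 1))
})

test_that("credits always sum to exactly one per paper", {
  set.seed(7)
  for (i in 1:50) {
    orgs <- sample(LETTERS[1:6], sample(1:8, 1), replace = TRUE)
    expect_equal(sum(paper_credits(orgs)), 1)
  }
})

test_that("score table sums credits by institution-year and conserves totals", {
  papers <- norm_corpus(list(
    list(year = 2016, orgs = "A"), list(year = 2016, orgs = "A"),
    list(year = 2016, orgs = "A")))
  st <- build_score_table(papers)
  expect_identical(st$score[st$institution == "A"], 3)

  # worked two-affiliation example repeated twice: linear in papers
  p2 <- norm_corpus(list(list(year = 2016, orgs = c("QUT", "OHRI")),
                         list(year = 2016, orgs = c("QUT", "OHRI"))))
  st2 <- build_score_table(p2)
  expect_identical(sort(st2$score), c(1, 1))

  corp <- generate_corpus(corpus_config(n_universities = 25,
                                        n_papers_per_year = 120, seed = 19))
  norm <- normalize_corpus(filter_corpus(corp$papers)$eligible,
                           corp$truth$mapping)
  st3 <- build_score_table(norm)
  yrs <- vapply(norm, function(p) p$year, integer(1))
  for (y in unique(yrs))
    expect_equal(sum(st3$score[st3$year == y]), sum(yrs == y),
                 tolerance = 1e-9)
})

test_that("duplicate DOIs within a year are rejected by name", {
  papers <- norm_corpus(list(list(year = 2016, orgs = "A"),
                             list(year = 2016, orgs = "B")))
  papers[[2]]$doi <- papers[[1]]$doi
  expect_error(build_score_table(papers), papers[[1]]$doi, fixed = TRUE)
  # same DOI in different years is fine
  papers[[2]]$year <- 2017L
  papers[[2]]$affiliations_norm <- papers[[2]]$affiliations_norm
  expect_silent(build_score_table(papers))
})

test_that("scores are invariant to paper and affiliation order", {
  corp <- generate_corpus(corpus_config(n_universities = 20,
                                        n_papers_per_year = 80, seed = 37))
  norm <- normalize_corpus(corp$papers, corp$truth$mapping)
  st <- build_score_table(norm)
  set.seed(4)
  shuffled <- lapply(norm[sample(seq_along(norm))], function(p) {
    p$affiliations_norm <- p$affiliations_norm[
      sample(nrow(p$affiliations_norm)), , drop = FALSE]
    p
  })
  st2 <- build_score_table(shuffled)
  expect_equal(as.data.frame(st), as.data.frame(st2))
})

test_that("adding a solely-affiliated paper raises only that score by 1", {
  papers <- norm_corpus(list(list(year = 2016, orgs = c("A", "B")),
                             list(year = 2016, orgs = "B")))
  st <- build_score_table(papers)
  extra <- norm_corpus(list(list(year = 2016, orgs = "A")))
  extra[[1]]$doi <- "10.1/extra"
  st2 <- build_score_table(c(papers, extra))
  a1 <- st$score[st$institution == "A"]
  a2 <- st2$score[st2$institution == "A"]
  b1 <- st$score[st$institution == "B"]
  b2 <- st2$score[st2$institution == "B"]
  expect_equal(a2 - a1, 1)
  expect_equal(b2, b1)
})

test_that("geographic aggregation excludes Missing and matches a groupby oracle", {
  papers <- list(
    with_norm(make_paper(doi = "10.1/a"), c("U1", "U2"),
              countries = c("Australia", "Canada")),
    with_norm(make_paper(doi = "10.1/b"), c("U1", "Missing"),
              countries = c("Australia", "Missing")),
    with_norm(make_paper(doi = "10.1/c"), "U3", countries = "Canada"))
  st <- build_score_table(papers)
  geo <- aggregate_geography(st)
  au <- geo$country$score[geo$country$country == "Australia"]
  ca <- geo$country$score[geo$country$country == "Canada"]
  expect_equal(au, 0.5 + 0.5)
  expect_equal(ca, 0.5 + 1)
  expect_false("Missing" %in% geo$country$country)
  expect_false("Missing" %in% geo$region$region)
  # additivity: two universities in one country sum to the country score
  oc <- geo$region$score[geo$region$region == "Oceania"]
  expect_equal(oc, au)

  # independent re-aggregation from entry level on a generated corpus
  corp <- generate_corpus(corpus_config(n_universities = 25,
                                        n_papers_per_year = 100, seed = 43))
  norm <- normalize_corpus(filter_corpus(corp$papers)$eligible,
                           corp$truth$mapping)  # all eligible papers have DOIs
  st2 <- build_score_table(norm)
  geo2 <- aggregate_geography(st2)
  flat <- flatten_affiliations(norm)
  flat$w <- stats::ave(rep(1, nrow(flat)), flat$doi, flat$year,
                       FUN = function(x) 1 / length(x))
  keep <- flat$country != "Missing"
  oracle <- tapply(flat$w[keep], paste(flat$country[keep], flat$year[keep]),
                   sum)
  got <- stats::setNames(geo2$country$score,
                         paste(geo2$country$country, geo2$country$year))
  expect_equal(unname(got[names(oracle)]), as.numeric(oracle),
               tolerance = 1e-9)

  # unmapped countries fall into an Unmapped region with a warning
  papers2 <- list(with_norm(make_paper(), "U9", countries = "Atlantis"))
  expect_warning(geo3 <- aggregate_geography(build_score_table(papers2)),
                 "Atlantis")
  expect_identical(geo3$region$region, "Unmapped")
})
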