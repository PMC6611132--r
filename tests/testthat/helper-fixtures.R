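# Shared fixtures: small hand-built paper records and independent oracles.

make_paper <- function(doi = "10.1/x", year = 2016L,
                       title = "A systematic review of statins",
                       pub_type = "Article",
                       cited = "PRISMA-2009",
                       affiliations = list(list(raw = "University of Sydney",
                                                country = "Australia"))) {
  list(doi = doi, year = as.integer(year), title = title, pub_type = pub_type,
       cited_guidelines = cited, affiliations = affiliations)
}

# attach pre-normalized affiliations directly (bypasses string cleaning)
with_norm <- function(paper, canonicals, countries = NULL) {
  if (is.null(countries)) countries <- rep("Australia", length(canonicals))
  countries[canonicals == "Missing"] <- "Missing"
  paper$affiliations_norm <- data.frame(
    raw = canonicals, canonical = canonicals, country = countries,
    rule_applied = "exact", stringsAsFactors = FALSE)
  paper
}

# a tiny normalized corpus: each element (doi, year, canonical orgs)
norm_corpus <- function(specs) {
  lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    with_norm(make_paper(doi = sprintf("10.1/p%d", i), year = s$year),
              s$orgs)
  })
}

# independent OLS oracle via the normal equations
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  unname(solve(t(X) %*% X, t(X) %*% y)[2, 1])
}

# independent Spearman oracle: average ranks, then the Pearson formula
spearman_oracle <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  num / den
}
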