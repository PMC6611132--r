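# goodrank

University league tables reward research *quantity* — publication and
citation counts — and thereby feed the publish-or-perish culture they are
often criticised for. `goodrank` builds the opposite kind of table: it
scores institutions by a marker of **good research practice**, namely
papers whose authors cited a reporting guideline (CONSORT for randomised
trials, PRISMA for systematic reviews and meta-analyses, STROBE for
observational studies), and it treats the resulting ranking with the
statistical caution rankings deserve — bootstrap confidence intervals for
every rank, and a Bayesian clustering model that groups institutions
instead of pretending a total order exists.

The package is aimed at meta-researchers and bibliometricians who want a
tested, reproducible pipeline from raw citation records to a
league table with uncertainty, without access to a proprietary citation
database: a synthetic Scopus-like corpus generator with known ground truth
stands in for the real extraction, and every downstream stage is exercised
against that truth.

## What it computes

**Fractional scores.** Each eligible paper carries one unit of credit,
split over the entries of its address list (organisational-level
fractional counting): a paper with one affiliation from Queensland
University of Technology and one from Ottawa Hospital Research Institute
gives 0.5 to each. The score of institution *i* in year *t* is

    S(i,t) = sum over year-t papers of (entries resolving to i) / (total entries)

so scores in a year sum exactly to the number of eligible papers.
Unresolvable affiliations credit a nominal institution "Missing", ranked
alongside real ones to expose the cost of incomplete affiliation data.

**Eligibility.** A paper enters the table if it cites a registered
guideline paper, is an Article or Review (not an Editorial, Commentary or
Correction), has a DOI, falls in an analysis year, and passes a
design-specific title filter ("randomised/randomized trial" or "RCT" for
CONSORT; systematic-review / meta-analysis phrases, hyphenated or not, for
PRISMA; no restriction for STROBE). A paper citing several guideline
families is counted once.

**Affiliation cleaning.** Free-text affiliation strings are normalized by
a keyed lookup plus rule cascade: exact matches, institute-to-university
consolidations, acronym expansion, "The " prefix stripping,
department-segment stripping, location-suffix stripping (with an exception
list for institutions whose city disambiguates them), and vague strings
("Faculty of Health") mapped to Missing. Matching is diacritic- and
case-folded, so "Universite de Montreal" resolves to "Université de
Montréal".

**Rank uncertainty.** Papers are resampled with replacement within year
(1,000 replicates by default), scores and competition ranks recomputed,
and each institution reported with its median rank and a 95% percentile
interval.

**Clustering.** Scores of 2 or above enter a five-component Bayesian
ordered mixture:

    S(i,t) ~ Normal(xbar[c(i,t)], sigma2)
    xbar(1) = gamma(1),  xbar(j) = xbar(j-1) + gamma(j),  gamma(j) ~ Exponential(1)
    c(i,t) ~ Categorical(pi),  pi(j) = delta(j) / sum(delta),  delta(j) ~ Uniform(1, 99/4)
    sigma2 ~ Uniform(0.01, 1000)

The cumulative-increment construction keeps the component means strictly
increasing (no label switching; cluster 5 is always the best), and the
delta prior floors every cluster probability at exactly 1%. The sampler is
written in the package: Gibbs updates for memberships, adaptive
random-walk Metropolis for the continuous parameters, plus a collapsed
independence move anchored at the exact 1-D k-means partition that
protects against merged-component modes. Convergence is reported via
R-hat and effective sample sizes.

**Agreement.** Year-to-year rank stability is summarised by Bland–Altman
limits of agreement (mean difference ± 1.96 SD over institutions in the
top 200 of both years), and comparison against an external
standard ranking by Spearman correlation.

## Worked example

```r
library(goodrank)

cfg <- pipeline_config(
  synth = corpus_config(n_universities = 40, n_papers_per_year = 400, seed = 42),
  n_replicates = 500,
  mcmc = list(iterations = 4000, burnin = 2000, chains = 2, thin = 2),
  seed = 7)
res <- run_pipeline(cfg)

res$manifest$papers_in        # 800
res$manifest$papers_eligible  # 530
unlist(res$manifest$rejections)
#> bad_pub_type       no_doi no_guideline title_filter
#>          107           12           71           80

head(res$league[res$league$year == 2016,
  c("institution", "score_display", "median_cluster",
    "median_rank", "ci_low", "ci_high")], 5)
#>                        institution score_display median_cluster median_rank ci_low ci_high
#> 1 Norfield Institute of Technology          42.3              5           1      1       2
#> 2              Eldmouth University          34.7              5           2      1       2
#> 3           University of Quinbury          25.1              4           3      3       6
#> 4  National University of Bramstad          22.2              4           5      3       6
#> 5           University of Quinwick          22.0              4           5      3       6
```

Of 800 generated papers, 530 pass the five eligibility gates (the
rejection counts itemize why the rest fail). The top two institutions are
separated from the pack — their rank intervals are (1, 2) — while ranks
3–5 are already exchangeable within their intervals, which is exactly the
over-interpretation the clustering column guards against: all three sit
in cluster 4.

Year-to-year agreement from the same run:

```r
res$agreement$stats
#> $n_compared        39
#> $mean_difference   0.282
#> $sd_difference     4.84
#> $loa_low          -9.21
#> $loa_high          9.78
```

On average ranks barely move between the two synthetic years (mean
difference 0.28), but an individual institution can move about ±10 places
within the limits of agreement — on a 40-institution table, a caution
against reading meaning into single-rank changes.

## Command line

A thin CLI over the package functions lives at `inst/cli/goodrank.R`:

```sh
Rscript inst/cli/goodrank.R synth  --out corpus.jsonl --truth truth.json --seed 1
Rscript inst/cli/goodrank.R filter --in corpus.jsonl --out eligible.jsonl --audit decisions.csv
Rscript inst/cli/goodrank.R run    --config config.yaml --out-dir out/
```

See `vignettes/league-tables.Rmd` for the model, its assumptions, the
generator's design and known limitations.
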