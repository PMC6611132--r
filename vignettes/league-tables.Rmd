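---
title: "League tables of good research practice: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{League tables of good research practice: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(goodrank)
```

## The problem

International university rankings overwhelmingly count publications and
citations. `goodrank` implements the alternative: a cross-sectional league
table that scores institutions by a proxy for good research practice —
their researchers citing a reporting guideline (CONSORT, PRISMA or STROBE)
in papers of the matching study design — and that is explicit about the
uncertainty of the resulting ranks. The pipeline runs from paper-level
citation records to three statistical outputs: fractional scores per
institution-year, bootstrap rank intervals, and a Bayesian grouping of
institutions into five ordered clusters.

Because the raw records of such an analysis come from a proprietary
citation database, the package ships a synthetic corpus generator with
known ground truth; every stage of the pipeline is tested against that
truth rather than against data that cannot be redistributed.

## Scoring model

Eligible papers each carry one unit of credit, divided over the entries of
the address list (organisational-level fractional counting). The score is

$$S(i,t) = \sum_{p \in \text{year } t} \frac{n_{p,i}}{n_p},$$

where $n_{p,i}$ counts address-list entries of paper $p$ resolving to
institution $i$ and $n_p$ is the total number of entries. Two consequences
are deliberate and tested:

* **Conservation.** Credits sum to one per paper and scores per year sum
  to the number of eligible papers — an exact invariant used throughout
  the test suite.
* **Entries, not distinct organizations.** An institution listed twice on
  one paper earns double weight. This is the reading most consistent with
  "fractional count of author affiliations" plus the worked 0.5/0.5
  example with two entries; deduplicating entries per paper would be a
  different (also defensible) convention, and the credit function takes
  the address list as given so callers can deduplicate upstream if they
  prefer.

Entries that cannot be resolved credit a nominal institution `"Missing"`,
which is ranked and clustered like any real institution. Keeping Missing
visible (4th place is entirely possible) is a feature: it prices the cost
of incomplete affiliation data instead of silently discarding it. Country
and region aggregates, by contrast, exclude Missing, and follow each
entry's own country field rather than an institution's modal country.

## Eligibility gates

Five gates, applied in a fixed order with the first failure recorded for
audit: guideline citation, publication type (Articles and Reviews only),
DOI presence, year, title filter. Two details are design decisions the
data sources leave open:

* **Phrase matching** is case-insensitive substring matching for
  multi-word phrases; each hyphenated phrase is expanded to hyphen, space
  and concatenated variants ("meta-analysis", "meta analysis",
  "metaanalysis"). "RCT" is matched case-insensitively at word
  boundaries so it cannot fire inside unrelated words.
* **Single counting.** A paper citing several guideline families counts
  once, under the fixed precedence CONSORT > PRISMA > STROBE; the title
  filter applied is the assigned family's. Any fixed precedence keeps
  results deterministic; the choice biases multi-family papers toward the
  rarer CONSORT family, which is conservative for the much larger PRISMA
  and STROBE pools.

## Affiliation normalization

Free-text affiliations are resolved by a keyed lookup backed by a rule
cascade, in a fixed order: exact match → institute consolidation →
acronym expansion → "The " prefix stripping → department-segment
stripping → location-suffix stripping (honouring an exception list for
institutions whose city disambiguates them) → vague check → Missing.
Exact matches come first so curated tables always pre-empt heuristics;
the vague check comes late so a vague *segment* ("Faculty of Medicine,
Mansoura University") does not hide a resolvable institution.

All lookups use a diacritic-folded, case-folded key, so canonical names
keep their diacritics while ASCII-mangled variants resolve. Unmatched
non-vague strings pass through as their own (title-cased) canonical: an
unmapped institution splits visibly across name variants rather than
vanishing, mirroring the known failure mode of missed consolidations
(institutions ranked too low because their credit is spread over
variants). Normalization is idempotent — a property test applies it twice
and demands a fixed point.

## Rank uncertainty

Ranks are competition ranks (ties share the minimum rank). Uncertainty
comes from a paper-level bootstrap: within each year — each year is its
own cross-sectional table, so pooled resampling would mix tables — papers
are resampled with replacement, scores rebuilt through the same credit
function, and institutions re-ranked. Defaults: 1,000 replicates, 95%
percentile intervals.

Numerical conventions worth stating:

* Quantiles of integer ranks use the inverse-ECDF (type 1) definition, so
  the reported median and interval bounds are ranks that actually
  occurred; an even posterior split resolves toward the better rank.
* An institution absent from a replicate is assigned rank (number ranked
  in that replicate + 1), so percentiles are defined for rarely sampled
  institutions. Dropping them instead would bias rare institutions'
  intervals optimistically.
* The bootstrap is implemented as one sparse paper-by-institution credit
  matrix per year; each replicate is a multinomial count vector times
  that matrix, which keeps 1,000 replicates on thousands of papers to
  seconds.

The interval-width regression (`width_vs_rank`) summarises how uncertainty
grows down the table: an OLS fit of interval width on median rank over the
top-*n* institutions, reported as slope per 10 ranks with its 95% CI.

## The cluster model

Institutions with a score of at least 2 (boundary inclusive, applied per
institution-year) enter a five-component Bayesian ordered mixture with a
single parameter set shared across years:

$$S(i,t) \sim N(\bar{x}_{c(i,t)}, \sigma^2), \qquad
\bar{x}_j = \textstyle\sum_{k \le j} \gamma_k, \quad
\gamma_k \sim \text{Exponential}(1),$$
$$c(i,t) \sim \text{Categorical}(\pi), \qquad
\pi_j = \delta_j / \textstyle\sum_k \delta_k, \quad
\delta_j \sim U(1, 99/4), \qquad \sigma^2 \sim U(0.01, 1000).$$

* The cumulative-increment construction makes the means strictly
  increasing by construction: label switching is structurally impossible
  and cluster 5 always has the largest mean.
* The $\delta$ prior floors every cluster probability at exactly
  $1/(1 + 4 \cdot 99/4) = 0.01$; both the analytic floor and the
  empirical approach to it are tested on direct prior draws.
* $K = 5$ is a fixed modelling opinion of how many groups are meaningful,
  not selected from data.
* The prior is placed on the **variance**, read literally from the model
  statement. BUGS-family samplers parameterise the Normal by its
  precision, so a fit under that convention may differ;
  `prior_on_precision = TRUE` reproduces it.
* Scores enter untransformed despite heavy right skew (`log_score = TRUE`
  is available but off by default). With raw scores the Normal components
  mostly partition the long tail; that is what the model is asked to do.

### Sampler

The MCMC scheme is written in the package (diagnostics use `coda`):

* memberships $c$: exact categorical Gibbs updates, vectorised with the
  Gumbel-max trick;
* $\gamma_j$, $\delta_j$, $\sigma^2$: random-walk Metropolis within their
  supports, step sizes adapted toward ~0.44 acceptance during burn-in
  only, then frozen (so retained draws come from a fixed kernel);
* a 10%-probability joint move per iteration: an independence proposal
  for the whole increment vector around the *exact* 1-D k-means partition
  of the scores (computed by dynamic programming over the sorted values),
  with memberships collapsed out of the acceptance ratio and redrawn from
  their full conditional on acceptance.

The last move exists because single-site random walks on ordered
increments occasionally trap a chain in a merged-components mode (two
components sharing one data cluster while a real cluster goes unmodelled);
in testing this occurred on roughly one seed in ten and did not resolve
within 20,000 iterations. The collapsed anchor move lets such a chain jump
to the dominant partition in one accepted step while remaining a valid
Metropolis–Hastings kernel. Heuristic k-means was not good enough as an
anchor: with unequal cluster sizes it lands in merged local optima itself,
which is why the exact dynamic-programming partition is used. Chains are
initialised at that partition too (lightly jittered per chain), with the
variance initialised at the pooled within-segment variance.

Defaults: 2 chains × 20,000 iterations, 10,000 burn-in, thinning 10.
`summary()` reports posterior means, 95% credible intervals, split-chain
R-hat and effective sizes; post-burn-in Metropolis acceptance rates are
attached and should sit in roughly (0.1, 0.7).

### Reported clusters

An institution-year's cluster is the posterior **median** of its
membership across retained draws; an even split resolves downward, so
public claims about cluster membership are conservative. One honest edge
case: when scores carry no separation at all (e.g. all identical), the
institutions are exchangeable and share one membership distribution; if
that distribution's median sits exactly on a cluster boundary, per-
institution empirical medians can straddle two adjacent labels. The tests
assert what the model actually guarantees — identical membership
distributions and at most two adjacent median labels — rather than a
single shared label.

`cross_tab_clusters()` counts between-year movements over institutions
present in both years, with margins, for the stability table.

## Agreement diagnostics

Bland–Altman limits of agreement on ranks: restrict to institutions in
the top 200 (median bootstrap ranks) of both years, difference oriented
later-minus-earlier so positive means the rank worsened, limits
mean ± 1.96·SD with the sample (n−1) SD. Comparison to an external
standard ranking uses Spearman's correlation with average-rank ties; the
standard ranking is consumed as a user-supplied table, since
reconstructing a paper-count ranking needs database access out of scope
here.

## The synthetic corpus generator

The generator emulates the features of a real guideline-citation corpus
that the pipeline must survive:

* two publication years, ~3.3 affiliation entries per paper (1 + Poisson
  dispersion; real dispersion is unknown, so the simplest count model is
  used), ~0.5% missing entries;
* three guideline families with registry identifiers, titles drawn from
  template pools that match or violate the title filters, publication
  types including the excluded ones, occasional missing DOIs and
  multi-family citers;
* affiliation strings corrupted by invertible rule-based noise:
  department segments, acronyms, location suffixes, stripped diacritics,
  "The " prefixes, dual name forms, affiliated-institute names and
  (rarely) vague strings;
* a latent five-cluster structure: each university draws a cluster, and
  papers arrive per university as Poisson counts with rate proportional
  to its cluster mean, conditioned on the configured yearly total
  (multinomial allocation), so realized scores scatter around the latent
  means.

Defaults are 100 universities, 1,000 papers per year, cluster means
(2, 10, 25, 50, 90) with probabilities (0.45, 0.30, 0.15, 0.07, 0.03) —
a skewed population where most institutions score low, matching the shape
of real guideline-citation counts.

What the generator does **not** emulate — so what passing tests do not
show — includes: real institution name distributions and their much
messier free-text variation (the seven rule-based corruptions are
invertible by construction; real Scopus strings are not), correlation of
affiliations within research communities, citation behaviour changing
over time, and any form of gaming (token guideline citation). Ground
truth recovery at ≥99% therefore validates the *mechanics* of the
cascade, not entity-linking performance on real data.

## Degenerate inputs and errors

Empty corpora fail at scoring with a stage-tagged message; duplicate DOIs
within a year are rejected by name; a year with no scores cannot be
ranked; fewer than 5 included observations (score ≥ 2) cannot be
clustered; non-finite scores are rejected; bootstrap intervals require at
least 2 replicates; agreement statistics require at least 3 paired
institutions; a width regression with all ranks equal is a degenerate
design and errors. Unmapped countries aggregate into an "Unmapped" region
with a warning rather than being dropped.

## Problem sizes in the test suite

The unit suite runs corpora of 10–80 universities and up to a few hundred
papers per year with shortened chains; the acceptance suite runs the
exhaustive 27-resample bootstrap enumeration, a 10,000-replicate bootstrap
on 3 papers, recovery of five ordered components from 200 scores, 100,000
prior draws, and one full pipeline at the default study conditions (2,000
papers, 1,000 replicates, 2 × 20,000 MCMC iterations). These sizes were
chosen so the entire suite completes in a few minutes on one CPU while
still exercising every contract at meaningful scale.

## Known limitations

* Citing a guideline is a proxy; the pipeline cannot tell engagement from
  token citation.
* No size normalization: bigger institutions score higher by
  construction, and the score is an absolute count, not a rate.
* The mapping table is only as good as its curation; unmapped name
  variants split an institution's credit (visibly, by design).
* Whether the original analysis placed its uniform prior on the variance
  or effectively on the precision is not decidable from the model
  statement alone; both are supported, variance is the default.
* The bootstrap treats papers as exchangeable within year; it does not
  model correlated multi-paper groups or database coverage error.
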