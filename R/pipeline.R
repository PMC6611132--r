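## End-to-end orchestration: corpus -> eligibility -> normalization ->
## scoring -> ranking -> clustering -> agreement, behind one configuration,
## with per-stage audit counts in a run manifest.

#' Pipeline configuration
#'
#' @param corpus path to a JSONL corpus, or `NULL` to generate a synthetic
#'   corpus from `synth`
#' @param synth a [corpus_config()] used when `corpus` is `NULL`
#' @param registry path to a registry file, or `NULL` for
#'   [default_registry()]
#' @param mapping path to a mapping-table file, or `NULL` (uses the
#'   generator's own mapping table for synthetic corpora, otherwise an
#'   empty table)
#' @param regions path to a country-region CSV, or `NULL` for
#'   [default_region_table()]
#' @param years years analysed
#' @param n_replicates bootstrap replicates
#' @param top_n top-n restriction for the agreement comparison
#' @param mcmc list of MCMC settings (`iterations`, `burnin`, `chains`,
#'   `thin`)
#' @param rounding `"one_decimal"` or `"integer"` display rounding
#' @param seed master seed; stage seeds are derived from it by fixed offsets
#' @param out_dir directory for output CSVs, or `NULL` to skip writing
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(corpus = NULL, synth = corpus_config(),
                            registry = NULL, mapping = NULL, regions = NULL,
                            years = c(2016L, 2017L),
                            n_replicates = 1000, top_n = 200,
                            mcmc = list(iterations = 20000, burnin = 10000,
                                        chains = 2, thin = 10),
                            rounding = "one_decimal",
                            seed = 1L, out_dir = NULL) {
  if (length(years) == 0) stop("years must be non-empty")
  for (p in c(corpus, registry, mapping, regions))
    if (!is.null(p) && !file.exists(p)) stop("path does not exist: ", p)
  structure(list(corpus = corpus, synth = synth, registry = registry,
                 mapping = mapping, regions = regions,
                 years = as.integer(years),
                 n_replicates = n_replicates, top_n = top_n, mcmc = mcmc,
                 rounding = rounding, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `synth`
#' section holds [corpus_config()] fields (with `noise: off` to disable all
#' corruption).
#'
#' @param path YAML file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  synth_args <- y$synth %||% list()
  if (identical(synth_args$noise, "off")) synth_args$noise <- noise_profile_off()
  synth <- do.call(corpus_config, synth_args)
  args <- y[setdiff(names(y), "synth")]
  do.call(pipeline_config, c(args, list(synth = synth)))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full league-table pipeline
#'
#' Executes the stages in order — corpus, eligibility filtering, affiliation
#' normalization, fractional scoring, geographic aggregation, bootstrap
#' ranking, Bayesian clustering, between-year agreement — and assembles the
#' league table. The run manifest records the seed, per-stage record counts
#' (with eligibility rejections itemized by reason) and timing. Identical
#' configuration and seed give identical outputs.
#'
#' @param config a [pipeline_config()] (or a path to a YAML file)
#' @return list with `league` (league-table rows), `scores`, `geography`,
#'   `ranks`, `cluster_fit`, `assignments`, `cross_tab`, `agreement`,
#'   `missingness`, `decisions` and `manifest`; output CSVs are written to
#'   `config$out_dir` when set
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  manifest <- list(seed = config$seed, started = format(t0))

  truth <- NULL
  papers <- stage("corpus", {
    if (is.null(config$corpus)) {
      synth <- config$synth
      synth$seed <- derive_seed(config$seed, 1)
      corp <- generate_corpus(synth)
      truth <- corp$truth
      corp$papers
    } else {
      read_corpus(config$corpus)
    }
  })
  manifest$papers_in <- length(papers)

  registry <- if (is.null(config$registry)) default_registry()
              else read_registry(config$registry)
  filt <- stage("eligibility",
                filter_corpus(papers, registry, config$years))
  manifest$papers_eligible <- length(filt$eligible)
  rej <- filt$decisions$rejection_reason
  manifest$rejections <- as.list(table(rej[!is.na(rej)]))

  mapping <- if (!is.null(config$mapping)) read_mapping_table(config$mapping)
             else if (!is.null(truth)) truth$mapping
             else mapping_table()
  normalized <- stage("normalization", normalize_corpus(filt$eligible, mapping))
  flat <- flatten_affiliations(normalized)
  manifest$affiliation_entries <- nrow(flat)

  scores <- stage("scoring", build_score_table(normalized))
  regions <- if (is.null(config$regions)) default_region_table()
             else utils::read.csv(config$regions, stringsAsFactors = FALSE)
  geography <- stage("scoring", aggregate_geography(scores, regions))
  missingness <- missingness_report(flat)

  ranks <- stage("ranking", bootstrap_ranks(
    normalized, n_replicates = config$n_replicates,
    seed = derive_seed(config$seed, 2)))

  fit <- stage("clustering", fit_cluster_model(
    scores, iterations = config$mcmc$iterations, burnin = config$mcmc$burnin,
    chains = config$mcmc$chains, thin = config$mcmc$thin %||% 10,
    seed = derive_seed(config$seed, 3)))
  assignments <- cluster_assignments(fit)

  yrs <- sort(unique(ranks$year))
  agreement <- NULL
  cross_tab <- NULL
  if (length(yrs) >= 2) {
    ra <- with(ranks[ranks$year == yrs[1], ],
               stats::setNames(median_rank, institution))
    rb <- with(ranks[ranks$year == yrs[2], ],
               stats::setNames(median_rank, institution))
    agreement <- stage("agreement",
                       bland_altman_ranks(ra, rb, top_n = config$top_n))
    cross_tab <- cross_tab_clusters(assignments, yrs[1], yrs[2])
  }

  league <- merge(as.data.frame(ranks),
                  assignments[, c("institution", "year", "median_cluster")],
                  by = c("institution", "year"), all.x = TRUE)
  league <- format_league_table(league, config$rounding)

  manifest$finished <- format(Sys.time())
  manifest$elapsed_secs <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  result <- list(league = league, scores = scores, geography = geography,
                 ranks = ranks, cluster_fit = fit, assignments = assignments,
                 cross_tab = cross_tab, agreement = agreement,
                 missingness = missingness, decisions = filt$decisions,
                 truth = truth, manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) utils::write.csv(
      x, file.path(config$out_dir, f), row.names = FALSE)
    wr(league, "league_table.csv")
    wr(as.data.frame(scores), "scores.csv")
    wr(geography$country, "scores_by_country.csv")
    wr(geography$region, "scores_by_region.csv")
    wr(missingness, "missing_by_country.csv")
    wr(filt$decisions, "eligibility_decisions.csv")
    wr(summary(fit), "cluster_posterior.csv")
    if (!is.null(cross_tab))
      utils::write.csv(as.data.frame.matrix(cross_tab),
                       file.path(config$out_dir, "cluster_cross_tab.csv"))
    if (!is.null(agreement))
      jsonlite::write_json(agreement$stats,
                           file.path(config$out_dir, "agreement.json"),
                           auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' Format league-table rows for display
#'
#' Orders rows by score (descending) within year, breaking ties by
#' institution name, and adds a display-rounded score: one decimal place
#' (the in-paper style) or integers rounded half away from zero (the
#' public-table style that discourages over-interpreting small
#' differences). Full-precision scores are preserved alongside.
#'
#' @param rows data.frame with at least `institution`, `year`, and a score
#'   column (`point_score` or `score`)
#' @param rounding `"one_decimal"` or `"integer"`
#' @return the rows, ordered, with `score_display` prepended after the key
#'   columns
#' @export
format_league_table <- function(rows, rounding = c("one_decimal", "integer")) {
  rounding <- match.arg(rounding)
  if (nrow(rows) == 0) stop("rows must be non-empty")
  score <- if ("point_score" %in% names(rows)) rows$point_score
           else rows$score
  rows$score_display <- if (rounding == "one_decimal")
    sprintf("%.1f", score) else sprintf("%d", as.integer(round_half_away(score)))
  rows <- rows[order(rows$year, -score, rows$institution), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
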