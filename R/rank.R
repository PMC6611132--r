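## Ranking and bootstrap rank uncertainty.
##
## Ranks are competition ranks (rank 1 = highest score; ties share the
## minimum rank). Uncertainty comes from a paper-level bootstrap: within
## each year, papers are resampled with replacement, scores rebuilt and
## institutions re-ranked; the median rank and a percentile interval are
## reported per institution.

#' Competition ranks for one year of a score table
#'
#' @param table a [build_score_table()] result
#' @param year year to rank
#' @return named integer vector: institution -> rank (1 = highest score;
#'   tied scores share the minimum rank)
#' @export
rank_scores <- function(table, year) {
  stopifnot(inherits(table, "score_table"))
  scores <- table$score[table$year == year]
  insts <- table$institution[table$year == year]
  if (length(scores) == 0) stop("no scores for year ", year)
  stats::setNames(as.integer(rank(-scores, ties.method = "min")), insts)
}

competition_rank <- function(scores) {
  as.integer(rank(-scores, ties.method = "min"))
}

## Percentile of integer ranks: smallest observed value whose empirical CDF
## reaches p (inverse-ECDF quantile), so medians with an even posterior
## split resolve toward the lower (better) rank.
rank_quantile <- function(x, p) {
  as.integer(stats::quantile(x, p, type = 1, names = FALSE))
}

#' Bootstrap confidence intervals for league-table ranks
#'
#' For each replicate and year, resamples that year's papers with
#' replacement, rebuilds fractional scores and re-ranks. Institutions absent
#' from a replicate are assigned rank (number ranked in that replicate + 1)
#' so medians and percentiles are defined for rarely sampled institutions.
#' Intervals are percentile-method at level `ci_level`.
#'
#' @param papers normalized papers from [normalize_corpus()]
#' @param n_replicates bootstrap replicates (default 1000)
#' @param ci_level confidence level (default 0.95)
#' @param seed integer seed; results are deterministic given
#'   `(papers, n_replicates, ci_level, seed)`
#' @return data.frame of class `rank_estimates`: `institution`, `year`,
#'   `point_score`, `point_rank`, `median_rank`, `ci_low`, `ci_high`
#' @export
bootstrap_ranks <- function(papers, n_replicates = 1000, ci_level = 0.95,
                            seed = 1L) {
  if (n_replicates < 2) stop("n_replicates must be >= 2: interval undefined")
  stopifnot(ci_level > 0, ci_level < 1)
  table <- build_score_table(papers)
  set.seed(as.integer(seed))
  alpha <- (1 - ci_level) / 2

  years <- vapply(papers, function(p) as.integer(p$year), integer(1))
  out <- vector("list", length(unique(years)))
  for (yi in seq_along(sort(unique(years)))) {
    year <- sort(unique(years))[yi]
    idx <- which(years == year)
    n_pap <- length(idx)
    insts <- table$institution[table$year == year]
    point_score <- table$score[table$year == year]
    n_inst <- length(insts)

    # sparse paper-by-institution credit matrix for fast resampled scoring
    trip <- do.call(rbind, lapply(seq_along(idx), function(j) {
      cr <- paper_credits(papers[[idx[j]]]$affiliations_norm$canonical)
      data.frame(p = j, i = match(names(cr), insts), x = as.numeric(cr))
    }))
    credit_mat <- Matrix::sparseMatrix(i = trip$p, j = trip$i, x = trip$x,
                                       dims = c(n_pap, n_inst))

    ranks <- matrix(NA_integer_, n_inst, n_replicates)
    for (r in seq_len(n_replicates)) {
      counts <- tabulate(sample.int(n_pap, n_pap, replace = TRUE), n_pap)
      s <- as.numeric(Matrix::crossprod(credit_mat, counts))
      present <- s > 0
      rk <- rep.int(sum(present) + 1L, n_inst)
      rk[present] <- competition_rank(s[present])
      ranks[, r] <- rk
    }

    out[[yi]] <- data.frame(
      institution = insts, year = year,
      point_score = point_score,
      point_rank = competition_rank(point_score),
      median_rank = apply(ranks, 1, rank_quantile, p = 0.5),
      ci_low = apply(ranks, 1, rank_quantile, p = alpha),
      ci_high = apply(ranks, 1, rank_quantile, p = 1 - alpha),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$year, res$median_rank, -res$point_score,
                   res$institution), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("rank_estimates", "data.frame")
  res
}

#' How interval width grows with rank
#'
#' Ordinary least-squares regression of bootstrap interval width
#' (`ci_high - ci_low`) on median rank, over institutions with median rank
#' at or inside `top_n` (pooled across years). The slope is reported per 10
#' ranks, with its 95% confidence interval.
#'
#' @param estimates a [bootstrap_ranks()] result
#' @param top_n restrict to institutions with median rank `<= top_n`
#' @return list: `slope_per_10`, `ci` (length-2), `n`, and the underlying
#'   `lm` fit
#' @export
width_vs_rank <- function(estimates, top_n = 200) {
  stopifnot(inherits(estimates, "rank_estimates"))
  d <- as.data.frame(estimates)
  d <- d[d$median_rank <= top_n, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 rank estimates")
  d$width <- d$ci_high - d$ci_low
  if (length(unique(d$median_rank)) < 2)
    stop("degenerate design: all median ranks equal")
  fit <- stats::lm(width ~ median_rank, data = d)
  ci <- stats::confint(fit)["median_rank", ] * 10
  list(slope_per_10 = unname(stats::coef(fit)["median_rank"]) * 10,
       ci = unname(ci), n = nrow(d), fit = fit)
}
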