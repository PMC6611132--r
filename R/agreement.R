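## Between-year and between-table rank agreement.

#' Bland-Altman agreement between two years' ranks
#'
#' Restricts to institutions ranked at or inside `top_n` in both years,
#' takes per-institution rank differences (`ranks_b - ranks_a`, so positive
#' means the rank worsened in the second year), and reports the mean
#' difference with limits of agreement mean +/- 1.96 * SD (sample SD, n - 1
#' denominator).
#'
#' @param ranks_a,ranks_b named integer vectors (institution -> rank), e.g.
#'   median bootstrap ranks from [bootstrap_ranks()]
#' @param top_n only institutions ranked `<= top_n` in both years are
#'   compared (ties at the boundary are included)
#' @return list with `stats` (`n_compared`, `mean_difference`,
#'   `sd_difference`, `loa_low`, `loa_high`) and `pairs` (data.frame:
#'   `institution`, `mean_rank`, `difference`) for plotting
#' @export
bland_altman_ranks <- function(ranks_a, ranks_b, top_n = 200) {
  shared <- intersect(names(ranks_a), names(ranks_b))
  shared <- shared[ranks_a[shared] <= top_n & ranks_b[shared] <= top_n]
  if (length(shared) < 3)
    stop("need at least 3 institutions in the top ", top_n, " of both years")
  diff <- as.numeric(ranks_b[shared] - ranks_a[shared])
  m <- mean(diff)
  s <- stats::sd(diff)
  list(
    stats = list(n_compared = length(shared), mean_difference = m,
                 sd_difference = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s),
    pairs = data.frame(
      institution = shared,
      mean_rank = as.numeric(ranks_a[shared] + ranks_b[shared]) / 2,
      difference = diff, stringsAsFactors = FALSE)
  )
}

#' Spearman comparison of two rankings
#'
#' Spearman's rank correlation over institutions present in both rankings,
#' with average-rank tie handling (used to compare the good-practice
#' ranking with a standard paper-count ranking).
#'
#' @param our_ranks,standard_ranks named numeric vectors
#'   (institution -> rank)
#' @return list with `n_shared`, `rho` and the paired data.frame `pairs`
#' @export
compare_rankings <- function(our_ranks, standard_ranks) {
  shared <- intersect(names(our_ranks), names(standard_ranks))
  if (length(shared) < 3)
    stop("need at least 3 institutions shared between the rankings")
  a <- as.numeric(our_ranks[shared])
  b <- as.numeric(standard_ranks[shared])
  list(n_shared = length(shared),
       rho = stats::cor(a, b, method = "spearman"),
       pairs = data.frame(institution = shared, rank_a = a, rank_b = b,
                          stringsAsFactors = FALSE))
}

#' Bland-Altman plot of rank agreement
#'
#' @param agreement a [bland_altman_ranks()] result
#' @param ... passed to [graphics::plot()]
#' @export
plot_bland_altman <- function(agreement, ...) {
  p <- agreement$pairs
  s <- agreement$stats
  graphics::plot(p$mean_rank, p$difference,
                 xlab = "Mean rank over the two years",
                 ylab = "Difference in rank (later - earlier)", ...)
  graphics::abline(h = s$mean_difference, lty = 1)
  graphics::abline(h = c(s$loa_low, s$loa_high), lty = 2)
  invisible(agreement)
}
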