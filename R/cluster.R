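## Five-component Bayesian ordered mixture model for institution scores.
##
## Scores S(i,t) are modelled as Normal(xbar[c(i,t)], sigma2) where the five
## component means are built as cumulative sums of Exponential(1) increments
## (so they are strictly increasing and label switching is structurally
## impossible), memberships are Categorical(pi) with pi(j) = delta(j) /
## sum(delta) and delta(j) ~ Uniform(1, 99/4) — which floors every component
## probability at exactly 1% — and sigma2 ~ Uniform(0.01, 1000). One shared
## parameter set (xbar, pi, sigma2) covers all years. The sampler is a
## bespoke MCMC scheme: exact categorical Gibbs updates for the memberships
## and adaptive random-walk Metropolis (tuned during burn-in, then frozen)
## for the continuous parameters within their prior supports.

.delta_hi <- 99 / 4
.sig2_lo <- 0.01
.sig2_hi <- 1000

#' Apply the score inclusion threshold
#'
#' Clustering is only applied to institution-years with a score of 2 or
#' above, removing the long tail of institutions with very small samples.
#'
#' @param table a [build_score_table()] result (or any data.frame with a
#'   `score` column)
#' @param threshold minimum score retained (default 2, boundary inclusive)
#' @return the filtered table, attributes preserved
#' @export
apply_inclusion_threshold <- function(table, threshold = 2) {
  keep <- table$score >= threshold
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Draw from the model's prior
#'
#' Direct Monte Carlo draws of the prior over (gamma, xbar, delta, pi,
#' sigma2). Useful for checking the analytic probability floor: the minimum
#' achievable component probability is 1 / (1 + 4 * 99/4) = 0.01.
#'
#' @param n number of draws
#' @param seed integer seed
#' @return list of matrices `gamma`, `xbar`, `delta`, `pi` (n x 5) and
#'   vector `sigma2`
#' @export
rcluster_prior <- function(n, seed = 1L) {
  set.seed(as.integer(seed))
  gamma <- matrix(stats::rexp(n * 5, rate = 1), n, 5)
  xbar <- t(apply(gamma, 1, cumsum))
  delta <- matrix(stats::runif(n * 5, 1, .delta_hi), n, 5)
  pi <- delta / rowSums(delta)
  sigma2 <- stats::runif(n, .sig2_lo, .sig2_hi)
  list(gamma = gamma, xbar = xbar, delta = delta, pi = pi, sigma2 = sigma2)
}

## log-likelihood of scores given memberships, means and variance
.loglik <- function(y, c_idx, xbar, sig2) {
  -0.5 * length(y) * log(2 * pi * sig2) -
    sum((y - xbar[c_idx])^2) / (2 * sig2)
}

## Exact 1-d K-means on sorted data by dynamic programming over contiguous
## segments (the optimal 1-d partition is contiguous in the sorted order).
## Deterministic, so every chain anchors on the same partition.
kmeans1d <- function(y, K) {
  ys <- sort(y)
  n <- length(ys)
  cs <- cumsum(ys)
  cs2 <- cumsum(ys^2)
  sse <- function(i, j) {  # vectorized over i
    s <- cs[j] - c(0, cs)[i]
    s2 <- cs2[j] - c(0, cs2)[i]
    m <- j - i + 1
    pmax(s2 - s^2 / m, 0)
  }
  dp <- matrix(Inf, K, n)
  cut_at <- matrix(0L, K, n)
  dp[1, ] <- pmax(cs2 - cs^2 / seq_len(n), 0)
  if (K > 1) {
    for (k in 2:K) {
      for (j in k:n) {
        i <- k:j  # first index of the k-th segment
        tot <- dp[k - 1, i - 1] + sse(i, j)
        best <- which.min(tot)
        dp[k, j] <- tot[best]
        cut_at[k, j] <- i[best]
      }
    }
  }
  # back-track segment boundaries
  bounds <- integer(K + 1)
  bounds[K + 1] <- n
  j <- n
  for (k in K:2) {
    bounds[k] <- cut_at[k, j] - 1L
    j <- bounds[k]
  }
  bounds[1] <- 0L
  means <- vapply(seq_len(K), function(k)
    mean(ys[(bounds[k] + 1):bounds[k + 1]]), numeric(1))
  list(means = means, var = dp[K, n] / max(n - K, 1))
}

## marginal mixture log-likelihood (memberships summed out)
.mixloglik <- function(y, xbar, sig2, pi_vec) {
  lp <- matrix(log(pi_vec), length(y), length(xbar), byrow = TRUE) -
    0.5 * outer(y, xbar, "-")^2 / sig2 - 0.5 * log(2 * pi * sig2)
  mx <- apply(lp, 1, max)
  sum(mx + log(rowSums(exp(lp - mx))))
}

## one MCMC chain
run_chain <- function(y, iterations, burnin, thin, seed, K,
                      prior_on_precision) {
  set.seed(seed)
  n <- length(y)

  # initial values from the exact 1-d k-means partition of the scores:
  # component means at the segment means, variance at the pooled
  # within-segment variance, lightly jittered per chain
  part <- kmeans1d(y, K)
  anchor <- pmax(diff(c(0, part$means)), 0.05)
  gamma <- anchor * exp(stats::rnorm(K, 0, 0.1))
  delta <- stats::runif(K, 1, .delta_hi)
  v <- min(max(part$var, .sig2_lo * 2), .sig2_hi / 2)  # sig2 (or tau)
  if (prior_on_precision) v <- min(max(1 / v, .sig2_lo * 2), .sig2_hi / 2)

  step <- list(gamma = pmax(gamma / 4, 0.05),
               delta = rep(1, K),
               v = max(v / 4, 0.05))
  acc <- list(gamma = numeric(K), delta = numeric(K), v = 0)
  try_n <- list(gamma = numeric(K), delta = numeric(K), v = 0)

  n_keep <- floor((iterations - burnin) / thin)
  draws <- list(
    xbar = matrix(NA_real_, n_keep, K), pi = matrix(NA_real_, n_keep, K),
    gamma = matrix(NA_real_, n_keep, K), delta = matrix(NA_real_, n_keep, K),
    sigma2 = numeric(n_keep),
    c = matrix(NA_integer_, n_keep, n)
  )

  xbar <- cumsum(gamma)
  pi_vec <- delta / sum(delta)
  sig2 <- if (prior_on_precision) 1 / v else v
  # memberships start at the nearest component mean
  c_idx <- max.col(-abs(outer(y, xbar, "-")))
  ll <- .loglik(y, c_idx, xbar, sig2)

  kept <- 0L
  for (iter in seq_len(iterations)) {
    ## Gibbs update of memberships: exact categorical full conditional
    logp <- matrix(log(pi_vec), n, K, byrow = TRUE) -
      0.5 * (outer(y, xbar, "-")^2) / sig2
    gmb <- -log(-log(matrix(stats::runif(n * K), n, K)))  # Gumbel-max draw
    c_idx <- max.col(logp + gmb)
    ll <- .loglik(y, c_idx, xbar, sig2)

    ## random-walk Metropolis on each Exponential(1) increment
    for (j in seq_len(K)) {
      try_n$gamma[j] <- try_n$gamma[j] + 1
      prop <- gamma[j] + stats::rnorm(1, 0, step$gamma[j])
      if (prop > 0) {
        gamma_p <- gamma; gamma_p[j] <- prop
        xbar_p <- cumsum(gamma_p)
        ll_p <- .loglik(y, c_idx, xbar_p, sig2)
        if (log(stats::runif(1)) < (ll_p - prop) - (ll - gamma[j])) {
          gamma <- gamma_p; xbar <- xbar_p; ll <- ll_p
          acc$gamma[j] <- acc$gamma[j] + 1
        }
      }
    }

    ## occasional joint move: independence proposal for the whole increment
    ## vector, anchored at the fixed equal-count partition of the data, with
    ## memberships collapsed out (accepted on the marginal mixture
    ## likelihood, then redrawn from their full conditional). Lets a chain
    ## trapped in a merged-components mode escape in one move.
    if (stats::runif(1) < 0.1) {
      shp <- 8
      gamma_p <- stats::rgamma(K, shape = shp, rate = shp / anchor)
      xbar_p <- cumsum(gamma_p)
      mll_p <- .mixloglik(y, xbar_p, sig2, pi_vec)
      mll_c <- .mixloglik(y, xbar, sig2, pi_vec)
      lq_p <- sum(stats::dgamma(gamma_p, shp, rate = shp / anchor, log = TRUE))
      lq_c <- sum(stats::dgamma(gamma, shp, rate = shp / anchor, log = TRUE))
      lr <- (mll_p - sum(gamma_p)) - (mll_c - sum(gamma)) + lq_c - lq_p
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        gamma <- gamma_p; xbar <- xbar_p
        logp <- matrix(log(pi_vec), n, K, byrow = TRUE) -
          0.5 * (outer(y, xbar, "-")^2) / sig2
        gmb <- -log(-log(matrix(stats::runif(n * K), n, K)))
        c_idx <- max.col(logp + gmb)
        ll <- .loglik(y, c_idx, xbar, sig2)
      }
    }

    ## random-walk Metropolis on delta within [1, 99/4]
    counts <- tabulate(c_idx, K)
    for (j in seq_len(K)) {
      try_n$delta[j] <- try_n$delta[j] + 1
      prop <- delta[j] + stats::rnorm(1, 0, step$delta[j])
      if (prop >= 1 && prop <= .delta_hi) {
        delta_p <- delta; delta_p[j] <- prop
        lp_cur <- sum(counts * log(pi_vec))
        pi_p <- delta_p / sum(delta_p)
        lp_p <- sum(counts * log(pi_p))
        if (log(stats::runif(1)) < lp_p - lp_cur) {
          delta <- delta_p; pi_vec <- pi_p
          acc$delta[j] <- acc$delta[j] + 1
        }
      }
    }

    ## random-walk Metropolis on the variance (or precision) parameter
    try_n$v <- try_n$v + 1
    prop <- v + stats::rnorm(1, 0, step$v)
    if (prop >= .sig2_lo && prop <= .sig2_hi) {
      sig2_p <- if (prior_on_precision) 1 / prop else prop
      ll_p <- .loglik(y, c_idx, xbar, sig2_p)
      if (log(stats::runif(1)) < ll_p - ll) {
        v <- prop; sig2 <- sig2_p; ll <- ll_p
        acc$v <- acc$v + 1
      }
    }

    ## adapt proposal scales during burn-in only, toward ~0.44 acceptance
    if (iter <= burnin && iter %% 50 == 0) {
      adapt <- function(s, a, t) {
        rate <- ifelse(t > 0, a / t, 0.44)
        pmin(pmax(s * exp(rate - 0.44), 1e-3), 50)
      }
      step$gamma <- adapt(step$gamma, acc$gamma, try_n$gamma)
      step$delta <- adapt(step$delta, acc$delta, try_n$delta)
      step$v <- adapt(step$v, acc$v, try_n$v)
      acc <- list(gamma = numeric(K), delta = numeric(K), v = 0)
      try_n <- list(gamma = numeric(K), delta = numeric(K), v = 0)
    }

    if (iter > burnin && (iter - burnin) %% thin == 0) {
      kept <- kept + 1L
      draws$xbar[kept, ] <- xbar
      draws$pi[kept, ] <- pi_vec
      draws$gamma[kept, ] <- gamma
      draws$delta[kept, ] <- delta
      draws$sigma2[kept] <- sig2
      draws$c[kept, ] <- c_idx
    }
  }
  draws$acceptance <- c(
    gamma = mean(acc$gamma / pmax(try_n$gamma, 1)),
    delta = mean(acc$delta / pmax(try_n$delta, 1)),
    sigma2 = acc$v / max(try_n$v, 1)
  )
  draws
}

#' Fit the Bayesian ordered mixture model to institution scores
#'
#' Groups institution-years into five ordered clusters (cluster 5 always has
#' the highest mean) by MCMC. Only institution-years with a score at or
#' above `threshold` enter the model; one shared parameter set (means,
#' probabilities, variance) covers all years.
#'
#' @param table a [build_score_table()] result (columns `institution`,
#'   `year`, `score`)
#' @param iterations MCMC iterations per chain, including burn-in
#' @param burnin burn-in iterations discarded per chain
#' @param chains number of chains (>= 2 recommended for R-hat)
#' @param thin keep every `thin`-th post-burn-in draw
#' @param seed integer master seed; each chain derives its own stream
#' @param threshold inclusion threshold on the score (default 2)
#' @param prior_on_precision place the Uniform(0.01, 1000) prior on the
#'   precision 1/sigma2 instead of the variance. The variance scale is the
#'   default; BUGS-style samplers parameterise the Normal by its precision,
#'   so fits under that convention can be reproduced with this flag.
#' @param log_score model log(score) instead of the raw score (off by
#'   default; scores enter untransformed despite their right skew)
#' @return an object of class `cluster_fit`; see [cluster_assignments()],
#'   [coef.cluster_fit()], [summary.cluster_fit()]
#' @examples
#' \donttest{
#' scores <- data.frame(institution = paste0("U", 1:60),
#'                      year = 2016L,
#'                      score = c(rnorm(30, 3), rnorm(30, 40)))
#' fit <- fit_cluster_model(scores, iterations = 2000, burnin = 1000,
#'                          chains = 2, seed = 1)
#' coef(fit)
#' }
#' @export
fit_cluster_model <- function(table, iterations = 20000, burnin = 10000,
                              chains = 2, thin = 10, seed = 1L,
                              threshold = 2, prior_on_precision = FALSE,
                              log_score = FALSE) {
  K <- 5L
  stopifnot(iterations > burnin, burnin >= 0, chains >= 1, thin >= 1)
  inc <- apply_inclusion_threshold(as.data.frame(table), threshold)
  if (!all(c("institution", "year", "score") %in% names(inc)))
    stop("table must have columns institution, year, score")
  if (any(!is.finite(inc$score))) stop("non-finite scores in input")
  if (nrow(inc) < K)
    stop("need at least ", K, " included observations (score >= ",
         threshold, "); got ", nrow(inc))

  y <- if (log_score) log(inc$score) else inc$score
  chain_draws <- lapply(seq_len(chains), function(ch)
    run_chain(y, iterations, burnin, thin, derive_seed(seed, ch), K,
              prior_on_precision))

  structure(list(
    data = inc, y = y, chains = chain_draws, K = K,
    settings = list(iterations = iterations, burnin = burnin,
                    chains = chains, thin = thin, seed = seed,
                    threshold = threshold,
                    prior_on_precision = prior_on_precision,
                    log_score = log_score)
  ), class = "cluster_fit")
}

## pool a per-chain matrix column across chains
pooled <- function(fit, what, col = NULL) {
  do.call(rbind, lapply(fit$chains, function(d) {
    x <- d[[what]]
    if (is.null(col)) x else x[, col, drop = FALSE]
  }))
}

#' Median cluster and cluster probabilities per institution-year
#'
#' The median cluster is the posterior median of the categorical membership
#' across retained draws of all chains; an even posterior split resolves
#' down (toward the lower cluster), keeping public claims conservative.
#'
#' @param fit a [fit_cluster_model()] object
#' @return data.frame: `institution`, `year`, `score`, `median_cluster`,
#'   `p1`..`p5` (posterior probability of each cluster, summing to 1)
#' @export
cluster_assignments <- function(fit) {
  stopifnot(inherits(fit, "cluster_fit"))
  cmat <- pooled(fit, "c")
  med <- apply(cmat, 2, function(x)
    as.integer(stats::quantile(x, 0.5, type = 1, names = FALSE)))
  probs <- t(apply(cmat, 2, function(x) tabulate(x, fit$K) / length(x)))
  colnames(probs) <- paste0("p", seq_len(fit$K))
  cbind(fit$data[, c("institution", "year", "score")],
        median_cluster = med, as.data.frame(probs))
}

## split-chain R-hat and effective size via coda
.diag_params <- function(fit) {
  par_mat <- function(d) {
    m <- cbind(d$xbar, d$pi, d$sigma2)
    colnames(m) <- c(paste0("xbar", 1:fit$K), paste0("pi", 1:fit$K), "sigma2")
    m
  }
  coda::mcmc.list(lapply(fit$chains, function(d) coda::mcmc(par_mat(d))))
}

#' @export
coef.cluster_fit <- function(object, ...) {
  list(xbar = colMeans(pooled(object, "xbar")),
       pi = colMeans(pooled(object, "pi")),
       sigma2 = mean(pooled(object, "sigma2")))
}

#' Posterior summary of the cluster model
#'
#' @param object a [fit_cluster_model()] object
#' @param ... unused
#' @return data.frame with posterior mean, 2.5% and 97.5% quantiles, R-hat
#'   and effective sample size for the component means, probabilities and
#'   the variance
#' @export
summary.cluster_fit <- function(object, ...) {
  ml <- .diag_params(object)
  all <- do.call(rbind, ml)
  rhat <- if (length(ml) >= 2)
    coda::gelman.diag(ml, autoburnin = FALSE, multivariate = FALSE)$psrf[, 1]
  else rep(NA_real_, ncol(all))
  out <- data.frame(
    parameter = colnames(all),
    mean = colMeans(all),
    q2.5 = apply(all, 2, stats::quantile, 0.025),
    q97.5 = apply(all, 2, stats::quantile, 0.975),
    rhat = unname(rhat),
    n_eff = unname(coda::effectiveSize(ml)),
    row.names = NULL
  )
  attr(out, "acceptance") <- do.call(rbind, lapply(object$chains,
                                                   `[[`, "acceptance"))
  class(out) <- c("summary.cluster_fit", "data.frame")
  out
}

#' @export
print.summary.cluster_fit <- function(x, ...) {
  cat("Posterior summary (", nrow(x), " parameters)\n", sep = "")
  print.data.frame(cbind(x[1], round(x[-1], 3)), ...)
  acc <- attr(x, "acceptance")
  cat("Mean MH acceptance (post burn-in): ",
      paste(sprintf("%s=%.2f", colnames(acc), colMeans(acc)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.cluster_fit <- function(x, ...) {
  s <- x$settings
  cat("Bayesian ordered mixture (K = ", x$K, ") fitted to ",
      nrow(x$data), " institution-years (score >= ", s$threshold, ")\n",
      s$chains, " chains x ", s$iterations, " iterations (burn-in ",
      s$burnin, ", thin ", s$thin, ")\n", sep = "")
  est <- coef(x)
  cat("Posterior mean cluster means: ",
      paste(sprintf("%.2f", est$xbar), collapse = ", "), "\n", sep = "")
  cat("Posterior mean cluster probabilities: ",
      paste(sprintf("%.3f", est$pi), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
fitted.cluster_fit <- function(object, ...) {
  est <- coef(object)
  asg <- cluster_assignments(object)
  stats::setNames(est$xbar[asg$median_cluster],
                  paste(asg$institution, asg$year))
}

#' @export
residuals.cluster_fit <- function(object, ...) {
  object$y - unname(fitted(object))
}

#' Simulate scores from the posterior predictive distribution
#'
#' @param object a [fit_cluster_model()] object
#' @param nsim number of simulated datasets
#' @param seed optional integer seed
#' @param ... unused
#' @return matrix with `length(object$y)` rows and `nsim` columns
#' @export
simulate.cluster_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  xbar <- pooled(object, "xbar")
  pi_d <- pooled(object, "pi")
  sig2 <- pooled(object, "sigma2")
  n <- length(object$y)
  out <- matrix(NA_real_, n, nsim)
  for (s in seq_len(nsim)) {
    d <- sample.int(nrow(xbar), 1)
    comp <- sample.int(object$K, n, replace = TRUE, prob = pi_d[d, ])
    out[, s] <- stats::rnorm(n, xbar[d, comp], sqrt(sig2[d]))
  }
  out
}

#' Trace plots for the cluster model
#'
#' @param x a [fit_cluster_model()] object
#' @param ... passed to [graphics::matplot()]
#' @export
plot.cluster_fit <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  xb <- lapply(x$chains, `[[`, "xbar")
  graphics::matplot(do.call(rbind, xb), type = "l", lty = 1,
                    xlab = "retained draw (chains concatenated)",
                    ylab = "cluster means", main = "Ordered component means",
                    ...)
  graphics::matplot(do.call(cbind, lapply(x$chains, `[[`, "sigma2")),
                    type = "l", lty = 1, xlab = "retained draw",
                    ylab = "sigma2", main = "Variance")
  invisible(x)
}

#' Cross-tabulate median clusters between two years
#'
#' Counts how many institutions moved between clusters from `year_a` (rows)
#' to `year_b` (columns), over institutions present in both years. Row and
#' column margins and the grand total are appended.
#'
#' @param assignments a [cluster_assignments()] data.frame (or a
#'   `cluster_fit`, which is converted)
#' @param year_a,year_b the two years to compare
#' @return 6 x 6 integer matrix (5 clusters plus `Total` margins)
#' @export
cross_tab_clusters <- function(assignments, year_a, year_b) {
  if (inherits(assignments, "cluster_fit"))
    assignments <- cluster_assignments(assignments)
  a <- assignments[assignments$year == year_a, c("institution", "median_cluster")]
  b <- assignments[assignments$year == year_b, c("institution", "median_cluster")]
  m <- merge(a, b, by = "institution", suffixes = c("_a", "_b"))
  tab <- table(factor(m$median_cluster_a, 1:5),
               factor(m$median_cluster_b, 1:5))
  out <- rbind(cbind(tab, Total = rowSums(tab)),
               Total = c(colSums(tab), sum(tab)))
  storage.mode(out) <- "integer"
  names(dimnames(out)) <- c(paste0("year_", year_a), paste0("year_", year_b))
  out
}
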