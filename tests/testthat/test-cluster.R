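# Ordered mixture model: prior floor, support invariants, recovery,
# inclusion threshold, cross-tabulation, and an independent MCMC oracle.

make_scores <- function(means, n_per, sd = 1, seed = 1) {
  set.seed(seed)
  data.frame(institution = paste0("U", seq_len(length(means) * n_per)),
             year = 2016L,
             score = rnorm(length(means) * n_per, rep(means, each = n_per),
                           sd),
             true = rep(seq_along(means), each = n_per))
}

test_that("the inclusion threshold keeps scores >= 2, boundary inclusive", {
  tab <- data.frame(institution = c("A", "B", "C"), year = 2016L,
                    score = c(1.9, 2.0, 50))
  kept <- apply_inclusion_threshold(tab)
  expect_identical(kept$institution, c("B", "C"))
  expect_identical(nrow(apply_inclusion_threshold(tab[0, ])), 0L)
  # random tables equal a brute-force predicate filter
  set.seed(3)
  rt <- data.frame(institution = paste0("U", 1:50), year = 2016L,
                   score = runif(50, 0, 5))
  expect_identical(apply_inclusion_threshold(rt)$institution,
                   rt$institution[rt$score >= 2])
})

test_that("the prior floors every cluster probability at exactly 1%", {
  pr <- rcluster_prior(20000, seed = 10)
  expect_gte(min(pr$pi), 0.01)
  # the analytic floor 1/(1 + 4 * 99/4) = 0.01 is approached empirically
  expect_lt(min(pr$pi), 0.015)
  expect_true(all(apply(pr$xbar, 1, function(x) all(diff(x) > 0))))
  expect_true(all(pr$delta >= 1 & pr$delta <= 99 / 4))
  expect_true(all(pr$sigma2 >= 0.01 & pr$sigma2 <= 1000))
})

test_that("every retained posterior draw respects the prior supports", {
  sc <- make_scores(c(3, 12, 30, 55, 85), 12, seed = 2)
  fit <- fit_cluster_model(sc, iterations = 1200, burnin = 600, thin = 2,
                           chains = 2, seed = 4)
  for (d in fit$chains) {
    expect_true(all(apply(d$xbar, 1, function(x) all(diff(x) > 0))))
    expect_true(all(d$pi >= 0.01 - 1e-12))
    expect_true(all(abs(rowSums(d$pi) - 1) < 1e-9))
    expect_true(all(d$delta >= 1 & d$delta <= 99 / 4))
    expect_true(all(d$sigma2 >= 0.01 & d$sigma2 <= 1000))
    expect_true(all(d$c %in% 1:5))
  }
  # cluster probabilities per institution sum to 1
  asg <- cluster_assignments(fit)
  expect_equal(rowSums(asg[, paste0("p", 1:5)]), rep(1, nrow(asg)))
  # identical (data, settings, seed) reproduce the fit
  fit2 <- fit_cluster_model(sc, iterations = 1200, burnin = 600, thin = 2,
                            chains = 2, seed = 4)
  expect_identical(fit$chains, fit2$chains)
})

test_that("well-separated components are recovered with sensible mixing", {
  sc <- make_scores(c(2, 10, 25, 50, 90), 40, sd = 1, seed = 5)
  fit <- fit_cluster_model(sc, iterations = 3000, burnin = 1500, thin = 2,
                           chains = 2, seed = 6)
  m <- merge(cluster_assignments(fit), sc[, c("institution", "true")],
             by = "institution")
  expect_gte(mean(m$median_cluster == m$true), 0.95)
  s <- summary(fit)
  expect_lt(max(s$rhat), 1.2)
  acc <- attr(s, "acceptance")
  expect_true(all(acc > 0.1 & acc < 0.7))
  # posterior mean of the top component mean is near its generating value
  expect_lt(abs(coef(fit)$xbar[5] - 90), 1)
})

test_that("zero-separation scores give no differentiation between institutions", {
  sc <- data.frame(institution = paste0("U", 1:30), year = 2016L, score = 5)
  fit <- fit_cluster_model(sc, iterations = 2000, burnin = 1000, chains = 2,
                           seed = 3)
  asg <- cluster_assignments(fit)
  pm <- as.matrix(asg[, paste0("p", 1:5)])
  # exchangeable institutions: membership distributions agree to MC error
  # (retained draws are autocorrelated, so the error bound is generous)
  expect_lt(max(apply(pm, 2, function(col) diff(range(col)))), 0.25)
  # median labels collapse to one cluster, or at most two adjacent labels
  # when the posterior median sits on a cluster boundary
  expect_lte(diff(range(asg$median_cluster)), 1L)
})

test_that("degenerate inputs are rejected with informative errors", {
  few <- data.frame(institution = c("A", "B"), year = 2016L, score = c(5, 9))
  expect_error(fit_cluster_model(few), "at least 5")
  bad <- data.frame(institution = paste0("U", 1:10), year = 2016L,
                    score = c(rep(10, 9), Inf))
  expect_error(fit_cluster_model(bad), "non-finite")
})

test_that("cross-tabulation counts movements with margins and conservation", {
  asg <- data.frame(
    institution = rep(paste0("U", 1:6), 2),
    year = rep(c(2016L, 2017L), each = 6),
    median_cluster = c(1, 2, 3, 4, 5, 5, 1, 2, 3, 4, 5, 4))
  tab <- cross_tab_clusters(asg, 2016, 2017)
  expect_identical(tab["Total", "Total"], 6L)  # institutions in both years
  expect_identical(tab["5", "4"], 1L)
  expect_identical(sum(diag(tab[1:5, 1:5])), 5L)

  # unchanged assignments are purely diagonal
  asg2 <- asg; asg2$median_cluster[12] <- 5
  tab2 <- cross_tab_clusters(asg2, 2016, 2017)
  expect_identical(sum(tab2[1:5, 1:5]) - sum(diag(tab2[1:5, 1:5])), 0L)

  # random assignments match a brute-force nested-loop pair count
  set.seed(8)
  n <- 40
  asg3 <- data.frame(
    institution = rep(paste0("U", 1:n), 2),
    year = rep(c(2016L, 2017L), each = n),
    median_cluster = sample(1:5, 2 * n, replace = TRUE))
  tab3 <- cross_tab_clusters(asg3, 2016, 2017)
  for (r in 1:5) for (cc in 1:5) {
    count <- 0L
    for (i in 1:n) {
      a <- asg3$median_cluster[asg3$year == 2016][i]
      b <- asg3$median_cluster[asg3$year == 2017][i]
      if (a == r && b == cc) count <- count + 1L
    }
    expect_identical(tab3[r, cc], count)
  }
})

test_that("posterior means agree with an independent JAGS fit", {
  library(rjags)
  sc <- make_scores(c(2, 10, 25, 50, 90), 20, sd = 1, seed = 9)
  fit <- fit_cluster_model(sc, iterations = 3000, burnin = 1500, thin = 2,
                           chains = 2, seed = 2)

  model_str <- "
  model {
    for (i in 1:n) {
      y[i] ~ dnorm(xbar[c[i]], tau)
      c[i] ~ dcat(p[])
    }
    xbar[1] <- gamma[1]
    for (j in 2:5) { xbar[j] <- xbar[j-1] + gamma[j] }
    for (j in 1:5) {
      gamma[j] ~ dexp(1)
      delta[j] ~ dunif(1, 24.75)
      p[j] <- delta[j] / sum(delta[])
    }
    sig2 ~ dunif(0.01, 1000)
    tau <- 1 / sig2
  }"
  y <- sc$score[sc$score >= 2]
  # initialize JAGS near the data partition (prior-drawn means start all
  # points in one component, from which its samplers also struggle to
  # separate the ordered means)
  km <- goodrank:::kmeans1d(y, 5)
  jm <- jags.model(textConnection(model_str),
                   data = list(y = y, n = length(y)),
                   inits = list(gamma = pmax(diff(c(0, km$means)), 0.05),
                                delta = rep(5, 5), sig2 = max(km$var, 0.02),
                                .RNG.name = "base::Wichmann-Hill",
                                .RNG.seed = 7),
                   n.chains = 1, quiet = TRUE)
  update(jm, 2000, progress.bar = "none")
  post <- coda.samples(jm, c("xbar", "sig2"), n.iter = 4000,
                       progress.bar = "none")
  jags_xbar <- colMeans(as.matrix(post))[paste0("xbar[", 1:5, "]")]
  ours <- coef(fit)$xbar
  expect_lt(max(abs(ours - jags_xbar)), 1)
})
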