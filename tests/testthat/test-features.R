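# Brute-force likelihood oracle for the two-component mixture: coarse
# grid maximization, independent of the EM implementation.
grid_mixture_loglik <- function(x, mu_grid, sd_grid, pi_grid) {
  best <- -Inf
  best_par <- NULL
  for (m1 in mu_grid) for (m2 in mu_grid) {
    if (m2 < m1) next
    for (s in sd_grid) for (p in pi_grid) {
      ll <- sum(log(p * dnorm(x, m1, s) + (1 - p) * dnorm(x, m2, s)))
      if (ll > best) { best <- ll; best_par <- c(m1, m2, s, p) }
    }
  }
  list(loglik = best, par = best_par)
}

test_that("EM recovers well-separated clusters and beats a grid oracle", {
  set.seed(10)
  x <- c(rnorm(80, 0, 0.01), rnorm(80, 1, 0.01))
  fit <- fit_two_component_mixture(x)
  expect_true(fit$converged)
  expect_lt(abs(fit$mu1), 0.05)
  expect_lt(abs(fit$mu2 - 1), 0.05)
  expect_lt(abs(fit$pi1 - 0.5), 0.05)
  expect_lte(fit$mu1, fit$mu2)
  # oracle: shared-sd grid search must not beat the EM likelihood
  oracle <- grid_mixture_loglik(x, mu_grid = seq(-0.1, 1.1, by = 0.02),
                                sd_grid = c(0.005, 0.01, 0.02, 0.05),
                                pi_grid = seq(0.3, 0.7, by = 0.05))
  expect_gte(fit$loglik, oracle$loglik - 1e-6)
  expect_lt(abs(fit$mu1 - oracle$par[1]), 0.05)
  expect_lt(abs(fit$mu2 - oracle$par[2]), 0.05)
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller
  set.seed(21)
  x <- c(rnorm(100, 0.2, 0.05), rnorm(60, 0.8, 0.08))
  fit <- fit_two_component_mixture(x)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  mc_mu <- sort(mc$parameters$mean)
  expect_lt(abs(fit$mu1 - mc_mu[1]), 0.02)
  expect_lt(abs(fit$mu2 - mc_mu[2]), 0.02)
  expect_lt(abs(fit$loglik - mc$loglik), 1)
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  set.seed(12)
  for (x in list(rnorm(160), c(rnorm(80), rnorm(80, 3)),
                 runif(40))) {
    fit <- fit_two_component_mixture(x)
    expect_true(all(diff(fit$loglik_trace) > -1e-7))
  }
})

test_that("degenerate and undersized inputs are handled as contracted", {
  fit <- fit_two_component_mixture(rep(1.5, 20))
  expect_false(fit$converged)
  expect_true(fit$degenerate)
  expect_error(fit_two_component_mixture(c(1, 2, 3)))
  expect_identical(as.numeric(mixture_test_statistic(rep(1, 20), fit)), 0)
})

test_that("mixture test statistic separates unimodal from bimodal", {
  set.seed(31)
  null_stats <- replicate(200, mixture_test_statistic(rnorm(160)))
  expect_true(all(null_stats >= 0))
  expect_lt(median(null_stats), 6)
  set.seed(32)
  x <- c(rnorm(80, 0, 0.05), rnorm(80, 1, 0.05))
  stat <- mixture_test_statistic(x)
  expect_gt(stat, 50)
  # cross-check against explicit likelihood evaluation at the fitted and
  # single-normal parameters
  fit <- fit_two_component_mixture(x)
  ll2 <- sum(log(fit$pi1 * dnorm(x, fit$mu1, fit$sd1) +
                   (1 - fit$pi1) * dnorm(x, fit$mu2, fit$sd2)))
  ll1 <- sum(dnorm(x, mean(x), sqrt(mean((x - mean(x))^2)), log = TRUE))
  expect_equal(as.numeric(stat), max(0, 2 * (ll2 - ll1)), tolerance = 1e-6)
})

test_that("Ashman's D matches its closed form and is scale invariant", {
  fit <- structure(list(mu1 = 0, mu2 = 2, sd1 = 1, sd2 = 1,
                        degenerate = FALSE), class = "mixture_fit")
  expect_equal(as.numeric(ashman_d(fit)), 2)
  fit$mu2 <- 0
  expect_equal(as.numeric(ashman_d(fit)), 0)
  set.seed(41)
  x <- c(rnorm(80, 0, 0.1), rnorm(80, 1, 0.1))
  d1 <- as.numeric(ashman_d(fit_two_component_mixture(x)))
  d2 <- as.numeric(ashman_d(fit_two_component_mixture(3 * x + 7)))
  expect_equal(d1, d2, tolerance = 1e-4)
})

test_that("KS against a matched normal matches the closed form", {
  # 50/50 point masses at 0 and 1: matched normal ~ N(0.5, 0.5), and the
  # largest ECDF gap is at 0+: |0.5 - Phi(-1)| = 0.341
  x <- rep(c(0, 1), each = 80)
  ks <- ks_against_matched_normal(x)
  expect_lt(abs(unname(ks["ks_stat"]) - (0.5 - pnorm(-1))), 0.003)
  expect_true(ks["ks_stat"] >= 0 && ks["ks_stat"] <= 1)
  set.seed(51)
  pvals <- replicate(200, ks_against_matched_normal(rnorm(160))[["ks_p"]])
  expect_gt(median(pvals), 0.2)
  expect_error(ks_against_matched_normal(rep(1, 20)))
})

test_that("tetrad segregation profile counts strictly-above-mean spores", {
  p <- tetrad_panel(matrix(1, 40, 4))
  expect_equal(unname(tetrad_segregation_profile(p)), c(1, 0, 0, 0, 0))
  # 3:1 pattern: 3 spores high, 1 low in every tetrad
  p31 <- tetrad_panel(matrix(rep(c(1, 1, 1, 0), 40), ncol = 4,
                             byrow = TRUE))
  expect_equal(unname(tetrad_segregation_profile(p31)), c(0, 0, 0, 1, 0))
  f <- tetrad_segregation_profile(sim_panel(0.5, seed = 5))
  expect_equal(sum(f), 1)
  expect_error(tetrad_segregation_profile(
    tetrad_panel(matrix(NA_real_, 4, 4))))
})

test_that("feature extraction yields 24 finite, ordered, deterministic features", {
  p <- sim_panel(0.7, seed = 6)
  f <- extract_features(p)
  expect_length(f, 24L)
  expect_identical(names(f), feature_names())
  expect_true(all(is.finite(f)))
  q <- f[paste0("q", seq(0, 100, 10))]
  expect_true(all(diff(q) >= 0))
  expect_equal(unname(f["q0"]), min(p$values))
  expect_equal(unname(f["q100"]), max(p$values))
  expect_equal(sum(f[paste0("tetrad_freq_", 0:4)]), 1)
  expect_identical(f, extract_features(p))
})

test_that("features are invariant to spore order within tetrads", {
  p <- sim_panel(0.9, seed = 7)
  f1 <- extract_features(p)
  set.seed(8)
  p2 <- p
  for (i in seq_len(nrow(p2$values)))
    p2$values[i, ] <- p2$values[i, sample(4)]
  expect_equal(extract_features(p2), f1)
})

test_that("constant panels produce flagged sentinel features", {
  p <- tetrad_panel(matrix(0.3, 40, 4))
  f <- extract_features(p)
  expect_true(all(is.finite(f)))
  expect_true(all(f[paste0("q", seq(0, 100, 10))] == 0.3))
  expect_equal(unname(f["mix_stat"]), 0)
  expect_equal(unname(f["ashman_d"]), 0)
  expect_equal(unname(f["ks_stat"]), 0)
  expect_equal(unname(f["ks_p"]), 1)
  expect_equal(unname(f[paste0("tetrad_freq_", 0:4)]), c(1, 0, 0, 0, 0))
})

test_that("mode separation grows with the primary-gene weight", {
  set.seed(61)
  mean_d <- vapply(c(0, 0.5, 1), function(w) {
    mean(replicate(100, {
      g <- simulate_tetrad_genotypes(40, 101)
      a <- assign_architecture(w, noise_sd = 0.02)
      as.numeric(ashman_d(fit_two_component_mixture(
        as.vector(compute_phenotypes(g, a)$values))))
    }))
  }, numeric(1))
  expect_true(all(diff(mean_d) > 0))
})
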