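#' Fit a two-component normal mixture by EM
#'
#' Deterministic expectation-maximisation fit of a two-component Gaussian
#' mixture. Initialisation is data-driven and deterministic: component
#' means at the 25th and 75th percentiles, equal mixing proportions, both
#' standard deviations at the pooled sample value. Component variances are
#' floored at `1e-6 * var(values)` to prevent collapse onto single points.
#' Components are reported ordered by mean.
#'
#' @param values numeric vector (at least 8 finite values).
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations.
#' @return Object of class `mixture_fit`: `mu1 <= mu2`, `sd1`, `sd2`,
#'   `pi1` (mixing proportion of the lower component), `loglik`,
#'   `loglik_trace` (per-iteration log-likelihoods), `converged`,
#'   `degenerate`, `n_iter`, and the per-observation posterior membership
#'   of the lower component in `posterior1`.
#'   Constant input yields a degenerate (flagged, non-converged) fit
#'   rather than an error.
#' @examples
#' x <- c(rnorm(80, 0, 0.01), rnorm(80, 1, 0.01))
#' fit_two_component_mixture(x)
#' @export
fit_two_component_mixture <- function(values, tol = 1e-8, max_iter = 500L) {
  x <- values[!is.na(values)]
  if (length(x) < 8L) stop("need at least 8 values for a mixture fit")
  if (any(!is.finite(x))) stop("values must be finite")
  n <- length(x)
  v <- var(x)
  if (v == 0) {
    return(structure(
      list(mu1 = x[1L], mu2 = x[1L], sd1 = 0, sd2 = 0, pi1 = 0.5,
           loglik = NA_real_, loglik_trace = numeric(0), converged = FALSE,
           degenerate = TRUE, n_iter = 0L, posterior1 = rep(0.5, n)),
      class = "mixture_fit"))
  }
  vfloor <- 1e-6 * v
  mu <- as.numeric(quantile(x, c(0.25, 0.75), names = FALSE))
  s2 <- c(v, v)
  pi1 <- 0.5
  ll_old <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d1 <- pi1 * dnorm(x, mu[1L], sqrt(s2[1L]))
    d2 <- (1 - pi1) * dnorm(x, mu[2L], sqrt(s2[2L]))
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    if (iter > max_iter) break
    ll_old <- ll
    g1 <- d1 / tot
    n1 <- sum(g1); n2 <- n - n1
    if (n1 < 1e-10 || n2 < 1e-10) break     # a component emptied out
    mu[1L] <- sum(g1 * x) / n1
    mu[2L] <- sum((1 - g1) * x) / n2
    s2[1L] <- max(sum(g1 * (x - mu[1L])^2) / n1, vfloor)
    s2[2L] <- max(sum((1 - g1) * (x - mu[2L])^2) / n2, vfloor)
    pi1 <- n1 / n
  }
  g1 <- pi1 * dnorm(x, mu[1L], sqrt(s2[1L])) /
    pmax(pi1 * dnorm(x, mu[1L], sqrt(s2[1L])) +
           (1 - pi1) * dnorm(x, mu[2L], sqrt(s2[2L])),
         .Machine$double.xmin)
  if (mu[1L] > mu[2L]) {                    # order components by mean
    mu <- rev(mu); s2 <- rev(s2); pi1 <- 1 - pi1; g1 <- 1 - g1
  }
  structure(
    list(mu1 = mu[1L], mu2 = mu[2L], sd1 = sqrt(s2[1L]), sd2 = sqrt(s2[2L]),
         pi1 = pi1, loglik = ll, loglik_trace = ll_trace,
         converged = converged, degenerate = FALSE,
         n_iter = iter, posterior1 = g1),
    class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate two-component mixture fit (constant data)\n")
  } else {
    cat(sprintf(
      "Two-component normal mixture: mu = (%.4f, %.4f), sd = (%.4f, %.4f)\n",
      x$mu1, x$mu2, x$sd1, x$sd2))
    cat(sprintf("  pi1 = %.3f, loglik = %.3f, %sconverged in %d iterations\n",
                x$pi1, x$loglik, if (x$converged) "" else "NOT ", x$n_iter))
  }
  invisible(x)
}

single_normal_loglik <- function(x, vfloor) {
  s <- sqrt(max(mean((x - mean(x))^2), vfloor))
  sum(dnorm(x, mean(x), s, log = TRUE))
}

#' Two-versus-one component mixture test statistic
#'
#' Penalised likelihood-ratio statistic `2 * (loglik_2 - loglik_1)`
#' comparing the two-component mixture fit against the maximum-likelihood
#' single normal, with the same variance floor applied to both models and
#' the statistic clipped at zero. Large values indicate bimodality; the
#' statistic is used as a monotone bimodality score, not as a calibrated
#' test.
#'
#' @param values the data both models were fitted to.
#' @param fit a `mixture_fit` for `values`; refitted if missing.
#' @return Non-negative statistic; 0 (with attribute `degenerate = TRUE`)
#'   for degenerate fits.
#' @export
mixture_test_statistic <- function(values, fit = NULL) {
  x <- values[!is.na(values)]
  if (is.null(fit)) fit <- fit_two_component_mixture(x)
  if (isTRUE(fit$degenerate) || !is.finite(fit$loglik))
    return(structure(0, degenerate = TRUE))
  ll1 <- single_normal_loglik(x, vfloor = 1e-6 * var(x))
  max(0, 2 * (fit$loglik - ll1))
}

#' Ashman's D mode-separation statistic
#'
#' `D = sqrt(2) * |mu1 - mu2| / sqrt(sd1^2 + sd2^2)` for a two-component
#' mixture fit; `D > 2` indicates clearly separated modes. Invariant under
#' affine rescaling of the data.
#'
#' @param fit a `mixture_fit`.
#' @return Non-negative statistic; 0 (flagged) for degenerate fits.
#' @examples
#' ashman_d(structure(list(mu1 = 0, mu2 = 2, sd1 = 1, sd2 = 1,
#'                         degenerate = FALSE), class = "mixture_fit"))  # 2
#' @export
ashman_d <- function(fit) {
  if (isTRUE(fit$degenerate)) return(structure(0, degenerate = TRUE))
  s <- fit$sd1^2 + fit$sd2^2
  if (s == 0) return(structure(0, degenerate = TRUE))
  sqrt(2) * abs(fit$mu1 - fit$mu2) / sqrt(s)
}

#' Kolmogorov-Smirnov comparison against a matched normal
#'
#' Two-sided KS test of the values against a normal distribution with the
#' sample's own mean and variance. Ties (expected for clamped growth
#' ratios) make the p-value approximate; it is used as a feature, not as
#' an inferential test.
#'
#' @param values numeric vector (at least 8 values, nonzero variance).
#' @return Named numeric: `ks_stat`, `ks_p`.
#' @export
ks_against_matched_normal <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 8L) stop("need at least 8 values")
  s <- sd(x)
  if (s == 0) stop("zero variance: matched normal undefined")
  kt <- suppressWarnings(ks.test(x, "pnorm", mean(x), s))
  c(ks_stat = unname(kt$statistic), ks_p = unname(kt$p.value))
}

#' Tetrad segregation profile
#'
#' For each complete tetrad, counts the spores whose phenotype is strictly
#' greater than the panel-wide mean phenotype, and returns the frequency of
#' tetrads with 0, 1, 2, 3 and 4 such spores. A noiseless monogenic trait
#' gives profile (0, 0, 1, 0, 0) — every tetrad 2:2. Ties at the mean
#' count as not above, so a constant panel gives (1, 0, 0, 0, 0).
#'
#' @param panel a [tetrad_panel()] (incomplete tetrads are dropped; at
#'   least one complete tetrad required).
#' @return Numeric length-5 vector of frequencies summing to 1, named
#'   `tetrad_freq_0` ... `tetrad_freq_4`.
#' @export
tetrad_segregation_profile <- function(panel) {
  v <- panel_values(panel, complete_only = TRUE)
  if (nrow(v) == 0L) stop("no complete tetrads in panel")
  m <- mean(panel$values, na.rm = TRUE)
  counts <- rowSums(v > m)
  freq <- tabulate(counts + 1L, nbins = 5L) / nrow(v)
  setNames(freq, paste0("tetrad_freq_", 0:4))
}

#' Canonical feature names
#'
#' The 24 features of a phenotype distribution, in the fixed order used by
#' the classifier: the 11 growth-ratio quantiles at 0%, 10%, ..., 100%;
#' the two mixture-component means and standard deviations; the penalised
#' two-vs-one-component likelihood-ratio statistic; Ashman's D; the KS
#' statistic and p-value against a matched normal; and the five tetrad
#' segregation profile frequencies. Column order is part of the model
#' contract and is stored inside trained models.
#'
#' @return Character vector of length 24.
#' @export
feature_names <- function() {
  c(paste0("q", seq(0, 100, by = 10)),
    "mix_mu1", "mix_mu2", "mix_sd1", "mix_sd2", "mix_stat",
    "ashman_d", "ks_stat", "ks_p",
    paste0("tetrad_freq_", 0:4))
}

#' Extract the 24-feature representation of a panel
#'
#' Assembles the feature vector listed in [feature_names()]. Degenerate
#' sub-computations (constant data, collapsed mixture) produce flagged
#' sentinel values — 0 for statistics and 1 for p-values — never
#' non-finite entries. Extraction is deterministic given the panel.
#'
#' @param panel a [tetrad_panel()], or a plain numeric vector whose length
#'   is a multiple of 4 (treated as complete tetrads).
#' @return Named numeric vector of length 24.
#' @export
extract_features <- function(panel) {
  if (!inherits(panel, "tetrad_panel")) panel <- tetrad_panel(panel)
  x <- panel$values[!is.na(panel$values)]
  if (length(x) < 8L) stop("too few observed phenotypes in panel")
  if (any(!is.finite(x))) stop("phenotypes must be finite")
  q <- quantile(x, probs = seq(0, 1, by = 0.1), names = FALSE, type = 7)
  if (var(x) == 0) {
    mix <- c(mix_mu1 = x[1L], mix_mu2 = x[1L], mix_sd1 = 0, mix_sd2 = 0,
             mix_stat = 0)
    ash <- 0
    ks <- c(ks_stat = 0, ks_p = 1)
  } else {
    fit <- fit_two_component_mixture(x)
    mix <- c(mix_mu1 = fit$mu1, mix_mu2 = fit$mu2, mix_sd1 = fit$sd1,
             mix_sd2 = fit$sd2,
             mix_stat = as.numeric(mixture_test_statistic(x, fit)))
    ash <- as.numeric(ashman_d(fit))
    ks <- ks_against_matched_normal(x)
  }
  out <- c(setNames(q, paste0("q", seq(0, 100, by = 10))),
           mix, ashman_d = ash, ks,
           tetrad_segregation_profile(panel))
  names(out) <- feature_names()
  out
}

#' Feature matrix for a list of panels
#'
#' @param panels list of [tetrad_panel()] objects or a `labeled_panels`
#'   training set.
#' @return Numeric matrix, one row per panel, 24 canonical columns.
#' @export
extract_feature_matrix <- function(panels) {
  if (inherits(panels, "labeled_panels")) panels <- panels$panels
  m <- t(vapply(panels, extract_features, numeric(24L)))
  colnames(m) <- feature_names()
  m
}
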