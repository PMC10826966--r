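#' Place parental phenotypes relative to the two modes
#'
#' Under a mixture fit, each parent is assigned to the lower or upper
#' component by maximum posterior probability; a parent whose maximum
#' posterior is below 0.6 sits between the modes and is called
#' `"intermediate"` (a parent exactly at the posterior-equality point is
#' therefore intermediate). Under the density fallback a parent is placed
#' by which side of the valley threshold it falls on. Absent parent
#' values give `"missing"`.
#'
#' @param fit a `mixture_fit`, or a single numeric threshold (the density
#'   fallback valley).
#' @param parent_values numeric length-2 vector.
#' @return Character vector of length 2 with values in
#'   `c("low", "high", "intermediate", "missing")`.
#' @export
assign_parental_modes <- function(fit, parent_values) {
  place_one <- function(p) {
    if (is.na(p)) return("missing")
    if (inherits(fit, "mixture_fit")) {
      d1 <- fit$pi1 * dnorm(p, fit$mu1, max(fit$sd1, 1e-12))
      d2 <- (1 - fit$pi1) * dnorm(p, fit$mu2, max(fit$sd2, 1e-12))
      if (d1 + d2 == 0) {                      # far outside both components
        return(if (abs(p - fit$mu1) <= abs(p - fit$mu2)) "low" else "high")
      }
      post1 <- d1 / (d1 + d2)
      if (max(post1, 1 - post1) < 0.6) return("intermediate")
      if (post1 >= 0.6) "low" else if (post1 <= 0.4) "high" else "intermediate"
    } else {
      if (p < fit) "low" else if (p > fit) "high" else "intermediate"
    }
  }
  vapply(parent_values, place_one, character(1L))
}

#' Density-valley fallback for mode separation
#'
#' When the two-component mixture cannot be fit (degenerate or
#' non-converged), modes are located on a Gaussian kernel density estimate
#' (Silverman's bandwidth, fixed 512-point grid): local maxima are grid
#' points where the numerical derivative changes sign, and if at least two
#' peaks exist the threshold separating the spore groups is the grid
#' minimum of the density between the two highest peaks.
#'
#' @param values numeric vector (at least 8 values).
#' @return List with `n_peaks`, `threshold` (`NA` if unimodal), `p_low`
#'   (fraction of values strictly below the threshold; `NA` if unimodal)
#'   and `peaks` (phenotype positions of the detected peaks).
#' @export
density_peak_fallback <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 8L) stop("need at least 8 values")
  d <- density(x, bw = "nrd0", n = 512L)
  dy <- diff(d$y)
  s <- sign(dy)
  # peak where the derivative goes from positive to non-positive
  peak_idx <- which(s[-1] <= 0 & s[-length(s)] > 0) + 1L
  if (d$y[1L] > d$y[2L]) peak_idx <- c(1L, peak_idx)
  if (d$y[512L] > d$y[511L]) peak_idx <- c(peak_idx, 512L)
  if (length(peak_idx) < 2L) {
    return(list(n_peaks = length(peak_idx), threshold = NA_real_,
                p_low = NA_real_, peaks = d$x[peak_idx]))
  }
  top2 <- sort(peak_idx[order(d$y[peak_idx], decreasing = TRUE)][1:2])
  between <- seq(top2[1L], top2[2L])
  valley <- between[which.min(d$y[between])]
  thr <- d$x[valley]
  list(n_peaks = length(peak_idx), threshold = thr,
       p_low = mean(x < thr), peaks = d$x[peak_idx])
}

#' Classify the genetic complexity of one phenotype distribution
#'
#' Applies the full decision tree to a tetrad panel:
#' \enumerate{
#'   \item \emph{Callability}: the panel is `undetermined` when growth is
#'     essentially absent (at least `no_growth_frac` of segregant ratios
#'     below `no_growth_ratio`) or the phenotypes carry no variance.
#'   \item \emph{Bimodality}: the random forest predicts the primary-gene
#'     weight from the 24 features; a prediction below the calibrated
#'     threshold means unimodal, hence a `complex` trait.
#'   \item \emph{Mode structure}: for bimodal panels, a two-component
#'     mixture (or, when it fails, the density-valley fallback) yields the
#'     proportion of segregants in the lower mode and the parental
#'     placements. A balanced split (`p_low` within `mono_window`,
#'     matching 2:2 tetrad segregation of a single locus) with the two
#'     parents on opposite modes is `monogenic`; any other bimodal pattern
#'     (3:1/0:4-like proportions, parents on the same mode or between the
#'     modes) is `oligogenic`.
#' }
#'
#' @param panel a [tetrad_panel()].
#' @param model a calibrated `complexity_model`.
#' @param mono_window lower-mode proportion window for a monogenic call
#'   (default `c(0.4, 0.6)`, about 2.5 binomial standard deviations around
#'   0.5 for 160 segregants).
#' @param no_growth_ratio,no_growth_frac,min_variance callability
#'   thresholds.
#' @return Object of class `complexity_call`: list with `level`,
#'   `subtype`, `predicted_w1`, `bimodal`, `p_low`, `parent_modes`,
#'   `method`, `cross_id`, `condition`.
#' @export
classify_complexity <- function(panel, model,
                                mono_window = c(0.4, 0.6),
                                no_growth_ratio = 0.05,
                                no_growth_frac = 0.8,
                                min_variance = 1e-6) {
  if (!inherits(panel, "tetrad_panel")) stop("'panel' must be a tetrad_panel")
  if (!inherits(model, "complexity_model") || is.na(model$threshold))
    stop("'model' must be a calibrated complexity_model")
  x <- panel$values[!is.na(panel$values)]
  call <- list(level = "undetermined", subtype = "no_growth",
               predicted_w1 = NA_real_, bimodal = NA, p_low = NA_real_,
               parent_modes = c("missing", "missing"),
               method = "not_applicable",
               cross_id = panel$cross_id, condition = panel$condition)
  class(call) <- "complexity_call"
  if (mean(x < no_growth_ratio) >= no_growth_frac) return(call)
  if (var(x) < min_variance) { call$subtype <- "no_variance"; return(call) }

  pw <- predict_bimodality(model, extract_features(panel))
  call$predicted_w1 <- pw
  if (pw < model$threshold) {
    call$level <- "complex"
    call$subtype <- "unimodal"
    call$bimodal <- FALSE
    call$method <- "not_applicable"
    return(call)
  }
  call$bimodal <- TRUE
  fit <- fit_two_component_mixture(x)
  if (!fit$degenerate && fit$converged) {
    call$method <- "mixture"
    call$p_low <- fit$pi1
    call$parent_modes <- assign_parental_modes(fit, panel$parent_values)
  } else {
    fb <- density_peak_fallback(x)
    if (fb$n_peaks >= 2L) {
      call$method <- "density_fallback"
      call$p_low <- fb$p_low
      call$parent_modes <- assign_parental_modes(fb$threshold,
                                                 panel$parent_values)
    } else {
      # forest says bimodal but no second mode is resolvable
      call$level <- "oligogenic"
      call$subtype <- "bimodal_unresolved_modes"
      call$method <- "density_fallback"
      return(call)
    }
  }
  balanced <- call$p_low >= mono_window[1L] && call$p_low <= mono_window[2L]
  opposite <- setequal(call$parent_modes, c("low", "high"))
  same_mode <- all(call$parent_modes == "low") ||
    all(call$parent_modes == "high")
  if (balanced && opposite) {
    call$level <- "monogenic"
    call$subtype <- "bimodal_balanced_parents_opposite"
  } else {
    call$level <- "oligogenic"
    call$subtype <-
      if (!balanced) "bimodal_unbalanced"
      else if (same_mode) "bimodal_parents_same_mode"
      else if (any(call$parent_modes == "intermediate"))
        "bimodal_parent_intermediate"
      else "bimodal_parent_missing"
  }
  call
}

#' @export
print.complexity_call <- function(x, ...) {
  cat(sprintf("Complexity call for %s / %s: %s (%s)\n",
              x$cross_id, x$condition, x$level, x$subtype))
  if (!is.na(x$predicted_w1))
    cat(sprintf("  predicted w1 = %.3f; p_low = %s; parents %s/%s; method %s\n",
                x$predicted_w1,
                ifelse(is.na(x$p_low), "NA", sprintf("%.3f", x$p_low)),
                x$parent_modes[1L], x$parent_modes[2L], x$method))
  invisible(x)
}

#' Classify a list of panels into a calls table
#'
#' @param panels list of [tetrad_panel()] objects.
#' @param model a calibrated `complexity_model`.
#' @param ... passed to [classify_complexity()].
#' @return data.frame with columns `cross_id`, `condition`, `level`,
#'   `subtype`, `predicted_w1`, `p_low`, `parent_mode_1`, `parent_mode_2`,
#'   `method`.
#' @export
classify_panels <- function(panels, model, ...) {
  if (inherits(panels, "tetrad_panel")) panels <- list(panels)
  rows <- lapply(panels, function(p) {
    cl <- classify_complexity(p, model, ...)
    data.frame(cross_id = cl$cross_id, condition = cl$condition,
               level = cl$level, subtype = cl$subtype,
               predicted_w1 = cl$predicted_w1, p_low = cl$p_low,
               parent_mode_1 = cl$parent_modes[1L],
               parent_mode_2 = cl$parent_modes[2L],
               method = cl$method, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
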