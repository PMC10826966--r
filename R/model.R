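#' Train the random-forest bimodality model
#'
#' Fits a regression forest of `n_trees` trees mapping the 24 canonical
#' distribution features to the true primary-gene weight `w1` of simulated
#' panels. The predicted weight is later used as a bimodality score: a
#' large primary weight is the main determinant of a bimodal segregant
#' distribution.
#'
#' @param training_set a `labeled_panels` object from
#'   [generate_training_set()], or a list with elements `features`
#'   (matrix with the 24 canonical columns) and `w1`.
#' @param n_trees number of trees (default 100).
#' @param seed optional integer seed (forest bootstrap).
#' @return Object of class `complexity_model` (uncalibrated: `threshold`
#'   is `NA` until [calibrate_threshold()] is applied).
#' @export
train_bimodality_model <- function(training_set, n_trees = 100L,
                                   seed = NULL) {
  if (inherits(training_set, "labeled_panels")) {
    features <- extract_feature_matrix(training_set)
    w1 <- training_set$w1
  } else {
    features <- training_set$features
    w1 <- training_set$w1
  }
  if (is.null(features) || is.null(w1) || nrow(features) != length(w1))
    stop("features and w1 labels must have matching lengths")
  if (!identical(colnames(features), feature_names()))
    stop("feature matrix must have the 24 canonical columns in order")
  if (!is.null(seed)) set.seed(seed)
  forest <- randomForest::randomForest(x = features, y = w1,
                                       ntree = n_trees)
  structure(
    list(forest = forest,
         feature_order = feature_names(),
         threshold = NA_real_,
         calibration = NULL,
         training_meta = list(n_panels = length(w1), n_trees = n_trees,
                              seed = seed,
                              randomForest_version =
                                as.character(utils::packageVersion("randomForest")))),
    class = "complexity_model")
}

#' Predict the primary-gene weight (bimodality score) of a panel
#'
#' @param model a `complexity_model`.
#' @param features a 24-feature vector from [extract_features()], or a
#'   matrix of such rows.
#' @return Predicted primary-gene weight(s), clipped to `[0, 1]`.
#' @export
predict_bimodality <- function(model, features) {
  if (!inherits(model, "complexity_model"))
    stop("'model' must be a complexity_model")
  if (is.vector(features)) features <- matrix(features, nrow = 1L,
                                              dimnames = list(NULL, names(features)))
  if (ncol(features) != length(model$feature_order))
    stop("expected ", length(model$feature_order), " features, got ",
         ncol(features))
  if (!is.null(colnames(features))) {
    if (!setequal(colnames(features), model$feature_order))
      stop("feature names do not match the model's feature order")
    features <- features[, model$feature_order, drop = FALSE]
  }
  p <- predict(model$forest, newdata = features)
  pmin(1, pmax(0, as.numeric(p)))
}

#' Calibrate the bimodality threshold on labeled panels
#'
#' Builds the ROC curve of the model's predicted primary-gene weight
#' against binary bimodal/unimodal labels, reports the area under the
#' curve, and selects the threshold that is an equal compromise between
#' sensitivity and specificity: the cutoff minimising
#' `|sensitivity - specificity|`, ties resolved to the lowest cutoff.
#'
#' @param model a `complexity_model`.
#' @param panels list of [tetrad_panel()] objects, a `labeled_panels`
#'   object, or a precomputed feature matrix.
#' @param bimodal logical vector of labels (TRUE = bimodal).
#' @return The input model with `threshold` set and a `calibration` list
#'   (`auc`, `threshold`, `sensitivity_at_threshold`,
#'   `specificity_at_threshold`, `n_labeled`, and the full ROC
#'   coordinates).
#' @export
calibrate_threshold <- function(model, panels, bimodal) {
  if (is.matrix(panels)) features <- panels
  else features <- extract_feature_matrix(panels)
  bimodal <- as.logical(bimodal)
  if (nrow(features) != length(bimodal))
    stop("labels must match the number of panels")
  if (length(unique(bimodal)) < 2L)
    stop("calibration requires both bimodal and unimodal labels")
  pred <- predict_bimodality(model, features)
  roc <- pROC::roc(response = bimodal, predictor = pred,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ok <- is.finite(roc$thresholds)
  th <- roc$thresholds[ok]
  se <- roc$sensitivities[ok]
  sp <- roc$specificities[ok]
  gap <- abs(se - sp)
  cand <- which(gap == min(gap))
  pick <- cand[which.min(th[cand])]          # ties -> lowest cutoff
  model$threshold <- min(1, max(0, th[pick]))
  model$calibration <- list(
    auc = as.numeric(pROC::auc(roc)),
    threshold = model$threshold,
    sensitivity_at_threshold = se[pick],
    specificity_at_threshold = sp[pick],
    n_labeled = length(bimodal),
    roc = data.frame(threshold = th, sensitivity = se, specificity = sp))
  model
}

#' Fit a calibrated trait-complexity model
#'
#' One-stop model fit: simulates a labeled training corpus of tetrad
#' phenotype distributions, trains the 100-tree random forest predicting
#' the primary-gene weight, simulates an independent labeled calibration
#' set with weights drawn from `w1 < unimodal_max` (unimodal) and
#' `w1 > bimodal_min` (bimodal), and calibrates the bimodality threshold
#' on its ROC curve. Defaults reproduce the full-scale training design
#' (25,000 + 12,500 + 12,500 panels); scale the counts down for quick
#' exploratory fits.
#'
#' @param n_none,n_recessive,n_dominant training-set composition, passed
#'   to [generate_training_set()].
#' @param n_calibration number of calibration panels (half unimodal, half
#'   bimodal; epistasis modes in the same 2:1:1 proportion as training).
#' @param unimodal_max,bimodal_min calibration label design: unimodal
#'   panels draw `w1` uniformly on `[0, unimodal_max]`, bimodal panels on
#'   `[bimodal_min, 1]`.
#' @param n_trees forest size.
#' @param noise_sd phenotype noise standard deviation for the simulations.
#' @param seed integer seed controlling simulation and forest bootstrap.
#' @return A calibrated `complexity_model`.
#' @examples
#' \donttest{
#' m <- fit_complexity_model(n_none = 300, n_recessive = 150,
#'                           n_dominant = 150, n_calibration = 200,
#'                           seed = 1)
#' print(m)
#' }
#' @export
fit_complexity_model <- function(n_none = 25000L, n_recessive = 12500L,
                                 n_dominant = 12500L,
                                 n_calibration = 2000L,
                                 unimodal_max = 0.3, bimodal_min = 0.7,
                                 n_trees = 100L, noise_sd = 0.05,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  training <- generate_training_set(n_none, n_recessive, n_dominant,
                                    noise_sd = noise_sd)
  model <- train_bimodality_model(training, n_trees = n_trees)
  cal <- simulate_calibration_set(n_calibration, unimodal_max, bimodal_min,
                                  noise_sd = noise_sd)
  model <- calibrate_threshold(model, cal$panels, cal$bimodal)
  model$training_meta$seed <- seed
  model$training_meta$noise_sd <- noise_sd
  model
}

#' Simulate a labeled bimodal/unimodal calibration set
#'
#' Panels whose true primary-gene weight is drawn away from the ambiguous
#' middle range: half with `w1` uniform on `[0, unimodal_max]` (labeled
#' unimodal) and half on `[bimodal_min, 1]` (labeled bimodal), epistasis
#' modes mixed 2:1:1 as in training.
#'
#' @inheritParams fit_complexity_model
#' @param n total number of panels.
#' @param seed optional integer seed.
#' @return List with `panels`, `w1`, `mode`, `bimodal` (logical labels).
#' @export
simulate_calibration_set <- function(n, unimodal_max = 0.3,
                                     bimodal_min = 0.7, noise_sd = 0.05,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_lo <- n %/% 2L
  n_hi <- n - n_lo
  sampler <- local({
    # permuted so that label and epistasis mode are not confounded
    lows <- sample(c(rep(TRUE, n_lo), rep(FALSE, n_hi)))
    function(k) ifelse(lows[seq_len(k)],
                       runif(k, 0, unimodal_max),
                       runif(k, bimodal_min, 1))
  })
  counts <- round(n * c(0.5, 0.25, 0.25))
  counts[1L] <- n - sum(counts[-1L])
  ts <- generate_training_set(counts[1L], counts[2L], counts[3L],
                              w1_sampler = sampler, noise_sd = noise_sd)
  # generate_training_set orders panels by mode, so re-derive labels from w1
  list(panels = ts$panels, w1 = ts$w1, mode = ts$mode,
       bimodal = ts$w1 >= bimodal_min)
}

#' @export
print.complexity_model <- function(x, ...) {
  cat("Trait-complexity model (random-forest bimodality score)\n")
  cat(sprintf("  forest: %d regression trees on %d features, trained on %d panels\n",
              x$forest$ntree, length(x$feature_order),
              x$training_meta$n_panels))
  if (is.na(x$threshold)) {
    cat("  threshold: not calibrated\n")
  } else {
    cat(sprintf("  threshold: %.3f (AUC %.3f; sens %.3f / spec %.3f on %d labeled panels)\n",
                x$threshold, x$calibration$auc,
                x$calibration$sensitivity_at_threshold,
                x$calibration$specificity_at_threshold,
                x$calibration$n_labeled))
  }
  invisible(x)
}

#' @export
summary.complexity_model <- function(object, ...) {
  print(object)
  imp <- randomForest::importance(object$forest)
  ord <- order(imp[, 1L], decreasing = TRUE)
  cat("  top feature importances (IncNodePurity):\n")
  for (i in head(ord, 6L))
    cat(sprintf("    %-14s %10.2f\n", rownames(imp)[i], imp[i, 1L]))
  invisible(object)
}

#' Predict from a trait-complexity model
#'
#' @param object a `complexity_model`.
#' @param newdata a [tetrad_panel()], a list of panels, a `labeled_panels`
#'   object, or a 24-column feature matrix.
#' @param type `"w1"` for the predicted primary-gene weight (bimodality
#'   score); `"call"` for full complexity calls (requires calibration; see
#'   [classify_complexity()]).
#' @param ... unused.
#' @return Numeric vector of predicted weights, or for `type = "call"` a
#'   data.frame of complexity calls (one row per panel).
#' @export
predict.complexity_model <- function(object, newdata,
                                     type = c("w1", "call"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "tetrad_panel")) newdata <- list(newdata)
  if (type == "w1") {
    features <- if (is.matrix(newdata)) newdata
                else extract_feature_matrix(newdata)
    return(predict_bimodality(object, features))
  }
  if (is.matrix(newdata))
    stop("type = 'call' needs panels (parental phenotypes and tetrads), not a feature matrix")
  if (inherits(newdata, "labeled_panels")) newdata <- newdata$panels
  classify_panels(newdata, object)
}

#' Plot the calibration ROC curve of a complexity model
#'
#' @param x a calibrated `complexity_model`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.complexity_model <- function(x, ...) {
  if (is.null(x$calibration)) stop("model is not calibrated")
  roc <- x$calibration$roc
  ord <- order(1 - roc$specificity, roc$sensitivity)
  plot(1 - roc$specificity[ord], roc$sensitivity[ord], type = "l",
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("Bimodality ROC (AUC = %.3f)", x$calibration$auc),
       ...)
  abline(0, 1, lty = 3)
  i <- which.min(abs(roc$threshold - x$threshold))
  graphics::points(1 - roc$specificity[i], roc$sensitivity[i], pch = 19)
  invisible(x)
}

#' Persist a complexity model
#'
#' Models serialise with their feature order, calibration threshold and
#' training metadata; loading validates the feature-order contract.
#'
#' @param model a `complexity_model`.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  if (!inherits(model, "complexity_model"))
    stop("'model' must be a complexity_model")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "complexity_model"))
    stop("file does not contain a complexity_model")
  if (!identical(model$feature_order, feature_names()))
    stop("model feature order does not match this package's canonical features")
  model
}
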