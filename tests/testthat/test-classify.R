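test_that("the trained forest has the contracted shape and is reproducible", {
  ts <- scaled_training()
  fm <- extract_feature_matrix(ts)
  m1 <- train_bimodality_model(list(features = fm, w1 = ts$w1), seed = 77)
  m2 <- train_bimodality_model(list(features = fm, w1 = ts$w1), seed = 77)
  expect_equal(m1$forest$ntree, 100L)
  expect_identical(m1$feature_order, feature_names())
  probe <- fm[1:20, , drop = FALSE]
  expect_identical(predict_bimodality(m1, probe),
                   predict_bimodality(m2, probe))
  expect_error(train_bimodality_model(list(features = fm,
                                           w1 = ts$w1[-1])))
})

test_that("predicted weights track the truth on training panels", {
  ts <- scaled_training()
  m <- scaled_model()
  pred <- predict(m, ts$panels)
  expect_true(all(pred >= 0 & pred <= 1))
  expect_gt(cor(pred, ts$w1, method = "spearman"), 0.8)
  # planted extremes
  expect_gt(predict(m, sim_panel(1, noise_sd = 0, seed = 31)), 0.8)
  expect_lt(predict(m, sim_panel(0, seed = 32)), 0.3)
  expect_error(predict_bimodality(m, matrix(0, 1, 10)))
})

test_that("threshold calibration minimises the sensitivity-specificity gap", {
  m <- scaled_model()
  cal <- m$calibration
  expect_true(m$threshold >= 0 && m$threshold <= 1)
  expect_true(cal$auc >= 0.5 && cal$auc <= 1)
  gap <- abs(cal$roc$sensitivity - cal$roc$specificity)
  expect_equal(abs(cal$sensitivity_at_threshold -
                     cal$specificity_at_threshold), min(gap))
  # perfectly separated labels give AUC 1 and sens = spec = 1
  ts <- scaled_training()
  fm <- extract_feature_matrix(ts)
  sep <- ts$w1 < 0.2 | ts$w1 > 0.8
  m_sep <- calibrate_threshold(m, fm[sep, ], ts$w1[sep] > 0.5)
  expect_gt(m_sep$calibration$auc, 0.99)
  expect_error(calibrate_threshold(m, fm, rep(TRUE, nrow(fm))))
})

test_that("labels shuffled away from the predictions give chance AUC", {
  m <- scaled_model()
  ts <- scaled_training()
  fm <- extract_feature_matrix(ts)
  set.seed(55)
  shuffled <- sample(ts$w1 > 0.5)
  m_null <- calibrate_threshold(m, fm, shuffled)
  expect_lt(abs(m_null$calibration$auc - 0.5), 0.08)
})

test_that("parental placement follows the mixture posterior", {
  fit <- structure(list(mu1 = 0, mu2 = 1, sd1 = 0.1, sd2 = 0.1, pi1 = 0.5,
                        degenerate = FALSE), class = "mixture_fit")
  expect_equal(assign_parental_modes(fit, c(0, 1)), c("low", "high"))
  # the posterior-equality point is intermediate
  expect_equal(assign_parental_modes(fit, c(0.5, NA)),
               c("intermediate", "missing"))
  # parents far outside both components go to the nearest mode
  expect_equal(assign_parental_modes(fit, c(-30, -30)), c("low", "low"))
  # fallback threshold placement
  expect_equal(assign_parental_modes(0.5, c(0.1, 0.9)), c("low", "high"))
  expect_equal(assign_parental_modes(0.5, c(0.5, 0.5)),
               c("intermediate", "intermediate"))
})

test_that("density-valley fallback finds two separated spore groups", {
  set.seed(66)
  x <- c(rnorm(40, 0, 0.02), rnorm(120, 1, 0.02))
  fb <- density_peak_fallback(x)
  expect_gte(fb$n_peaks, 2L)
  expect_true(fb$threshold > 0 && fb$threshold < 1)
  expect_equal(fb$p_low, 0.25, tolerance = 0.02)
  peaks <- sort(fb$peaks[order(-abs(fb$peaks - fb$threshold))][1:2])
  expect_true(fb$threshold > min(fb$peaks) && fb$threshold < max(fb$peaks))
  # unimodal data: one peak, no threshold
  set.seed(67)
  fb1 <- density_peak_fallback(rnorm(160))
  expect_equal(fb1$n_peaks, 1L)
  expect_true(is.na(fb1$threshold))
  expect_error(density_peak_fallback(1:5))
})

test_that("the decision tree assigns the three complexity levels", {
  m <- scaled_model()
  # unimodal polygenic panel, parents at the middle -> complex
  set.seed(71)
  complex_panel <- tetrad_panel(matrix(rnorm(160, 0.5, 0.1), ncol = 4),
                                parent_values = c(0.5, 0.5))
  call_c <- classify_complexity(complex_panel, m)
  expect_equal(call_c$level, "complex")
  expect_false(call_c$bimodal)
  # planted strong monogenic with parents on opposite modes
  mono_panel <- sim_panel(0.9, noise_sd = 0.02, seed = 72)
  call_m <- classify_complexity(mono_panel, m)
  expect_equal(call_m$level, "monogenic")
  expect_true(call_m$bimodal)
  expect_true(call_m$p_low >= 0.4 && call_m$p_low <= 0.6)
  expect_setequal(call_m$parent_modes, c("low", "high"))
  # bimodal 1:3 split, parents on opposite modes -> oligogenic
  set.seed(73)
  v <- c(rnorm(40, 0, 0.03), rnorm(120, 1, 0.03))
  oligo_panel <- tetrad_panel(matrix(sample(v), ncol = 4),
                              parent_values = c(0, 1))
  call_o <- classify_complexity(oligo_panel, m)
  expect_equal(call_o$level, "oligogenic")
  expect_equal(call_o$subtype, "bimodal_unbalanced")
})

test_that("no-growth and invariant panels are undetermined", {
  m <- scaled_model()
  dead <- tetrad_panel(matrix(c(rep(0, 150), runif(10, 0, 0.04)),
                              ncol = 4), parent_values = c(1, 0))
  expect_equal(classify_complexity(dead, m)$level, "undetermined")
  flat <- tetrad_panel(matrix(0.8, 40, 4), parent_values = c(0.8, 0.8))
  expect_equal(classify_complexity(flat, m)$level, "undetermined")
})

test_that("every call satisfies the level-bimodality consistency contract", {
  m <- scaled_model()
  ts <- scaled_training()
  calls <- classify_panels(ts$panels[seq(1, 500, by = 10)], m)
  expect_true(all(calls$level %in% c("monogenic", "oligogenic", "complex",
                                     "undetermined")))
  for (i in seq_len(nrow(calls))) {
    if (calls$level[i] == "complex")
      expect_false(is.na(calls$predicted_w1[i]) ||
                     calls$predicted_w1[i] >= m$threshold)
    if (calls$level[i] %in% c("monogenic", "oligogenic"))
      expect_gte(calls$predicted_w1[i], m$threshold)
  }
})

test_that("complexity calls are invariant to affine phenotype rescaling", {
  m <- scaled_model()
  set.seed(81)
  seeds <- sample.int(1e6, 50)
  w1s <- runif(50)
  agree <- vapply(seq_len(50), function(i) {
    p <- sim_panel(w1s[i], seed = seeds[i])
    p2 <- p
    p2$values <- p$values * 2
    p2$parent_values <- p$parent_values * 2
    classify_complexity(p, m)$level == classify_complexity(p2, m)$level
  }, logical(1))
  # quantile features shift under rescaling, so demand near-perfect but
  # not bitwise agreement
  expect_gte(mean(agree), 0.96)
})

test_that("model persistence round-trips and validates the feature order", {
  m <- scaled_model()
  path <- tempfile(fileext = ".rds")
  write_model(m, path)
  m2 <- read_model(path)
  probe <- extract_features(sim_panel(0.5, seed = 91))
  expect_identical(predict_bimodality(m, probe),
                   predict_bimodality(m2, probe))
  m_bad <- m
  m_bad$feature_order <- rev(m_bad$feature_order)
  path2 <- tempfile(fileext = ".rds")
  saveRDS(m_bad, path2)
  expect_error(read_model(path2), "feature order")
  unlink(c(path, path2))
})

test_that("model methods print, summarise and plot", {
  m <- scaled_model()
  expect_output(print(m), "threshold")
  expect_output(summary(m), "importances")
  pdf(NULL)
  expect_silent(plot(m))
  dev.off()
})
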