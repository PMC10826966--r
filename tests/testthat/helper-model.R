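# Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

# A scaled-down calibrated model: 800 training panels (2:1:1 modes),
# 400 calibration panels. Large enough to rank bimodality reliably,
# small enough to fit in seconds.
scaled_model <- function() {
  if (is.null(.cache$model))
    .cache$model <- fit_complexity_model(
      n_none = 400, n_recessive = 200, n_dominant = 200,
      n_calibration = 400, seed = 20260101)
  .cache$model
}

# A small labeled panel set reused by feature/classify tests.
scaled_training <- function() {
  if (is.null(.cache$training))
    .cache$training <- generate_training_set(250, 125, 125, seed = 42)
  .cache$training
}

# Simulate one panel with a given architecture, deterministic per seed.
sim_panel <- function(w1, mode = "none", noise_sd = 0.05, seed = 1,
                      n_tetrads = 40, n_loci = 101) {
  if (!is.null(seed)) set.seed(seed)
  g <- simulate_tetrad_genotypes(n_tetrads, n_loci)
  a <- assign_architecture(w1, mode, n_secondary = n_loci - 1,
                           noise_sd = noise_sd)
  compute_phenotypes(g, a)
}

# Tiny two-condition plan with planted architectures for pipeline tests.
small_plan <- function(classes = c("monogenic", "complex", "oligogenic"),
                       n_parents = 3, seed = 7, noise_sd = 0.05) {
  plan <- plan_half_diallel(sprintf("P%d", seq_len(n_parents)),
                            conditions = c("SC_ref", "drugA"))
  set.seed(seed)
  for (i in seq_len(nrow(plan$crosses))) {
    cls <- classes[((i - 1) %% length(classes)) + 1]
    arch <- switch(cls,
      monogenic = assign_architecture(runif(1, 0.9, 1), "none",
                                      noise_sd = noise_sd),
      oligogenic = assign_architecture(runif(1, 0.7, 0.9), "recessive",
                                       noise_sd = noise_sd),
      complex = assign_architecture(runif(1, 0, 0.1), "none",
                                    noise_sd = noise_sd))
    plan$planted_truth[[paste(plan$crosses$cross_id[i], "drugA",
                              sep = "\r")]] <-
      list(architecture = arch, true_class = cls)
  }
  plan
}
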