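#' Plan a half-diallel cross panel
#'
#' Crosses a set of parents in all pairwise combinations without
#' reciprocal or self crosses: `n` parents give `n * (n - 1) / 2` unique
#' crosses (20 parents give 190).
#'
#' @param parent_ids character vector of distinct parent identifiers
#'   (length at least 2).
#' @param conditions character vector of condition names; the first (or
#'   `reference_condition`) is the reference (no-compound) condition.
#' @param reference_condition which condition is the reference.
#' @param n_tetrads tetrads per cross (default 40, i.e. 160 segregants).
#' @param n_replicates colonies per strain x condition (default 2).
#' @return Object of class `panel_plan`: list with `parent_ids`, `crosses`
#'   (data.frame `cross_id`, `parent_1`, `parent_2`), `conditions`,
#'   `reference_condition`, `n_tetrads`, `n_replicates` and
#'   `planted_truth` (empty until [plant_architectures()]).
#' @examples
#' plan <- plan_half_diallel(sprintf("P%02d", 1:20))
#' nrow(plan$crosses)  # 190
#' @export
plan_half_diallel <- function(parent_ids,
                              conditions = c("SC_ref", "condition_1"),
                              reference_condition = conditions[1L],
                              n_tetrads = 40L, n_replicates = 2L) {
  parent_ids <- as.character(parent_ids)
  if (length(parent_ids) < 2L) stop("need at least 2 parents")
  if (anyDuplicated(parent_ids)) stop("duplicate parent ids")
  if (!reference_condition %in% conditions)
    stop("reference condition must be among the conditions")
  pairs <- t(utils::combn(parent_ids, 2L))
  crosses <- data.frame(
    cross_id = paste(pairs[, 1L], pairs[, 2L], sep = "x"),
    parent_1 = pairs[, 1L], parent_2 = pairs[, 2L],
    stringsAsFactors = FALSE)
  structure(
    list(parent_ids = parent_ids, crosses = crosses,
         conditions = conditions,
         reference_condition = reference_condition,
         n_tetrads = as.integer(n_tetrads),
         n_replicates = as.integer(n_replicates),
         planted_truth = list()),
    class = "panel_plan")
}

#' @export
print.panel_plan <- function(x, ...) {
  cat(sprintf(
    "Half-diallel plan: %d parents -> %d crosses, %d conditions (ref: %s)\n",
    length(x$parent_ids), nrow(x$crosses), length(x$conditions),
    x$reference_condition))
  cat(sprintf("  %d tetrads x 4 spores per cross, %d replicates; %d planted architectures\n",
              x$n_tetrads, x$n_replicates, length(x$planted_truth)))
  invisible(x)
}

planted_key <- function(cross_id, condition) paste(cross_id, condition,
                                                   sep = "\r")

#' Plant known-complexity architectures into a panel plan
#'
#' Assigns every cross x non-reference condition a genetic architecture of
#' a known complexity class, so that downstream classification can be
#' scored against ground truth. Class-specific drawing rules:
#' `monogenic` — non-epistatic, `w1` uniform on `[0.85, 1]`;
#' `oligogenic` — recessive or dominant epistasis (equal odds), `w1`
#' uniform on `[0.6, 0.95]` (two primary loci give 3:1/1:3-like mode
#' proportions); `complex` — non-epistatic, `w1` uniform on `[0, 0.15]`;
#' `no_growth` — a flagged architecture with no growth on the treatment
#' (downstream calls must be `undetermined`). The default class mix
#' mirrors the complexity spectrum observed across a natural yeast panel
#' (91.2% complex, 4.7% oligogenic, 4.1% monogenic).
#'
#' @param plan a `panel_plan`.
#' @param class_probs named probabilities over
#'   `c("complex", "oligogenic", "monogenic", "no_growth")` (missing names
#'   mean probability 0).
#' @param noise_sd phenotype noise standard deviation for the planted
#'   simulations.
#' @param seed optional integer seed.
#' @return The plan with `planted_truth` filled: per cross x condition a
#'   list with `architecture` and `true_class`.
#' @export
plant_architectures <- function(plan,
                                class_probs = c(complex = 0.912,
                                                oligogenic = 0.047,
                                                monogenic = 0.041),
                                noise_sd = 0.05, seed = NULL) {
  stopifnot(inherits(plan, "panel_plan"))
  if (!is.null(seed)) set.seed(seed)
  classes <- c("complex", "oligogenic", "monogenic", "no_growth")
  p <- setNames(numeric(4L), classes)
  p[names(class_probs)] <- class_probs
  p <- p / sum(p)
  treatment <- setdiff(plan$conditions, plan$reference_condition)
  for (cond in treatment) {
    for (cross in plan$crosses$cross_id) {
      cls <- sample(classes, 1L, prob = p)
      arch <- switch(cls,
        monogenic = assign_architecture(runif(1, 0.85, 1), "none",
                                        noise_sd = noise_sd),
        oligogenic = assign_architecture(runif(1, 0.6, 0.95),
                                         sample(c("recessive", "dominant"), 1L),
                                         noise_sd = noise_sd),
        complex = assign_architecture(runif(1, 0, 0.15), "none",
                                      noise_sd = noise_sd),
        no_growth = {
          a <- assign_architecture(0, "none", noise_sd = noise_sd)
          a$no_growth <- TRUE
          a
        })
      plan$planted_truth[[planted_key(cross, cond)]] <-
        list(architecture = arch, true_class = cls)
    }
  }
  plan
}

#' Ground-truth table of a planted plan
#'
#' @param plan a `panel_plan` with planted architectures.
#' @return data.frame: `cross_id`, `condition`, `true_class`, `w1`,
#'   `epistasis_mode`.
#' @export
ground_truth_table <- function(plan) {
  stopifnot(inherits(plan, "panel_plan"))
  if (!length(plan$planted_truth)) stop("plan has no planted architectures")
  keys <- strsplit(names(plan$planted_truth), "\r", fixed = TRUE)
  data.frame(
    cross_id = vapply(keys, `[`, "", 1L),
    condition = vapply(keys, `[`, "", 2L),
    true_class = vapply(plan$planted_truth, function(t) t$true_class, ""),
    w1 = vapply(plan$planted_truth, function(t) t$architecture$w1, 0),
    epistasis_mode = vapply(plan$planted_truth,
                            function(t) t$architecture$epistasis_mode, ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Generate a raw colony-size table from a planted plan
#'
#' Simulates the full measurement chain for every cross: one meiosis
#' (genotypes shared across conditions), planted-architecture phenotypes
#' per treatment condition, and conversion of growth ratios to colony
#' sizes through an invertible affine map —
#' `size_24h = size_0h + round(G_ref * ratio)` with the initial size
#' drawn uniformly on `[80, 120]` and reference-condition growth equal to
#' `G_ref`. Replicates get independent multiplicative lognormal noise on
#' growth (sd `replicate_sd` on the log scale), emulating the high but
#' imperfect replicate correlation of plate phenotyping. With
#' `replicate_sd = 0` the planted ratio is recoverable exactly up to the
#' rounding step (within `1 / G_ref`).
#'
#' @param plan a `panel_plan` whose non-reference cross x condition slots
#'   are all planted (see [plant_architectures()]).
#' @param seed optional integer seed.
#' @param G_ref reference growth in pixel units (default 400).
#' @param replicate_sd lognormal sd of replicate noise (default 0.05).
#' @return List with `table` (colony-record data.frame: `strain_id`,
#'   `cross_id`, `role`, `tetrad_index`, `spore_index`, `condition`,
#'   `replicate_index`, `size_0h`, `size_24h`), `ground_truth` (see
#'   [ground_truth_table()]) and `true_ratios` (data.frame of the planted
#'   noiseless-measurement phenotypes per strain x condition).
#' @export
generate_colony_table <- function(plan, seed = NULL, G_ref = 400,
                                  replicate_sd = 0.05) {
  stopifnot(inherits(plan, "panel_plan"))
  treatment <- setdiff(plan$conditions, plan$reference_condition)
  for (cond in treatment)
    for (cross in plan$crosses$cross_id)
      if (is.null(plan$planted_truth[[planted_key(cross, cond)]]))
        stop("no planted architecture for ", cross, " x ", cond)
  if (!is.null(seed)) set.seed(seed)
  nt <- plan$n_tetrads
  blocks <- list()
  ratio_rows <- list()
  for (ci in seq_len(nrow(plan$crosses))) {
    cross <- plan$crosses$cross_id[ci]
    g <- simulate_tetrad_genotypes(nt, 101L)
    seg_ids <- sprintf("%s_t%02d_s%d", cross, rep(seq_len(nt), each = 4L),
                       rep(1:4, nt))
    par_ids <- unlist(plan$crosses[ci, c("parent_1", "parent_2")],
                      use.names = FALSE)
    ids <- c(seg_ids, par_ids)
    roles <- c(rep("segregant", 4L * nt), "parent", "parent")
    tet <- c(rep(seq_len(nt), each = 4L), NA, NA)
    spo <- c(rep(1:4, nt), NA, NA)
    for (cond in plan$conditions) {
      if (cond == plan$reference_condition) {
        ratios <- rep(1, length(ids))
      } else {
        truth <- plan$planted_truth[[planted_key(cross, cond)]]
        panel <- compute_phenotypes(g, truth$architecture,
                                    cross_id = cross, condition = cond)
        ratios <- pmax(c(as.vector(t(panel$values)), panel$parent_values), 0)
      }
      ratio_rows[[length(ratio_rows) + 1L]] <- data.frame(
        strain_id = ids, cross_id = cross, condition = cond,
        true_ratio = ratios, stringsAsFactors = FALSE)
      for (rep_i in seq_len(plan$n_replicates)) {
        n <- length(ids)
        s0 <- sample(80:120, n, replace = TRUE)
        noise <- if (replicate_sd > 0) exp(rnorm(n, 0, replicate_sd)) else 1
        growth <- round(G_ref * ratios * noise)
        blocks[[length(blocks) + 1L]] <- data.frame(
          strain_id = ids, cross_id = cross, role = roles,
          tetrad_index = tet, spore_index = spo, condition = cond,
          replicate_index = rep_i, size_0h = s0,
          size_24h = s0 + pmax(growth, 0), stringsAsFactors = FALSE)
      }
    }
  }
  list(table = do.call(rbind, blocks),
       ground_truth = ground_truth_table(plan),
       true_ratios = do.call(rbind, ratio_rows))
}

#' Read and write colony tables
#'
#' Tab-separated with a header row and columns exactly `strain_id`,
#' `cross_id`, `role`, `tetrad_index`, `spore_index`, `condition`,
#' `replicate_index`, `size_0h`, `size_24h`; non-applicable indices
#' (parent rows) are empty fields.
#'
#' @param table colony-record data.frame.
#' @param path file path.
#' @export
write_colony_table <- function(table, path) {
  cols <- c("strain_id", "cross_id", "role", "tetrad_index", "spore_index",
            "condition", "replicate_index", "size_0h", "size_24h")
  stopifnot(all(cols %in% names(table)))
  write.table(table[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_colony_table
#' @export
read_colony_table <- function(path) {
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  na.strings = c("", "NA"),
                  colClasses = c(strain_id = "character",
                                 cross_id = "character",
                                 role = "character",
                                 tetrad_index = "integer",
                                 spore_index = "integer",
                                 condition = "character",
                                 replicate_index = "integer",
                                 size_0h = "numeric",
                                 size_24h = "numeric"))
  if (any(d$size_0h < 0, na.rm = TRUE) || any(d$size_24h < 0, na.rm = TRUE))
    stop("colony sizes must be non-negative")
  seg <- d$role == "segregant"
  if (anyNA(d$tetrad_index[seg]) || anyNA(d$spore_index[seg]))
    stop("segregant records must carry tetrad and spore indices")
  d
}
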