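#' Simulate 2:2-segregating tetrad genotypes
#'
#' Performs a simplified meiosis: each haploid genome is a string of
#' `n_loci` biallelic markers. Per tetrad, two recombinant strings are
#' formed by joining the all-1 parental string and the all-0 parental
#' string at two breakpoints (the string is parental-1 up to the first
#' breakpoint, parental-0 up to the second, parental-1 after it; the two
#' breakpoints are drawn uniformly from the `n_loci + 1` locus boundaries
#' and ordered). Spores 1-2 of a tetrad are the first recombinant and its
#' locus-wise complement, spores 3-4 the second recombinant and its
#' complement, so every locus segregates exactly 2:2 within every tetrad.
#'
#' @param n_tetrads number of tetrads (rows of 4 spores).
#' @param n_loci number of biallelic loci per genome.
#' @param seed optional integer seed for reproducibility.
#' @return Integer matrix of class `genotype_matrix`, `4 * n_tetrads` rows
#'   (tetrads in blocks of 4 consecutive rows) by `n_loci` columns, entries
#'   0/1.
#' @examples
#' g <- simulate_tetrad_genotypes(40, 101, seed = 1)
#' # 2:2 segregation at every locus of every tetrad:
#' all(rowsum(g, rep(1:40, each = 4)) == 2)
#' @export
simulate_tetrad_genotypes <- function(n_tetrads, n_loci, seed = NULL) {
  if (n_tetrads < 1L || n_loci < 1L)
    stop("'n_tetrads' and 'n_loci' must be positive")
  if (!is.null(seed)) set.seed(seed)
  nr <- 2L * n_tetrads                       # recombinant strings
  b <- matrix(sample.int(n_loci + 1L, 2L * nr, replace = TRUE) - 1L, ncol = 2L)
  b1 <- pmin(b[, 1], b[, 2])
  b2 <- pmax(b[, 1], b[, 2])
  idx <- matrix(seq_len(n_loci), nr, n_loci, byrow = TRUE)
  rec <- (idx <= b1) | (idx > b2)            # logical nr x n_loci
  g <- matrix(0L, 4L * n_tetrads, n_loci)
  r1 <- rec[seq(1L, nr, by = 2L), , drop = FALSE]
  r2 <- rec[seq(2L, nr, by = 2L), , drop = FALSE]
  g[seq(1L, 4L * n_tetrads, by = 4L), ] <- r1
  g[seq(2L, 4L * n_tetrads, by = 4L), ] <- 1L - r1
  g[seq(3L, 4L * n_tetrads, by = 4L), ] <- r2
  g[seq(4L, 4L * n_tetrads, by = 4L), ] <- 1L - r2
  structure(g, class = c("genotype_matrix", "matrix"),
            n_tetrads = n_tetrads)
}

#' Draw a genetic architecture for a simulated trait
#'
#' A trait is controlled by one primary gene of weight `w1` and
#' `n_secondary` secondary genes whose non-negative weights are drawn iid
#' uniform and renormalised to sum to `1 - w1`. Genes are mapped to loci by
#' a uniform random bijection (primary gene + secondary genes onto the
#' `n_secondary + 1` loci). Epistatic modes add a second primary locus,
#' drawn uniformly among the remaining loci, sharing the weight `w1`:
#' under `"recessive"` the primary effect requires both primary states to
#' be 1 (AND); under `"dominant"` either suffices (OR).
#'
#' @param w1 primary-gene weight in `[0, 1]`.
#' @param epistasis_mode `"none"`, `"recessive"` or `"dominant"`.
#' @param n_secondary number of secondary genes (default 100, giving the
#'   default 101-locus genome).
#' @param noise_sd standard deviation of the Gaussian measurement noise
#'   added per individual phenotype (phenotype scale, where the noiseless
#'   phenotype lies in `[0, 1]`).
#' @param seed optional integer seed.
#' @return Object of class `genetic_architecture`: list with `w1`,
#'   `secondary_weights`, `locus_weights` (secondary weights placed at
#'   their loci), `primary_positions`, `epistasis_mode`, `noise_sd`,
#'   `n_loci`, `no_growth`.
#' @export
assign_architecture <- function(w1, epistasis_mode = c("none", "recessive",
                                                       "dominant"),
                                n_secondary = 100L, noise_sd = 0.05,
                                seed = NULL) {
  epistasis_mode <- match.arg(epistasis_mode)
  if (!is.finite(w1) || w1 < 0 || w1 > 1)
    stop("'w1' must lie in [0, 1]")
  if (n_secondary < 0L) stop("'n_secondary' must be >= 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n_loci <- n_secondary + 1L
  perm <- sample.int(n_loci)                 # genes -> loci bijection
  primary <- perm[1L]
  sec_loci <- perm[-1L]
  if (n_secondary > 0L) {
    raw <- runif(n_secondary)
    sw <- raw / sum(raw) * (1 - w1)
  } else sw <- numeric(0)
  lw <- numeric(n_loci)
  lw[sec_loci] <- sw
  if (epistasis_mode != "none") {
    # second primary locus shares w1; may coincide with a secondary locus
    candidates <- setdiff(seq_len(n_loci), primary)
    primary <- c(primary, candidates[sample.int(length(candidates), 1L)])
  }
  structure(
    list(w1 = w1, secondary_weights = sw, locus_weights = lw,
         primary_positions = primary, epistasis_mode = epistasis_mode,
         noise_sd = noise_sd, n_loci = n_loci, no_growth = FALSE),
    class = "genetic_architecture")
}

#' @export
print.genetic_architecture <- function(x, ...) {
  cat(sprintf(
    "Genetic architecture: w1 = %.3f, %d secondary genes, epistasis %s\n",
    x$w1, length(x$secondary_weights), x$epistasis_mode))
  cat(sprintf("  primary locus/loci: %s; noise sd %.3g\n",
              paste(x$primary_positions, collapse = ", "), x$noise_sd))
  invisible(x)
}

primary_effect <- function(genotypes, arch) {
  p <- arch$primary_positions
  switch(arch$epistasis_mode,
         none = as.numeric(genotypes[, p[1L]]),
         recessive = as.numeric(genotypes[, p[1L]] & genotypes[, p[2L]]),
         dominant = as.numeric(genotypes[, p[1L]] | genotypes[, p[2L]]))
}

#' Compute segregant phenotypes from genotypes and an architecture
#'
#' The phenotype of an individual is the weighted sum of its binary locus
#' states: the secondary contribution plus `w1` times the primary effect
#' (the primary state, or the AND/OR of the two primary states under
#' epistasis), plus Gaussian noise of standard deviation `noise_sd`.
#' Noiseless phenotypes lie in `[0, 1]` because the weights sum to 1.
#' Parental phenotypes are those of the pure parental genotypes (all-1 and
#' all-0 strings), i.e. 1 and 0 before noise.
#'
#' @param genotypes a `genotype_matrix` from [simulate_tetrad_genotypes()].
#' @param arch a `genetic_architecture` from [assign_architecture()].
#' @param seed optional integer seed (noise draws).
#' @param cross_id,condition identifiers stored in the returned panel.
#' @return A [tetrad_panel()] with simulated provenance.
#' @export
compute_phenotypes <- function(genotypes, arch, seed = NULL,
                               cross_id = "sim", condition = "sim") {
  if (!inherits(arch, "genetic_architecture"))
    stop("'arch' must be a genetic_architecture")
  if (ncol(genotypes) != arch$n_loci)
    stop("genotype matrix has ", ncol(genotypes), " loci but architecture ",
         "expects ", arch$n_loci)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genotypes)
  if (n %% 4L != 0L) stop("genotype rows must form complete tetrads")
  if (arch$no_growth) {
    ph <- numeric(n)
    parents <- c(0, 0)
  } else {
    ph <- as.vector(genotypes %*% arch$locus_weights) +
      arch$w1 * primary_effect(genotypes, arch)
    parents <- c(1, 0)                       # all-1 and all-0 genomes
    if (arch$noise_sd > 0) {
      ph <- ph + rnorm(n, 0, arch$noise_sd)
      parents <- parents + rnorm(2L, 0, arch$noise_sd)
    }
  }
  tetrad_panel(matrix(ph, ncol = 4L, byrow = TRUE), parents,
               cross_id = cross_id, condition = condition,
               provenance = "simulated")
}

#' Generate a labeled training set of simulated phenotype distributions
#'
#' Generates panels under the non-epistatic model and the two epistatic
#' models, each with an independently drawn architecture and meiosis, and
#' records the true primary-gene weight and epistasis mode of each panel.
#' Defaults produce the 50,000-panel training corpus (25,000 non-epistatic,
#' 12,500 recessive, 12,500 dominant) with `w1` drawn uniformly on
#' `[0, 1]`.
#'
#' @param n_none,n_recessive,n_dominant panel counts per epistasis mode.
#' @param w1_sampler function of `n` returning `n` weights in `[0, 1]`.
#' @param n_tetrads,n_loci simulation dimensions per panel.
#' @param noise_sd phenotype noise standard deviation.
#' @param seed optional integer seed.
#' @return Object of class `labeled_panels`: list with `panels` (list of
#'   [tetrad_panel()]), `w1` (numeric true weights) and `mode` (character).
#' @examples
#' ts <- generate_training_set(10, 5, 5, seed = 1)
#' length(ts$panels)  # 20
#' table(ts$mode)
#' @export
generate_training_set <- function(n_none = 25000L, n_recessive = 12500L,
                                  n_dominant = 12500L,
                                  w1_sampler = function(n) runif(n),
                                  n_tetrads = 40L, n_loci = 101L,
                                  noise_sd = 0.05, seed = NULL) {
  if (min(n_none, n_recessive, n_dominant) < 0L)
    stop("panel counts must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  modes <- rep(c("none", "recessive", "dominant"),
               times = c(n_none, n_recessive, n_dominant))
  n <- length(modes)
  w1 <- w1_sampler(n)
  if (any(!is.finite(w1) | w1 < 0 | w1 > 1))
    stop("w1_sampler must return weights in [0, 1]")
  panels <- vector("list", n)
  for (i in seq_len(n)) {
    g <- simulate_tetrad_genotypes(n_tetrads, n_loci)
    a <- assign_architecture(w1[i], modes[i], n_secondary = n_loci - 1L,
                             noise_sd = noise_sd)
    panels[[i]] <- compute_phenotypes(g, a, cross_id = sprintf("sim%06d", i))
  }
  structure(list(panels = panels, w1 = w1, mode = modes),
            class = "labeled_panels")
}

#' @export
print.labeled_panels <- function(x, ...) {
  cat(sprintf("Labeled simulated panels: %d distributions\n",
              length(x$panels)))
  print(table(mode = x$mode))
  invisible(x)
}
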