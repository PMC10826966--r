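#' Tetrad panel of segregant phenotypes
#'
#' A tetrad panel holds the phenotype distribution of one cross under one
#' condition: an `n_tetrads x 4` matrix of segregant growth ratios (rows are
#' tetrads, columns are the four spores of each meiosis) plus the two
#' parental phenotypes. Experimental panels may contain `NA` for spores lost
#' to filtering; simulated panels are always complete.
#'
#' @param values numeric matrix with 4 columns (spores) and one row per
#'   tetrad, or a numeric vector whose length is a multiple of 4 (filled
#'   row-wise, spores within tetrads contiguous).
#' @param parent_values numeric length-2 vector of parental phenotypes
#'   (may be `NA` when parents were not phenotyped).
#' @param cross_id,condition identifiers carried through to calls tables.
#' @param provenance `"simulated"` or `"experimental"`.
#'
#' @return An object of class `tetrad_panel`.
#' @examples
#' g <- simulate_tetrad_genotypes(40, 101, seed = 1)
#' a <- assign_architecture(w1 = 0.9, seed = 1)
#' p <- compute_phenotypes(g, a, seed = 1)
#' print(p)
#' @export
tetrad_panel <- function(values, parent_values = c(NA_real_, NA_real_),
                         cross_id = "cross", condition = "condition",
                         provenance = c("simulated", "experimental")) {
  provenance <- match.arg(provenance)
  if (is.vector(values)) {
    if (length(values) %% 4L != 0L)
      stop("segregant values must fill complete tetrads (length multiple of 4)")
    values <- matrix(values, ncol = 4L, byrow = TRUE)
  }
  values <- as.matrix(values)
  if (ncol(values) != 4L)
    stop("'values' must have 4 columns (one per spore)")
  storage.mode(values) <- "double"
  if (any(is.infinite(values)))
    stop("segregant phenotypes must be finite or NA")
  if (length(parent_values) != 2L)
    stop("'parent_values' must have length 2")
  structure(
    list(values = values,
         parent_values = as.numeric(parent_values),
         cross_id = as.character(cross_id),
         condition = as.character(condition),
         provenance = provenance),
    class = "tetrad_panel")
}

#' @export
print.tetrad_panel <- function(x, ...) {
  v <- x$values
  cat(sprintf("Tetrad panel: %s / %s (%s)\n", x$cross_id, x$condition,
              x$provenance))
  cat(sprintf("  %d tetrads x 4 spores, %d missing values\n",
              nrow(v), sum(is.na(v))))
  obs <- v[!is.na(v)]
  if (length(obs))
    cat(sprintf("  phenotype range [%.3f, %.3f], mean %.3f\n",
                min(obs), max(obs), mean(obs)))
  cat(sprintf("  parents: %s, %s\n",
              format(x$parent_values[1], digits = 3),
              format(x$parent_values[2], digits = 3)))
  invisible(x)
}

panel_values <- function(panel, complete_only = FALSE) {
  v <- panel$values
  if (complete_only) {
    keep <- rowSums(is.na(v)) == 0L
    v <- v[keep, , drop = FALSE]
  }
  v
}

is_complete_panel <- function(panel) !anyNA(panel$values)

#' Write and read tetrad panels
#'
#' Panels serialise to a long tab-separated file with columns
#' `cross_id`, `condition`, `role`, `tetrad_index`, `spore_index`,
#' `phenotype`; parents appear as `role == "parent"` rows with empty tetrad
#' and spore indices.
#'
#' @param panels a `tetrad_panel` or list of them.
#' @param path file path.
#' @return `read_panels` returns a list of `tetrad_panel` objects.
#' @export
write_panels <- function(panels, path) {
  if (inherits(panels, "tetrad_panel")) panels <- list(panels)
  rows <- lapply(panels, function(p) {
    nt <- nrow(p$values)
    seg <- data.frame(
      cross_id = p$cross_id, condition = p$condition, role = "segregant",
      tetrad_index = rep(seq_len(nt), each = 4L),
      spore_index = rep(1:4, nt),
      phenotype = as.vector(t(p$values)),
      stringsAsFactors = FALSE)
    par <- data.frame(
      cross_id = p$cross_id, condition = p$condition, role = "parent",
      tetrad_index = NA_integer_, spore_index = c(1L, 2L),
      phenotype = p$parent_values, stringsAsFactors = FALSE)
    rbind(seg, par)
  })
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname write_panels
#' @export
read_panels <- function(path) {
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  na.strings = c("", "NA"))
  need <- c("cross_id", "condition", "role", "tetrad_index", "spore_index",
            "phenotype")
  if (!all(need %in% names(d)))
    stop("panel file must have columns: ", paste(need, collapse = ", "))
  key <- paste(d$cross_id, d$condition, sep = "\r")
  lapply(split(seq_len(nrow(d)), key), function(idx) {
    s <- d[idx, ]
    seg <- s[s$role == "segregant", ]
    nt <- max(seg$tetrad_index)
    v <- matrix(NA_real_, nt, 4L)
    v[cbind(seg$tetrad_index, seg$spore_index)] <- seg$phenotype
    par <- s[s$role == "parent", ]
    pv <- c(NA_real_, NA_real_)
    if (nrow(par)) pv[par$spore_index] <- par$phenotype
    tetrad_panel(v, pv, cross_id = seg$cross_id[1],
                 condition = seg$condition[1], provenance = "experimental")
  })
}
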