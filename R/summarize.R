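#' Tabulate the complexity spectrum of a set of calls
#'
#' Counts and percentages of monogenic / oligogenic / complex calls, with
#' undetermined calls excluded from the denominator. Scopes: `"overall"`
#' pools all calls; `"per_condition"` tabulates each condition;
#' `"per_parent"` expands each cross into its two parents (requires
#' `parent_1` / `parent_2` columns, see [annotate_parents()]) and
#' tabulates each parent x condition.
#'
#' @param calls data.frame of complexity calls ([classify_panels()]
#'   output), with a `level` column.
#' @param scope `"overall"`, `"per_condition"` or `"per_parent"`.
#' @return data.frame with the scope keys, `n_called`, counts
#'   `n_monogenic`, `n_oligogenic`, `n_complex`, and percentages
#'   `pct_monogenic`, `pct_oligogenic`, `pct_complex` (summing to 100).
#' @examples
#' calls <- data.frame(level = c(rep("complex", 8), "monogenic",
#'                               "oligogenic"))
#' complexity_spectrum(calls)  # 80 / 10 / 10
#' @export
complexity_spectrum <- function(calls, scope = c("overall", "per_condition",
                                                 "per_parent")) {
  scope <- match.arg(scope)
  stopifnot(is.data.frame(calls), "level" %in% names(calls))
  levels3 <- c("monogenic", "oligogenic", "complex")
  tab_one <- function(d, keys) {
    d <- d[d$level != "undetermined", , drop = FALSE]
    if (!nrow(d)) return(NULL)
    n <- vapply(levels3, function(l) sum(d$level == l), 0L)
    cbind(keys,
          data.frame(n_called = nrow(d),
                     n_monogenic = n[1L], n_oligogenic = n[2L],
                     n_complex = n[3L],
                     pct_monogenic = 100 * n[1L] / nrow(d),
                     pct_oligogenic = 100 * n[2L] / nrow(d),
                     pct_complex = 100 * n[3L] / nrow(d),
                     row.names = NULL))
  }
  if (scope == "overall") {
    out <- tab_one(calls, data.frame(scope = "overall"))
    if (is.null(out)) stop("all calls are undetermined")
    return(out)
  }
  if (scope == "per_parent") {
    calls <- expand_parents(calls)
    groups <- split(calls, paste(calls$parent, calls$condition, sep = "\r"))
    out <- do.call(rbind, lapply(groups, function(d)
      tab_one(d, data.frame(parent = d$parent[1L],
                            condition = d$condition[1L]))))
  } else {
    stopifnot("condition" %in% names(calls))
    groups <- split(calls, calls$condition)
    out <- do.call(rbind, lapply(groups, function(d)
      tab_one(d, data.frame(condition = d$condition[1L]))))
  }
  if (is.null(out)) stop("all calls are undetermined")
  rownames(out) <- NULL
  out
}

expand_parents <- function(calls) {
  if (!all(c("parent_1", "parent_2") %in% names(calls)))
    stop("per-parent summaries need parent_1/parent_2 columns; ",
         "see annotate_parents()")
  rbind(
    cbind(calls, parent = calls$parent_1),
    cbind(calls, parent = calls$parent_2))
}

#' Attach parent identities to a calls table
#'
#' @param calls calls data.frame with a `cross_id` column.
#' @param plan a `panel_plan` naming the parents of each cross.
#' @return `calls` with `parent_1` and `parent_2` columns.
#' @export
annotate_parents <- function(calls, plan) {
  stopifnot(inherits(plan, "panel_plan"))
  i <- match(calls$cross_id, plan$crosses$cross_id)
  if (anyNA(i)) stop("calls contain crosses not in the plan")
  calls$parent_1 <- plan$crosses$parent_1[i]
  calls$parent_2 <- plan$crosses$parent_2[i]
  calls
}

shannon_entropy <- function(freq) {
  f <- freq[freq > 0]
  -sum(f * log2(f))
}

#' Shannon entropy of complexity across the crosses of each parent
#'
#' For each parent x condition, the entropy (in bits) of the complexity
#' class frequencies over that parent's called crosses:
#' `H = -sum(f * log2(f))` over the observed monogenic / oligogenic /
#' complex frequencies, with `0 * log(0) = 0`. `H = 0` when every cross
#' has the same complexity; the maximum `log2(3) ~ 1.585` is reached at
#' uniform thirds. Undetermined calls are excluded.
#'
#' @param calls calls data.frame with `level`, `condition` and
#'   `parent_1` / `parent_2` columns (see [annotate_parents()]).
#' @return data.frame: `parent_id`, `condition`, `H`, `n_crosses`.
#' @export
parent_entropy <- function(calls) {
  calls <- expand_parents(calls)
  calls <- calls[calls$level != "undetermined", , drop = FALSE]
  if (!nrow(calls)) stop("no called crosses")
  groups <- split(calls, paste(calls$parent, calls$condition, sep = "\r"))
  out <- do.call(rbind, lapply(groups, function(d) {
    f <- table(factor(d$level, levels = c("monogenic", "oligogenic",
                                          "complex"))) / nrow(d)
    data.frame(parent_id = d$parent[1L], condition = d$condition[1L],
               H = shannon_entropy(as.numeric(f)), n_crosses = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' One-sided comparison of phenotypes between two variant groups
#'
#' Tests whether isolates carrying a candidate variant (group A) grow
#' worse than isolates carrying the alternative (group B) with a
#' one-sided Welch two-sample t-test (alternative: A lower), Bonferroni
#' adjusted for the number of candidate variants tested in the same gene.
#'
#' @param phenotypes_a,phenotypes_b numeric phenotype vectors (at least 2
#'   values each).
#' @param n_tests number of tests in the Bonferroni family (default 1).
#' @param alpha significance level on the adjusted p-value.
#' @return List with `p_value` (raw one-sided), `p_adjusted`
#'   (`min(1, p * n_tests)`), `significant`, `t_statistic`, `n_a`, `n_b`.
#' @examples
#' compare_variant_groups(rnorm(20, 0), rnorm(20, 1), n_tests = 3)
#' @export
compare_variant_groups <- function(phenotypes_a, phenotypes_b,
                                   n_tests = 1L, alpha = 0.05) {
  a <- phenotypes_a[!is.na(phenotypes_a)]
  b <- phenotypes_b[!is.na(phenotypes_b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need at least 2 values")
  if (var(a) == 0 && var(b) == 0)
    stop("degenerate groups: no variance in either group")
  tt <- t.test(a, b, alternative = "less")
  p_adj <- min(1, tt$p.value * n_tests)
  list(p_value = tt$p.value, p_adjusted = p_adj,
       significant = p_adj < alpha,
       t_statistic = unname(tt$statistic), n_a = length(a), n_b = length(b))
}
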