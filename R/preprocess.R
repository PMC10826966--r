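#' Colony growth over the incubation window
#'
#' Growth is the endpoint size minus the initial size; negative values
#' (shrinkage artefacts of the imaging pipeline) are clamped to zero.
#'
#' @param size_0h,size_24h non-negative colony sizes (pixel units);
#'   vectorised.
#' @return Non-negative growth.
#' @examples
#' compute_growth(100, 500)  # 400
#' compute_growth(100, 90)   # 0
#' @export
compute_growth <- function(size_0h, size_24h) {
  if (any(size_0h < 0, na.rm = TRUE) || any(size_24h < 0, na.rm = TRUE))
    stop("colony sizes must be non-negative")
  pmax(size_24h - size_0h, 0)
}

#' Remove colonies with insufficient baseline growth
#'
#' A colony (a strain x replicate) whose endpoint size on the reference
#' condition is strictly below `min_size` is removed across all
#' conditions: the filter judges only baseline growth, so it removes the
#' same colonies whether applied before or after ratio computation.
#' Strains with no reference-condition record at all are dropped and
#' reported.
#'
#' @param table a colony table data.frame (see [read_colony_table()]).
#' @param reference_condition name of the reference (no-compound)
#'   condition.
#' @param min_size baseline threshold on `size_24h` (default 200, strict
#'   `<`).
#' @return List with `table` (filtered) and `report` (list:
#'   `n_removed_low_baseline`, `n_removed_missing_reference`,
#'   `fraction_removed`, `removed_keys`).
#' @export
filter_baseline <- function(table, reference_condition, min_size = 200L) {
  stopifnot(is.data.frame(table))
  if (!reference_condition %in% table$condition)
    stop("reference condition '", reference_condition, "' not in table")
  key <- function(d) paste(d$strain_id, d$cross_id, d$replicate_index,
                           sep = "\r")
  strain_key <- function(d) paste(d$strain_id, d$cross_id, sep = "\r")
  ref <- table[table$condition == reference_condition, ]
  low_keys <- unique(key(ref)[ref$size_24h < min_size])
  has_ref_strain <- unique(strain_key(ref))
  missing_ref <- !(strain_key(table) %in% has_ref_strain)
  ref_missing_keys <- unique(paste(table$strain_id[missing_ref],
                                   table$cross_id[missing_ref]))
  drop <- key(table) %in% low_keys | missing_ref
  list(table = table[!drop, , drop = FALSE],
       report = list(
         n_removed_low_baseline = sum(key(table) %in% low_keys),
         n_removed_missing_reference = sum(missing_ref &
                                             !(key(table) %in% low_keys)),
         fraction_removed = mean(drop),
         removed_keys = low_keys,
         strains_missing_reference = ref_missing_keys))
}

#' Growth ratio of a treatment condition over the reference
#'
#' @param growth_condition,growth_reference non-negative colony growths;
#'   vectorised.
#' @return `growth_condition / growth_reference`, or `NA` (missing,
#'   flagged) where the reference growth is zero.
#' @examples
#' growth_ratio(200, 400)  # 0.5
#' growth_ratio(100, 0)    # NA
#' @export
growth_ratio <- function(growth_condition, growth_reference) {
  if (any(growth_condition < 0, na.rm = TRUE) ||
      any(growth_reference < 0, na.rm = TRUE))
    stop("growths must be non-negative")
  out <- growth_condition / growth_reference
  out[!is.na(growth_reference) & growth_reference == 0] <- NA_real_
  out
}

#' Average replicate growth ratios into one phenotype
#'
#' @param ratios numeric vector of surviving replicate ratios (`NA`s are
#'   dropped).
#' @return List with `growth_ratio` (arithmetic mean; `NA` if no
#'   replicate survives) and `n_replicates_used`.
#' @export
average_duplicates <- function(ratios) {
  r <- ratios[!is.na(ratios)]
  list(growth_ratio = if (length(r)) mean(r) else NA_real_,
       n_replicates_used = length(r))
}

#' Compute per-strain growth ratios from a colony table
#'
#' Applies the preprocessing chain: clamped growth per colony, baseline
#' filtering on the reference condition, replicate-matched growth ratios
#' (a replicate missing its reference partner falls back to the strain's
#' mean reference growth), and duplicate averaging.
#'
#' @param table a colony table data.frame.
#' @param reference_condition reference condition name.
#' @param min_size baseline threshold (see [filter_baseline()]).
#' @return List with `phenotypes` (data.frame: `strain_id`, `cross_id`,
#'   `role`, `tetrad_index`, `spore_index`, `condition`, `growth_ratio`,
#'   `n_replicates_used`) and `report` from the baseline filter.
#' @export
compute_growth_ratios <- function(table, reference_condition,
                                  min_size = 200L) {
  flt <- filter_baseline(table, reference_condition, min_size)
  tab <- flt$table
  tab$growth <- compute_growth(tab$size_0h, tab$size_24h)
  ref <- tab[tab$condition == reference_condition, ]
  ref_key <- paste(ref$strain_id, ref$cross_id, ref$replicate_index,
                   sep = "\r")
  ref_growth <- setNames(ref$growth, ref_key)
  mean_ref <- tapply(ref$growth, paste(ref$strain_id, ref$cross_id,
                                       sep = "\r"), mean)
  trt <- tab[tab$condition != reference_condition, ]
  tkey <- paste(trt$strain_id, trt$cross_id, trt$replicate_index, sep = "\r")
  gref <- ref_growth[tkey]
  miss <- is.na(gref)
  gref[miss] <- mean_ref[paste(trt$strain_id, trt$cross_id,
                               sep = "\r")[miss]]
  trt$ratio <- growth_ratio(trt$growth, unname(gref))
  grp <- paste(trt$strain_id, trt$cross_id, trt$condition, sep = "\r")
  agg <- lapply(split(seq_len(nrow(trt)), grp), function(idx) {
    s <- trt[idx, ]
    av <- average_duplicates(s$ratio)
    data.frame(strain_id = s$strain_id[1L], cross_id = s$cross_id[1L],
               role = s$role[1L], tetrad_index = s$tetrad_index[1L],
               spore_index = s$spore_index[1L], condition = s$condition[1L],
               growth_ratio = av$growth_ratio,
               n_replicates_used = av$n_replicates_used,
               stringsAsFactors = FALSE)
  })
  phenotypes <- do.call(rbind, agg)
  rownames(phenotypes) <- NULL
  list(phenotypes = phenotypes, report = flt$report)
}

#' Assemble tetrad panels from preprocessed phenotypes
#'
#' Builds one [tetrad_panel()] per cross x non-reference condition.
#' Missing spores (filtered colonies) are kept as `NA` markers so the
#' tetrad structure is preserved; the completeness fraction is recorded as
#' an attribute.
#'
#' @param phenotypes phenotype data.frame from [compute_growth_ratios()].
#' @param plan a `panel_plan` from [plan_half_diallel()] (supplies the
#'   tetrad count and parent ordering).
#' @return Named list of `tetrad_panel` objects
#'   (`"cross_id::condition"`), each with attribute `completeness`.
#' @export
build_panels <- function(phenotypes, plan) {
  stopifnot(inherits(plan, "panel_plan"))
  seg <- phenotypes[phenotypes$role == "segregant", ]
  if (nrow(seg) &&
      (anyNA(seg$tetrad_index) || any(seg$tetrad_index < 1L) ||
       any(seg$tetrad_index > plan$n_tetrads) ||
       any(!seg$spore_index %in% 1:4)))
    stop("segregant records carry tetrad/spore indices outside the plan")
  key <- paste(phenotypes$cross_id, phenotypes$condition, sep = "\r")
  out <- list()
  for (idx in split(seq_len(nrow(phenotypes)), key)) {
    s <- phenotypes[idx, ]
    cross <- s$cross_id[1L]; cond <- s$condition[1L]
    if (cond == plan$reference_condition) next
    if (!cross %in% plan$crosses$cross_id)
      stop("unknown cross '", cross, "' in phenotype table")
    v <- matrix(NA_real_, plan$n_tetrads, 4L)
    sg <- s[s$role == "segregant", ]
    v[cbind(sg$tetrad_index, sg$spore_index)] <- sg$growth_ratio
    parents <- plan$crosses[plan$crosses$cross_id == cross,
                            c("parent_1", "parent_2")]
    pv <- vapply(unlist(parents), function(p) {
      r <- s$growth_ratio[s$role == "parent" & s$strain_id == p]
      if (length(r)) r[1L] else NA_real_
    }, numeric(1L))
    panel <- tetrad_panel(v, unname(pv), cross_id = cross, condition = cond,
                          provenance = "experimental")
    attr(panel, "completeness") <- mean(!is.na(v))
    out[[paste(cross, cond, sep = "::")]] <- panel
  }
  out
}

#' Preprocess a colony table end to end
#'
#' Convenience wrapper chaining [compute_growth_ratios()] and
#' [build_panels()].
#'
#' @inheritParams compute_growth_ratios
#' @param plan a `panel_plan`.
#' @return List with `panels`, `phenotypes`, `report`.
#' @export
preprocess_colony_table <- function(table, plan,
                                    reference_condition = plan$reference_condition,
                                    min_size = 200L) {
  gr <- compute_growth_ratios(table, reference_condition, min_size)
  list(panels = build_panels(gr$phenotypes, plan),
       phenotypes = gr$phenotypes, report = gr$report)
}
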