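#' Diameter of a circle from its area
#'
#' `d = 2 * sqrt(area / pi)` — the circularity assumption used for all
#' electron-microscopy diameters.
#'
#' @param area cross-sectional area in um^2 (> 0).
#' @return Diameter in um.
#' @export
diameter_from_area <- function(area) {
  if (any(area <= 0)) stop("area must be positive")
  2 * sqrt(area / pi)
}

#' g-ratio of a myelinated axon
#'
#' Ratio of the axon diameter to the axon + myelin diameter, both derived
#' from the measured areas assuming circularity:
#' `g = d(axon_area) / d(outer_area) = sqrt(axon_area / outer_area)`,
#' in (0, 1]; `g = 1` means no myelin. Lower values mean thicker myelin.
#'
#' @param axon_area inner (axon) area, um^2.
#' @param outer_area axon + myelin area, um^2; must be >= `axon_area`.
#' @return g-ratio(s).
#' @export
g_ratio <- function(axon_area, outer_area) {
  if (any(axon_area <= 0)) stop("axon_area must be positive")
  if (any(outer_area < axon_area))
    stop("validation error: outer_area < axon_area")
  diameter_from_area(axon_area) / diameter_from_area(outer_area)
}

#' Exclude small-calibre axons
#'
#' Axons with an axon diameter strictly below `min_diameter` (default
#' 0.4 um) are excluded as unmyelinated small-calibre axons; the boundary is
#' inclusive-keep. Idempotent.
#'
#' @param profiles AxonProfile data.frame (needs `axon_area`).
#' @param min_diameter exclusion threshold in um.
#' @return List with `kept` and `excluded` data.frames.
#' @export
exclude_small_axons <- function(profiles, min_diameter = 0.4) {
  if (nrow(profiles) == 0) return(list(kept = profiles, excluded = profiles))
  d <- diameter_from_area(profiles$axon_area)
  keep <- d >= min_diameter
  list(kept = profiles[keep, , drop = FALSE],
       excluded = profiles[!keep, , drop = FALSE])
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Percentage of myelinated axons per animal
#'
#' `100 * myelinated / scored` per animal; axons surrounded by uncompacted
#' membranes count as unmyelinated (only compact myelin scores). The group
#' summary (mean +/- SEM) is computed across animals, not axons.
#'
#' @param profiles AxonProfile data.frame passing the size filter, with
#'   `animal_id`, `condition` and logical `myelinated`.
#' @return List with `per_animal` (animal_id, condition, n_scored,
#'   percent_myelinated) and `summary` (per condition: mean, sem, n_animals).
#' @export
myelinated_fraction <- function(profiles) {
  stopifnot(all(c("animal_id", "myelinated") %in% names(profiles)))
  split_by <- split(profiles, profiles$animal_id)
  zero <- vapply(split_by, nrow, integer(1)) == 0
  if (any(zero)) warning("animals with zero scored axons excluded")
  per <- do.call(rbind, lapply(split_by[!zero], function(d)
    data.frame(animal_id = d$animal_id[1],
               condition = if ("condition" %in% names(d)) d$condition[1]
               else "all",
               n_scored = nrow(d),
               percent_myelinated = 100 * mean(d$myelinated),
               stringsAsFactors = FALSE)))
  rownames(per) <- NULL
  summ <- do.call(rbind, lapply(split(per, per$condition), function(d)
    data.frame(condition = d$condition[1], mean = mean(d$percent_myelinated),
               sem = sem(d$percent_myelinated), n_animals = nrow(d),
               stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  list(per_animal = per, summary = summ)
}

#' Mitochondrial area fraction per object and per animal
#'
#' Fraction = total mitochondrial area / compartment area for each profile
#' (axon or glial cytoplasm), reported per object together with per-animal
#' means — the unit of inference for group comparisons — plus the raw count
#' and total area, since an area increase can reflect number, size or both.
#'
#' @param profiles AxonProfile data.frame with `axon_area` (compartment
#'   area) and `mito_areas` (semicolon-joined um^2, see [parse_areas()]).
#' @return List with `per_object` (adds `mito_count`, `mito_total_area`,
#'   `mito_fraction`) and `per_animal` (mean fraction/count/total per animal
#'   and condition).
#' @export
mito_area_fraction <- function(profiles) {
  areas <- parse_areas(profiles$mito_areas)
  total <- vapply(areas, sum, numeric(1))
  if (any(profiles$axon_area <= 0)) stop("compartment area must be positive")
  if (any(total >= profiles$axon_area))
    stop("validation error: mitochondrial area >= compartment area")
  per <- cbind(profiles[, setdiff(names(profiles), "mito_areas"), drop = FALSE],
               mito_count = lengths(areas), mito_total_area = total,
               mito_fraction = total / profiles$axon_area)
  per_animal <- do.call(rbind, lapply(split(per, per$animal_id), function(d)
    data.frame(animal_id = d$animal_id[1],
               condition = if ("condition" %in% names(d)) d$condition[1]
               else "all",
               mean_fraction = mean(d$mito_fraction),
               mean_count = mean(d$mito_count),
               mean_total_area = mean(d$mito_total_area),
               n_objects = nrow(d), stringsAsFactors = FALSE)))
  rownames(per_animal) <- NULL
  list(per_object = per, per_animal = per_animal)
}

#' RNAscope composite score per ROI
#'
#' `score = (fraction of OLIG2+ cells) * (mean puncta over all cells)`,
#' summarised per animal and per condition. Invariant to cell order; linear
#' in the mean puncta count at fixed positive fraction.
#'
#' @param rois data.frame with one row per cell: `roi_id`, `animal_id`,
#'   `condition`, `probe`, `olig2_positive` (logical), `puncta` (count >= 0).
#' @return List with `per_roi` (roi-level scores), `per_animal` and
#'   `per_condition` summaries (mean +/- SEM over animals).
#' @export
composite_score <- function(rois) {
  need <- c("roi_id", "animal_id", "condition", "olig2_positive", "puncta")
  stopifnot(all(need %in% names(rois)))
  if (any(rois$puncta < 0)) stop("puncta counts must be >= 0")
  per_roi <- do.call(rbind, lapply(split(rois, rois$roi_id), function(d) {
    if (nrow(d) == 0) stop("ROI with zero cells")
    data.frame(roi_id = d$roi_id[1], animal_id = d$animal_id[1],
               condition = d$condition[1],
               probe = if ("probe" %in% names(d)) d$probe[1] else "probe",
               n_cells = nrow(d),
               fraction_olig2 = mean(d$olig2_positive),
               mean_puncta = mean(d$puncta),
               score = mean(d$olig2_positive) * mean(d$puncta),
               stringsAsFactors = FALSE)
  }))
  rownames(per_roi) <- NULL
  per_animal <- do.call(rbind, lapply(split(per_roi, per_roi$animal_id),
                                      function(d)
    data.frame(animal_id = d$animal_id[1], condition = d$condition[1],
               mean_score = mean(d$score), n_rois = nrow(d),
               stringsAsFactors = FALSE)))
  rownames(per_animal) <- NULL
  per_condition <- do.call(rbind, lapply(split(per_animal,
                                               per_animal$condition),
                                         function(d)
    data.frame(condition = d$condition[1], mean = mean(d$mean_score),
               sem = sem(d$mean_score), n_animals = nrow(d),
               stringsAsFactors = FALSE)))
  rownames(per_condition) <- NULL
  list(per_roi = per_roi, per_animal = per_animal,
       per_condition = per_condition)
}

#' Two-group comparison with a normality gate
#'
#' Each group is checked for normality with the Lilliefors-corrected
#' Kolmogorov-Smirnov test (Dallal-Wilkinson p-value approximation); if both
#' groups pass at `alpha_normal`, a two-sided unpaired Student's t-test is
#' used, otherwise a two-sided Mann-Whitney U-test. The chosen test is
#' recorded. Groups too small for the normality test (n < 5) take the t path
#' with a note.
#'
#' @param values numeric per-animal summary values.
#' @param condition two-level grouping of the same length.
#' @param alpha_normal normality-test significance level.
#' @return List: `test` ("t" or "mann-whitney"), `p_value`, `statistic`,
#'   `normality_p` (per group), `note`.
#' @export
group_compare <- function(values, condition, alpha_normal = 0.05) {
  condition <- droplevels(as.factor(condition))
  if (nlevels(condition) != 2) stop("need exactly two conditions")
  gs <- split(values, condition)
  if (any(lengths(gs) < 2)) stop("need >= 2 values per condition")
  note <- ""
  norm_p <- vapply(gs, function(x) {
    if (length(x) < 5 || stats::sd(x) == 0) NA_real_
    else nortest::lillie.test(x)$p.value
  }, numeric(1))
  if (anyNA(norm_p))
    note <- "group too small or degenerate for normality test; t path used"
  normal <- all(is.na(norm_p) | norm_p > alpha_normal)
  if (normal) {
    tt <- stats::t.test(gs[[1]], gs[[2]], var.equal = TRUE)
    list(test = "t", p_value = tt$p.value, statistic = unname(tt$statistic),
         normality_p = norm_p, note = note)
  } else {
    wt <- stats::wilcox.test(gs[[1]], gs[[2]], exact = FALSE)
    list(test = "mann-whitney", p_value = wt$p.value,
         statistic = unname(wt$statistic), normality_p = norm_p, note = note)
  }
}
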