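#' @name population
#' @title Condition-level population statistics
#' @description Mother/daughter asymmetry of detected foci, colocalization
#'   of aggregate foci with organelle markers, inheritance scoring across a
#'   budding time-lapse, two-sample condition comparisons and fold-change
#'   arithmetic.
NULL

#' Colocalization of foci with an organelle mask
#'
#' A focus is colocalized when its centroid lies within `max_distance` of
#' the organelle mask (equivalently, inside the mask dilated by that
#' distance). The default distance is the optical resolution limit
#' (~250 nm).
#'
#' @param foci Data frame with `row`, `col` centroids (0-based px).
#' @param organelle_mask Logical/0-1 matrix, same frame of reference.
#' @param pixel_size Pixel size, nm.
#' @param max_distance Colocalization distance, nm.
#' @return List of class `colocalization_result`: `n_foci`, `n_colocalized`,
#'   `fraction` (%), `max_distance`, `colocalized` (logical per focus).
#' @export
colocalize <- function(foci, organelle_mask, pixel_size = 120,
                       max_distance = 250) {
  if (!nrow(foci)) stop("colocalization fraction undefined for zero foci")
  mask <- organelle_mask != 0
  if (!any(mask)) stop("organelle mask is empty")
  # Euclidean distance (px) from every pixel to the nearest mask pixel
  dist_px <- EBImage::distmap(matrix(as.numeric(!mask), nrow(mask)))
  dist_px <- dist_px@.Data
  r <- pmin(pmax(round(foci$row) + 1L, 1L), nrow(mask))
  c <- pmin(pmax(round(foci$col) + 1L, 1L), ncol(mask))
  d_nm <- dist_px[cbind(r, c)] * pixel_size
  coloc <- d_nm <= max_distance
  structure(list(n_foci = nrow(foci), n_colocalized = sum(coloc),
                 fraction = 100 * mean(coloc), max_distance = max_distance,
                 colocalized = coloc),
            class = "colocalization_result")
}

#' Mother vs daughter focus statistics
#'
#' Per-role mean and sd of focus area and integrated intensity after
#' interquartile outlier removal. Roles with zero foci are flagged and
#' their summary fields left `NA`.
#'
#' @param foci Data frame from [detect_foci()] (needs `cell_id`,
#'   `area_um2`, `integrated_intensity`).
#' @param roles Data frame with `cell_id`, `role` columns, or a list of
#'   role-annotated `cell_roi`s.
#' @param iqr_k Fence multiplier for [remove_outliers_iqr()].
#' @return Data frame, one row per role: role, n_foci, mean_area_um2,
#'   sd_area_um2, mean_integrated_intensity, sd_integrated_intensity, empty.
#' @export
mother_daughter_stats <- function(foci, roles, iqr_k = 1.5) {
  if (is.list(roles) && !is.data.frame(roles)) {
    roles <- data.frame(
      cell_id = vapply(roles, function(r) r$cell_id, numeric(1)),
      role = vapply(roles, function(r) r$role, character(1)))
  }
  if (!all(foci$cell_id %in% roles$cell_id))
    stop("every focus must belong to a role-annotated ROI")
  foci$role <- roles$role[match(foci$cell_id, roles$cell_id)]
  res <- lapply(unique(roles$role), function(rl) {
    fr <- foci[foci$role == rl, , drop = FALSE]
    if (!nrow(fr)) {
      return(data.frame(role = rl, n_foci = 0L, mean_area_um2 = NA_real_,
                        sd_area_um2 = NA_real_,
                        mean_integrated_intensity = NA_real_,
                        sd_integrated_intensity = NA_real_, empty = TRUE))
    }
    a <- suppressWarnings(remove_outliers_iqr(fr$area_um2, iqr_k))
    i <- suppressWarnings(remove_outliers_iqr(fr$integrated_intensity, iqr_k))
    data.frame(role = rl, n_foci = nrow(fr),
               mean_area_um2 = mean(a), sd_area_um2 = stats::sd(a),
               mean_integrated_intensity = mean(i),
               sd_integrated_intensity = stats::sd(i), empty = FALSE)
  })
  do.call(rbind, res)
}

#' Score aggregate inheritance across a budding time-lapse
#'
#' Per timepoint, counts aggregate foci in the mother vs the bud, flags
#' whether the organelle marker has entered the bud, and reports the
#' fraction of aggregates inherited by the bud at the final timepoint.
#'
#' @param foci_by_time List (one element per timepoint) of foci data frames
#'   with `row`, `col` centroids.
#' @param cell_masks List of per-timepoint label masks (1 = mother,
#'   2 = bud). A `NULL` entry skips that timepoint with a warning.
#' @param organelle_masks Optional list of per-timepoint organelle masks.
#' @return List of class `inheritance_result` with `per_timepoint` (data
#'   frame: timepoint, n_mother, n_bud, organelle_in_bud) and
#'   `inherited_fraction`.
#' @export
inheritance_score <- function(foci_by_time, cell_masks,
                              organelle_masks = NULL) {
  stopifnot(length(foci_by_time) == length(cell_masks))
  rows <- list()
  for (t in seq_along(foci_by_time)) {
    m <- cell_masks[[t]]
    if (is.null(m)) {
      warning("no cell mask for timepoint ", t, "; skipped")
      next
    }
    f <- foci_by_time[[t]]
    lab <- if (nrow(f)) m[cbind(pmin(pmax(round(f$row) + 1L, 1L), nrow(m)),
                                pmin(pmax(round(f$col) + 1L, 1L), ncol(m)))]
           else integer(0)
    org_in_bud <- if (is.null(organelle_masks) ||
                        is.null(organelle_masks[[t]])) NA
      else any(organelle_masks[[t]] != 0 & m == 2L)
    rows[[length(rows) + 1L]] <- data.frame(
      timepoint = t - 1L, n_mother = sum(lab == 1L), n_bud = sum(lab == 2L),
      organelle_in_bud = org_in_bud)
  }
  pt <- do.call(rbind, rows)
  last <- pt[nrow(pt), ]
  total <- last$n_mother + last$n_bud
  structure(list(per_timepoint = pt,
                 inherited_fraction = if (total > 0) last$n_bud / total
                                      else NA_real_),
            class = "inheritance_result")
}

#' Two-sample condition comparison
#'
#' `"student_t"` is Welch's unequal-variance t-test; `"mann_whitney"` is the
#' two-sided Mann-Whitney U test, by exact enumeration for small samples
#' without ties and by the tie-corrected normal approximation otherwise.
#' Two identical zero-variance samples under t return p = 1 with a flag
#' rather than an error.
#'
#' @param sample_a,sample_b Numeric vectors.
#' @param test `"student_t"` or `"mann_whitney"`.
#' @return List: `test`, `statistic`, `p_value`, `degenerate`.
#' @export
compare_conditions <- function(sample_a, sample_b,
                               test = c("student_t", "mann_whitney")) {
  test <- match.arg(test)
  if (test == "student_t") {
    stopifnot(length(sample_a) >= 3, length(sample_b) >= 3)
    if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0 &&
          sample_a[1] == sample_b[1]) {
      return(list(test = test, statistic = 0, p_value = 1, degenerate = TRUE))
    }
    ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
    list(test = test, statistic = unname(ht$statistic),
         p_value = ht$p.value, degenerate = FALSE)
  } else {
    stopifnot(length(sample_a) >= 1, length(sample_b) >= 1)
    ties <- any(duplicated(c(sample_a, sample_b)))
    exact <- !ties && length(sample_a) <= 20 && length(sample_b) <= 20
    ht <- suppressWarnings(
      stats::wilcox.test(sample_a, sample_b, exact = exact, correct = TRUE))
    list(test = test, statistic = unname(ht$statistic),
         p_value = ht$p.value, degenerate = FALSE)
  }
}

#' Fold-change arithmetic between two condition summaries
#'
#' Reports the percent increase `100*(b-a)/a`, the fold change `b/a`, and -
#' because "a decrease of x%" is sometimes used in the literature for the
#' remaining-percentage ratio - both decrease conventions:
#' `percent_decrease = 100*(a-b)/a` and `percent_of = 100*b/a`.
#'
#' @param a,b Condition means (denominator `a` must be nonzero).
#' @return List: `percent_increase`, `factor`, `percent_decrease`,
#'   `percent_of`.
#' @export
fold_changes <- function(a, b) {
  if (a == 0) stop("fold change undefined for zero denominator")
  list(percent_increase = 100 * (b - a) / a,
       factor = b / a,
       percent_decrease = 100 * (a - b) / a,
       percent_of = 100 * b / a)
}

#' Summarise one experimental condition
#'
#' @param label Condition label.
#' @param foci Foci table (may span several fields via a `field` column for
#'   the replicate sd of the positive fraction).
#' @param cells Data frame with `cell_id` and optional `field`.
#' @param stoichiometries,diffusions Optional numeric vectors.
#' @return One-row data frame of class `condition_summary`.
#' @export
condition_summary <- function(label, foci, cells, stoichiometries = NULL,
                              diffusions = NULL) {
  pct <- aggregate_positive_fraction(foci, cells$cell_id)
  pct_sd <- NA_real_
  if (!is.null(cells$field)) {
    per_field <- vapply(split(cells, cells$field), function(cf) {
      ff <- foci[foci$cell_id %in% cf$cell_id, , drop = FALSE]
      aggregate_positive_fraction(ff, cf$cell_id)
    }, numeric(1))
    if (length(per_field) > 1) pct_sd <- stats::sd(per_field)
  }
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x))
                     else NA_real_
  out <- data.frame(
    condition = label, n_cells = length(unique(cells$cell_id)),
    n_foci = nrow(foci), pct_positive = pct, pct_positive_sd = pct_sd,
    mean_focus_area_um2 = if (nrow(foci)) mean(foci$area_um2) else NA_real_,
    sd_focus_area_um2 = if (nrow(foci) > 1) stats::sd(foci$area_um2)
                        else NA_real_,
    mean_integrated_intensity = if (nrow(foci))
      mean(foci$integrated_intensity) else NA_real_,
    sd_integrated_intensity = if (nrow(foci) > 1)
      stats::sd(foci$integrated_intensity) else NA_real_,
    mean_stoichiometry = if (length(stoichiometries))
      mean(stoichiometries) else NA_real_,
    sem_stoichiometry = if (length(stoichiometries)) sem(stoichiometries)
                        else NA_real_,
    mean_diffusion = if (length(diffusions)) mean(diffusions) else NA_real_,
    sem_diffusion = if (length(diffusions)) sem(diffusions) else NA_real_)
  class(out) <- c("condition_summary", "data.frame")
  out
}
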