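#' @name detection
#' @title Cell segmentation and per-cell foci detection
#' @description Reimplementation of a per-cell spot-detection workflow: cell
#'   outlines are obtained either from a supplied label mask or by a radial
#'   dark-boundary search around user seeds (after the Cell Magic Wand
#'   approach); fluorescent foci are then detected inside each cell outline
#'   by per-ROI thresholding and 8-connected component labelling, and their
#'   area and intensity statistics extracted.
NULL

shift_mat <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' 8-connected component labelling of a binary image
#'
#' @param bin Logical matrix.
#' @return Integer matrix; 0 = background, components numbered 1..k.
#' @export
label_components <- function(bin) {
  stopifnot(is.matrix(bin))
  bin <- bin != 0
  n_fg <- sum(bin)
  if (n_fg == 0) return(matrix(0L, nrow(bin), ncol(bin)))
  lab <- matrix(Inf, nrow(bin), ncol(bin))
  lab[bin] <- seq_len(n_fg)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  repeat {
    new <- lab
    for (i in seq_len(nrow(offs))) {
      new <- pmin(new, shift_mat(lab, offs$dr[i], offs$dc[i], Inf))
    }
    new[!bin] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, nrow(bin), ncol(bin))
  ids <- sort(unique(lab[bin]))
  out[bin] <- match(lab[bin], ids)
  out
}

#' Otsu threshold of a numeric sample
#'
#' Classic between-class-variance maximisation over a 256-bin histogram of
#' the supplied values (typically the pixels of one cell ROI).
#'
#' @param vals Numeric vector.
#' @return Threshold value; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(vals) {
  vals <- vals[is.finite(vals)]
  if (!length(vals) || max(vals) == min(vals)) return(suppressWarnings(max(vals)))
  nb <- 256L
  br <- seq(min(vals), max(vals), length.out = nb + 1L)
  h <- tabulate(pmin(findInterval(vals, br, rightmost.closed = TRUE), nb), nb)
  mids <- (br[-1] + br[-(nb + 1L)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  tot <- w[nb]; mu_tot <- mu[nb]
  w0 <- w[-nb]; w1 <- tot - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nb - 1L)
  bcv[valid] <- (mu_tot * w0[valid] - tot * mu[-nb][valid])^2 /
    (w0[valid] * w1[valid])
  mids[which.max(bcv)]
}

new_cell_roi <- function(cell_id, mask, pixel_size, role = "unassigned") {
  structure(list(cell_id = cell_id, mask = mask, role = role,
                 area_um2 = sum(mask) * (pixel_size / 1000)^2),
            class = "cell_roi")
}

#' Build cell ROIs from a label mask
#'
#' @param label_mask Integer matrix, 0 = background, k = cell k.
#' @param pixel_size Pixel size, nm.
#' @param roles Optional named character vector mapping label -> role
#'   (`"mother"`, `"daughter"` or `"unassigned"`).
#' @return List of `cell_roi` objects.
#' @export
rois_from_labels <- function(label_mask, pixel_size = 120, roles = NULL) {
  ids <- sort(setdiff(unique(as.integer(label_mask)), 0L))
  lapply(ids, function(k) {
    role <- if (!is.null(roles) && as.character(k) %in% names(roles))
      roles[[as.character(k)]] else "unassigned"
    new_cell_roi(k, label_mask == k, pixel_size, role)
  })
}

bilinear <- function(image, r, c) {
  # r, c are 1-based fractional matrix coordinates
  r0 <- floor(r); c0 <- floor(c)
  r0 <- pmin(pmax(r0, 1L), nrow(image) - 1L)
  c0 <- pmin(pmax(c0, 1L), ncol(image) - 1L)
  fr <- r - r0; fc <- c - c0
  image[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    image[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    image[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    image[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Segment cells from a brightfield image or pass through a label mask
#'
#' With `seeds = NULL` the input is interpreted as a label mask and converted
#' to ROIs unchanged. With seeds, each seed launches a radial search for the
#' dark cell boundary (minimum-intensity radius along each of `n_rays` rays,
#' median-smoothed), in the spirit of the Cell Magic Wand tool. A seed whose
#' rays find no boundary contrast above the image noise yields no ROI and is
#' reported via a message. Overlaps are resolved by first-claim priority in
#' seed order.
#'
#' @param image Numeric matrix (brightfield) or integer label mask.
#' @param seeds Optional n x 2 matrix of 0-based (row, col) seed points.
#' @param radius_bounds `c(min, max)` admissible cell radius, pixels.
#' @param pixel_size Pixel size, nm.
#' @param n_rays Number of radial probes.
#' @return List of `cell_roi` objects.
#' @export
segment_cells <- function(image, seeds = NULL, radius_bounds = c(3, 30),
                          pixel_size = 120, n_rays = 180) {
  stopifnot(is.matrix(image))
  if (is.null(seeds)) return(rois_from_labels(image, pixel_size))
  seeds <- rbind(seeds)
  noise_sd <- stats::mad(as.numeric(image))
  claimed <- matrix(FALSE, nrow(image), ncol(image))
  rois <- list()
  angles <- seq(0, 2 * pi, length.out = n_rays + 1L)[-(n_rays + 1L)]
  radii <- seq(radius_bounds[1], radius_bounds[2], by = 0.5)
  for (s in seq_len(nrow(seeds))) {
    sr <- seeds[s, 1] + 1; sc <- seeds[s, 2] + 1   # to 1-based
    seed_int <- stats::median(image[
      pmin(pmax(round(sr) + (-1:1), 1), nrow(image)),
      pmin(pmax(round(sc) + (-1:1), 1), ncol(image))])
    rb <- numeric(length(angles)); depth <- numeric(length(angles))
    for (a in seq_along(angles)) {
      rr <- sr + radii * sin(angles[a])
      cc <- sc + radii * cos(angles[a])
      ok <- rr >= 1 & rr <= nrow(image) & cc >= 1 & cc <= ncol(image)
      if (!any(ok)) { rb[a] <- NA; depth[a] <- 0; next }
      prof <- bilinear(image, rr[ok], cc[ok])
      j <- which.min(prof)
      rb[a] <- radii[ok][j]
      depth[a] <- seed_int - prof[j]
    }
    if (all(is.na(rb)) || stats::median(depth, na.rm = TRUE) <=
          5 * noise_sd + 1e-9) {
      message("segment_cells: seed ", s,
              " found no enclosing boundary; skipped")
      next
    }
    rb[is.na(rb)] <- stats::median(rb, na.rm = TRUE)
    # circular median smoothing of the boundary radius profile
    k <- 3L
    ext <- c(utils::tail(rb, k), rb, utils::head(rb, k))
    rb_s <- vapply(seq_along(rb), function(i)
      stats::median(ext[i:(i + 2 * k)]), numeric(1))
    ri <- outer(seq_len(nrow(image)) - sr, rep(1, ncol(image)))
    ci <- outer(rep(1, nrow(image)), seq_len(ncol(image)) - sc)
    rp <- sqrt(ri^2 + ci^2)
    ang <- atan2(ri, ci) %% (2 * pi)
    idx <- pmin(floor(ang / (2 * pi) * n_rays) + 1L, n_rays)
    inside <- rp <= rb_s[idx] & !claimed
    if (!any(inside)) {
      message("segment_cells: seed ", s, " yielded an empty region; skipped")
      next
    }
    claimed <- claimed | inside
    rois[[length(rois) + 1L]] <- new_cell_roi(length(rois) + 1L, inside,
                                              pixel_size)
  }
  rois
}

as_roi_list <- function(cell_rois, pixel_size) {
  if (is.matrix(cell_rois)) return(rois_from_labels(cell_rois, pixel_size))
  if (inherits(cell_rois, "cell_roi")) return(list(cell_rois))
  cell_rois
}

#' Detect fluorescent foci inside per-cell ROIs
#'
#' The threshold is computed per ROI from that ROI's pixels only
#' (detection in one cell is unaffected by pixels outside it). Connected
#' components (8-connectivity) of strictly suprathreshold pixels with at
#' least `min_area_px` pixels become foci; each record carries the area,
#' the raw integrated intensity, a background-subtracted integrated
#' intensity (in-cell non-focus median times focus area) and the mean
#' intensity. Centroids are intensity-weighted, 0-based (row, col).
#'
#' @param image Numeric matrix (one frame).
#' @param cell_rois Label matrix or list of `cell_roi` objects.
#' @param threshold_method One of `"otsu"`, `"mean"`, `"percentile"`,
#'   `"fixed"`.
#' @param min_area_px Minimum component size, pixels.
#' @param fixed_value Threshold for `method = "fixed"`.
#' @param percentile Quantile for `method = "percentile"`.
#' @param min_snr Quality gate: a component is kept only when its peak
#'   exceeds the in-cell background median by at least `min_snr` robust
#'   standard deviations. Set to 0 to disable (bare thresholding).
#' @param pixel_size Pixel size, nm (for areas in um^2).
#' @param frame Frame index stored in the output, 0-based.
#' @return Data frame: focus_id, cell_id, frame, row, col, area_px,
#'   area_um2, integrated_intensity, integrated_intensity_bgsub,
#'   mean_intensity.
#' @export
detect_foci <- function(image, cell_rois,
                        threshold_method = c("otsu", "mean", "percentile",
                                             "fixed"),
                        min_area_px = 4, fixed_value = NULL,
                        percentile = 0.975, min_snr = 5,
                        pixel_size = 120, frame = 0L) {
  threshold_method <- match.arg(threshold_method)
  rois <- as_roi_list(cell_rois, pixel_size)
  out <- list()
  fid <- 0L
  for (roi in rois) {
    if (any(dim(roi$mask) != dim(image)))
      stop("ROI mask dimensions do not match the image")
    vals <- image[roi$mask]
    if (!length(vals)) next
    thr <- switch(threshold_method,
      otsu = otsu_threshold(vals),
      mean = mean(vals),
      percentile = stats::quantile(vals, percentile, names = FALSE, type = 7),
      fixed = {
        if (is.null(fixed_value)) stop("fixed_value required for method 'fixed'")
        fixed_value
      })
    bin <- (image > thr) & roi$mask
    if (!any(bin)) next
    lab <- label_components(bin)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_area_px)
    if (!length(keep)) next
    focus_any <- lab > 0
    bg_med <- stats::median(image[roi$mask & !focus_any])
    if (is.na(bg_med)) bg_med <- 0
    # SNR gate baseline: whole-ROI median/mad, robust to suprathreshold
    # speckle swallowing the upper half of the histogram
    gate <- stats::median(vals) + min_snr * stats::mad(vals)
    for (k in keep) {
      px <- which(lab == k, arr.ind = TRUE)
      ints <- image[px]
      if (min_snr > 0 && max(ints) < gate) next
      w <- pmax(ints - bg_med, 0)
      if (sum(w) <= 0) w <- rep(1, length(ints))
      fid <- fid + 1L
      out[[fid]] <- data.frame(
        focus_id = fid, cell_id = roi$cell_id, frame = as.integer(frame),
        row = sum(w * (px[, 1] - 1)) / sum(w),
        col = sum(w * (px[, 2] - 1)) / sum(w),
        area_px = length(ints),
        area_um2 = length(ints) * (pixel_size / 1000)^2,
        integrated_intensity = sum(ints),
        integrated_intensity_bgsub = sum(ints) - bg_med * length(ints),
        mean_intensity = mean(ints))
    }
  }
  if (!length(out)) {
    return(data.frame(focus_id = integer(), cell_id = integer(),
                      frame = integer(), row = numeric(), col = numeric(),
                      area_px = integer(), area_um2 = numeric(),
                      integrated_intensity = numeric(),
                      integrated_intensity_bgsub = numeric(),
                      mean_intensity = numeric()))
  }
  do.call(rbind, out)
}

#' Percentage of cells containing at least one detected focus
#'
#' An aggregate-positive cell is a cell with at least one detected
#' fluorescent focus.
#'
#' @param foci Data frame with a `cell_id` column (from [detect_foci()]).
#' @param cells Cell ids in the population: an integer vector, a label
#'   mask, or a list of `cell_roi`s.
#' @return Percentage in `[0, 100]`.
#' @export
aggregate_positive_fraction <- function(foci, cells) {
  ids <- if (is.matrix(cells)) sort(setdiff(unique(as.integer(cells)), 0L))
  else if (is.list(cells)) vapply(cells, function(r) r$cell_id, numeric(1))
  else cells
  if (!length(ids)) stop("aggregate_positive_fraction undefined for zero cells")
  pos <- unique(foci$cell_id)
  100 * sum(ids %in% pos) / length(ids)
}

#' Remove outliers by the interquartile fence
#'
#' Drops values outside `[Q1 - k*IQR, Q3 + k*IQR]`, quartiles by linear
#' interpolation (type 7). Fewer than 4 values are returned unchanged with
#' a warning.
#'
#' @param values Numeric vector.
#' @param k Fence multiplier (1.5 = standard).
#' @return Filtered numeric vector.
#' @export
remove_outliers_iqr <- function(values, k = 1.5) {
  if (length(values) < 4) {
    warning("fewer than 4 values; returned unchanged")
    return(values)
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  values[values >= q[1] - k * iqr & values <= q[2] + k * iqr]
}
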