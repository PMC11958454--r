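#' @name tracking
#' @title Sub-pixel localization, track linking and diffusion estimation
#' @description Foci are localized to sub-pixel precision by iterative
#'   Gaussian-mask fitting (centroid refinement under a Gaussian weight
#'   recentred each iteration), linked frame-to-frame by greedy
#'   nearest-neighbour assignment, and their mobility summarised by the
#'   initial gradient of the mean squared displacement, which equals 4D for
#'   two-dimensional Brownian motion in a purely viscous environment.
NULL

#' Localize one focus by iterative Gaussian-mask fitting
#'
#' Starting from `initial_guess`, the centre is refined as the centroid of
#' the background-subtracted window under a Gaussian weight centred on the
#' current estimate, iterated until the centre moves by less than 1e-3 px
#' (at most 100 iterations). The local background and its noise are taken
#' from the window perimeter. The fitted width is the weighted second
#' moment corrected for the mask width; the localization precision follows
#' the photon-statistics (Thompson) formula with a background term.
#'
#' @param image Numeric matrix.
#' @param initial_guess 0-based `c(row, col)` starting point.
#' @param window_radius Half-width of the square fit window, px.
#' @param psf_sigma_px Nominal PSF sigma used for the mask, px.
#' @param pixel_size Pixel size, nm (for the precision estimate).
#' @param quiet Suppress rejection warnings (for batch use).
#' @return A list of class `localization` (`row`, `col` 0-based sub-pixel;
#'   `fitted_sigma` px; `amplitude`; `local_background`; `summed_intensity`
#'   background-corrected; `precision_nm`; `n_iter`), or `NULL` with a
#'   warning when the fit does not converge or the spot is not
#'   distinguishable from background noise.
#' @export
localize_focus <- function(image, initial_guess, window_radius = 8,
                           psf_sigma_px = 0.725, pixel_size = 120,
                           quiet = FALSE) {
  r0 <- round(initial_guess[1]) + 1L   # to 1-based
  c0 <- round(initial_guess[2]) + 1L
  w <- as.integer(window_radius)
  if (r0 - w < 1 || r0 + w > nrow(image) || c0 - w < 1 || c0 + w > ncol(image))
    stop("fit window extends outside the image")
  win <- image[(r0 - w):(r0 + w), (c0 - w):(c0 + w)]
  n <- 2L * w + 1L
  # background from the outer two pixel rings; intensity from a tight
  # circular aperture (the background-mean error then multiplies ~50 rather
  # than ~300 pixels, which matters for resolving single-molecule steps)
  ring <- pmax(abs(row(win) - w - 1L), abs(col(win) - w - 1L)) >= w - 1L
  bg <- mean(win[ring])
  noise_sd <- stats::sd(win[ring])
  sub <- pmax(win - bg, 0)
  rr <- matrix((r0 - w):(r0 + w) - 1, n, n)          # 0-based rows
  cc <- matrix((c0 - w):(c0 + w) - 1, n, n, byrow = TRUE)
  ctr <- c(initial_guess[1], initial_guess[2])
  sig_mask <- 1.5 * psf_sigma_px
  reject <- function(msg) {
    if (!quiet) warning("localization rejected: ", msg)
    NULL
  }
  converged <- FALSE
  it <- 0L
  while (it < 100L) {
    it <- it + 1L
    wt <- exp(-((rr - ctr[1])^2 + (cc - ctr[2])^2) / (2 * sig_mask^2))
    m <- sub * wt
    sm <- sum(m)
    if (sm <= 0) return(reject("no signal above background in the window"))
    new_ctr <- c(sum(m * rr), sum(m * cc)) / sm
    if (sqrt(sum((new_ctr - ctr)^2)) < 1e-3) {
      ctr <- new_ctr
      converged <- TRUE
      break
    }
    ctr <- new_ctr
  }
  if (!converged) return(reject("no convergence within 100 iterations"))
  if (ctr[1] < rr[1, 1] || ctr[1] > rr[n, 1] ||
      ctr[2] < cc[1, 1] || ctr[2] > cc[1, n])
    return(reject("fitted centre left the window"))
  r_ap <- min(max(4, ceiling(5 * psf_sigma_px)), w)
  ap <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= r_ap^2
  summed <- sum(win[ap]) - bg * sum(ap)
  wt <- exp(-((rr - ctr[1])^2 + (cc - ctr[2])^2) / (2 * sig_mask^2))
  m <- sub * wt
  var_meas <- (sum(m * (rr - ctr[1])^2) + sum(m * (cc - ctr[2])^2)) /
    (2 * sum(m))
  inv <- 1 / var_meas - 1 / sig_mask^2    # undo Gaussian-mask shrinkage
  fitted_sigma <- if (inv > 0) sqrt(1 / inv) else sqrt(var_meas)
  amplitude <- summed / (2 * pi * fitted_sigma^2)
  if (summed <= 0 || amplitude <= 2 * noise_sd)
    return(reject("amplitude not distinguishable from background noise"))
  s_nm <- fitted_sigma * pixel_size
  n_ph <- max(summed, 1)
  prec <- sqrt((s_nm^2 + pixel_size^2 / 12) / n_ph +
                 8 * pi * s_nm^4 * noise_sd^2 / (pixel_size^2 * n_ph^2))
  structure(list(row = ctr[1], col = ctr[2], fitted_sigma = fitted_sigma,
                 amplitude = amplitude, local_background = bg,
                 summed_intensity = summed, precision_nm = prec,
                 n_iter = it),
            class = "localization")
}

#' Follow detected foci through a movie
#'
#' Seeds (e.g. foci detected on the first frame) are re-localized in every
#' subsequent frame with [localize_focus()], each time starting from the
#' previous position. A seed stops being followed when its localization is
#' rejected (typically once the focus has fully photobleached). The
#' resulting per-frame localizations can be linked into formal tracks with
#' [link_tracks()].
#'
#' @param movie frames x rows x cols array.
#' @param seeds n x 2 matrix of 0-based (row, col) positions at the first
#'   frame (e.g. `cbind(foci$row, foci$col)`).
#' @param window_radius,psf_sigma_px,pixel_size Passed to [localize_focus()].
#' @param start_frame 0-based frame at which the seeds were detected.
#' @return Data frame of localizations: frame (0-based), row, col,
#'   fitted_sigma, amplitude, local_background, summed_intensity,
#'   precision_nm, seed.
#' @export
track_stack <- function(movie, seeds, window_radius = 8, psf_sigma_px = 0.725,
                        pixel_size = 120, start_frame = 0L) {
  seeds <- rbind(seeds)
  nf <- dim(movie)[1]; rows <- dim(movie)[2]; cols <- dim(movie)[3]
  w <- window_radius
  pos <- lapply(seq_len(nrow(seeds)), function(i) seeds[i, ])
  alive <- rep(TRUE, nrow(seeds))
  out <- vector("list", nf)
  for (f in (start_frame + 1L):nf) {
    img <- movie[f, , ]
    recs <- list()
    for (i in which(alive)) {
      g <- pos[[i]]
      g[1] <- min(max(g[1], w), rows - 1 - w)   # keep the window inside
      g[2] <- min(max(g[2], w), cols - 1 - w)
      loc <- localize_focus(img, g, window_radius = w,
                            psf_sigma_px = psf_sigma_px,
                            pixel_size = pixel_size, quiet = TRUE)
      if (is.null(loc)) {
        alive[i] <- FALSE
        next
      }
      pos[[i]] <- c(loc$row, loc$col)
      recs[[length(recs) + 1L]] <- data.frame(
        frame = f - 1L, row = loc$row, col = loc$col,
        fitted_sigma = loc$fitted_sigma, amplitude = loc$amplitude,
        local_background = loc$local_background,
        summed_intensity = loc$summed_intensity,
        precision_nm = loc$precision_nm, seed = i)
    }
    if (length(recs)) out[[f]] <- do.call(rbind, recs)
    if (!any(alive)) break
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(frame = integer(), row = numeric(), col = numeric(),
                      fitted_sigma = numeric(), amplitude = numeric(),
                      local_background = numeric(),
                      summed_intensity = numeric(), precision_nm = numeric(),
                      seed = integer()))
  }
  do.call(rbind, out)
}

#' Link per-frame localizations into tracks
#'
#' Greedy nearest-neighbour assignment between consecutive frames: candidate
#' links are taken in order of increasing distance; links beyond `max_disp`
#' are forbidden; unmatched localizations start new tracks. No gap closing.
#'
#' @param locs Data frame with columns `frame`, `row`, `col` (pixels).
#' @param max_disp Maximum frame-to-frame displacement, px.
#' @return `locs` with a `track_id` column, ordered by track and frame.
#' @export
link_tracks <- function(locs, max_disp = 5) {
  stopifnot(max_disp > 0)
  if (!nrow(locs)) return(cbind(locs, track_id = integer()))
  locs <- locs[order(locs$frame), , drop = FALSE]
  locs$track_id <- NA_integer_
  frames <- sort(unique(locs$frame))
  next_id <- 0L
  idx_prev <- which(locs$frame == frames[1])
  locs$track_id[idx_prev] <- next_id + seq_along(idx_prev)
  next_id <- next_id + length(idx_prev)
  for (k in seq_along(frames)[-1]) {
    idx_cur <- which(locs$frame == frames[k])
    if (frames[k] - frames[k - 1] != 1L) {
      idx_prev <- idx_cur           # gap: previous tracks all terminate
      locs$track_id[idx_cur] <- next_id + seq_along(idx_cur)
      next_id <- next_id + length(idx_cur)
      next
    }
    d <- outer(seq_along(idx_prev), seq_along(idx_cur), function(i, j)
      sqrt((locs$row[idx_prev[i]] - locs$row[idx_cur[j]])^2 +
             (locs$col[idx_prev[i]] - locs$col[idx_cur[j]])^2))
    ord <- order(d)
    used_p <- logical(length(idx_prev)); used_c <- logical(length(idx_cur))
    for (o in ord) {
      if (d[o] > max_disp) break
      i <- (o - 1L) %% length(idx_prev) + 1L
      j <- (o - 1L) %/% length(idx_prev) + 1L
      if (used_p[i] || used_c[j]) next
      used_p[i] <- TRUE; used_c[j] <- TRUE
      locs$track_id[idx_cur[j]] <- locs$track_id[idx_prev[i]]
    }
    new_c <- which(!used_c)
    if (length(new_c)) {
      locs$track_id[idx_cur[new_c]] <- next_id + seq_along(new_c)
      next_id <- next_id + length(new_c)
    }
    idx_prev <- idx_cur
  }
  locs[order(locs$track_id, locs$frame), , drop = FALSE]
}

#' Mean squared displacement of one track
#'
#' `MSD(n*dt)` is the mean over all frame pairs `(i, i+n)` of the squared 2D
#' displacement, for lags `n = 1..min(len-1, n_max)`.
#'
#' @param track Data frame with `frame`, `row`, `col` (pixels) for one track.
#' @param pixel_size Pixel size, nm.
#' @param frame_interval Frame interval, s.
#' @param n_max Maximum lag (frames).
#' @return Data frame `dt` (s), `msd` (um^2), `n_pairs`.
#' @export
compute_msd <- function(track, pixel_size, frame_interval, n_max = 20L) {
  if (nrow(track) < 2) stop("track must have at least 2 localizations")
  track <- track[order(track$frame), , drop = FALSE]
  px_um <- pixel_size / 1000
  x <- track$col * px_um
  y <- track$row * px_um
  fr <- track$frame
  span <- max(fr) - min(fr)
  lags <- seq_len(min(span, n_max))
  res <- lapply(lags, function(n) {
    j <- match(fr + n, fr)
    ok <- !is.na(j)
    if (!any(ok)) return(NULL)
    d2 <- (x[j[ok]] - x[ok])^2 + (y[j[ok]] - y[ok])^2
    data.frame(dt = n * frame_interval, msd = mean(d2), n_pairs = sum(ok))
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  structure(out, class = c("msd_curve", "data.frame"))
}

#' Diffusion coefficient from the initial MSD gradient
#'
#' Weighted least-squares line (weights = number of displacement pairs)
#' through the first `n_points` MSD points; `D = slope / 4`. The intercept
#' is retained: it absorbs the localization-noise offset (~`4*sigma_loc^2`
#' for a static emitter).
#'
#' @param msd An `msd_curve` from [compute_msd()].
#' @param n_points Number of initial points to fit (warns and uses all,
#'   minimum 2, when fewer are available).
#' @return List of class `diffusion_estimate`: `d_coeff` (um^2/s),
#'   `intercept` (um^2), `n_points_used`, `fit_error` (s.e. of D).
#' @export
estimate_diffusion <- function(msd, n_points = 4L) {
  if (nrow(msd) < 2) stop("need at least 2 MSD points")
  if (nrow(msd) < n_points) {
    warning("fewer MSD points than requested; using all ", nrow(msd))
    n_points <- nrow(msd)
  }
  m <- msd[seq_len(n_points), , drop = FALSE]
  fit <- stats::lm(msd ~ dt, data = m, weights = m$n_pairs)
  sl <- unname(stats::coef(fit)[2])
  se <- if (n_points > 2)
    suppressWarnings(summary(fit)$coefficients[2, 2]) else NA_real_
  structure(list(d_coeff = sl / 4, intercept = unname(stats::coef(fit)[1]),
                 n_points_used = n_points,
                 fit_error = if (is.na(se)) NA_real_ else se / 4),
            class = "diffusion_estimate")
}

#' Per-track diffusion estimates for a linked localization table
#'
#' @param tracks Output of [link_tracks()].
#' @param pixel_size,frame_interval,n_max See [compute_msd()].
#' @param n_points See [estimate_diffusion()].
#' @param min_length Minimum localizations per track.
#' @return Data frame: track_id, d_coeff, intercept, n_points_used, n_locs.
#' @export
estimate_diffusion_tracks <- function(tracks, pixel_size, frame_interval,
                                      n_points = 4L, n_max = 20L,
                                      min_length = 8L) {
  ids <- unique(tracks$track_id)
  res <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    if (nrow(tr) < max(min_length, n_points + 1L)) return(NULL)
    est <- estimate_diffusion(
      compute_msd(tr, pixel_size, frame_interval, n_max), n_points)
    data.frame(track_id = id, d_coeff = est$d_coeff,
               intercept = est$intercept, n_points_used = est$n_points_used,
               n_locs = nrow(tr))
  })
  out <- res[!vapply(res, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(track_id = integer(), d_coeff = numeric(),
                      intercept = numeric(), n_points_used = integer(),
                      n_locs = integer()))
  }
  do.call(rbind, out)
}
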