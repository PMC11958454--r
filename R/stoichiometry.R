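#' @name stoichiometry
#' @title Molecule counting by stepwise-photobleaching brightness calibration
#' @description The number of fluorescent reporter molecules in a tracked
#'   focus is estimated as S = I0 / I_single: the initial unbleached track
#'   intensity divided by the brightness of a single photoactive fluorophore.
#'   I_single is calibrated in situ from the sizes of terminal photobleaching
#'   steps (the last molecule bleaching to background), after edge-preserving
#'   Chung-Kennedy filtering and change-point step detection. Population
#'   distributions are rendered by Gaussian kernel density estimation with
#'   reflection at zero. An optional dark-fraction correction (around 7% of
#'   fluorescent proteins never mature to a photoactive state) scales S by
#'   1/(1 - p_dark).
NULL

#' Chung-Kennedy edge-preserving filter
#'
#' Each point is replaced by a combination of the forward (past-window) and
#' backward (future-window) running means, weighted by the inverse local
#' variance of each window raised to `weighting_exponent`. Plateaus are
#' smoothed while step edges are preserved: at an edge one window lies
#' entirely on a single plateau and receives all the weight.
#'
#' @param trace Numeric vector.
#' @param window Window length, frames (>= 2).
#' @param weighting_exponent Exponent applied to the inverse variances.
#' @return Filtered numeric vector of the same length.
#' @export
chung_kennedy_filter <- function(trace, window = 10L, weighting_exponent = 2) {
  stopifnot(window >= 2)
  n <- length(trace)
  if (n <= window) {
    warning("trace shorter than the filter window; returned unchanged")
    return(trace)
  }
  out <- numeric(n)
  p <- weighting_exponent
  for (t in seq_len(n)) {
    fw <- trace[max(1L, t - window + 1L):t]
    bw <- trace[t:min(n, t + window - 1L)]
    mf <- mean(fw); mb <- mean(bw)
    vf <- if (length(fw) > 1) stats::var(fw) else 0
    vb <- if (length(bw) > 1) stats::var(bw) else 0
    out[t] <- if (vf == 0 && vb == 0) (mf + mb) / 2
    else if (vf == 0) mf
    else if (vb == 0) mb
    else {
      wf <- vf^(-p); wb <- vb^(-p)
      (wf * mf + wb * mb) / (wf + wb)
    }
  }
  out
}

best_split <- function(x) {
  n <- length(x)
  i <- seq_len(n - 1L)
  cs <- cumsum(x)
  m1 <- cs[i] / i
  m2 <- (cs[n] - cs[i]) / (n - i)
  gain <- i * (n - i) / n * (m1 - m2)^2
  j <- which.max(gain)
  list(at = j, delta = m1[j] - m2[j])
}

#' Detect intensity steps by recursive change-point segmentation
#'
#' The trace is recursively split at the change point giving the largest
#' reduction in residual sum of squares; a split is accepted when the level
#' change is at least `min_step` and both resulting segments persist for at
#' least `min_dwell` frames. Steps are reported as `(frame, size)` pairs
#' where `frame` is the 0-based index of the first frame at the new level
#' and `size = level_before - level_after` (positive for photobleaching
#' drops).
#'
#' @param trace Numeric vector (typically Chung-Kennedy filtered).
#' @param min_step Minimum absolute level change; `NULL` uses an automatic
#'   threshold of 3x the robust noise sd estimated from first differences.
#' @param min_dwell Minimum segment length, frames.
#' @return Data frame `frame`, `size`, `level_before`, `level_after`
#'   (zero rows if no steps found).
#' @export
detect_steps <- function(trace, min_step = NULL, min_dwell = 5L) {
  stopifnot(length(trace) >= 1)
  if (is.null(min_step)) {
    min_step <- 3 * stats::mad(diff(trace)) / sqrt(2)
    if (min_step == 0) min_step <- .Machine$double.eps
  }
  bounds <- integer(0)
  recurse <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < 2L * min_dwell) return(invisible(NULL))
    sp <- best_split(trace[lo:hi])
    if (abs(sp$delta) < min_step) return(invisible(NULL))
    if (sp$at < min_dwell || (n - sp$at) < min_dwell) return(invisible(NULL))
    cut <- lo + sp$at - 1L
    bounds <<- c(bounds, cut)
    recurse(lo, cut)
    recurse(cut + 1L, hi)
  }
  recurse(1L, length(trace))
  if (!length(bounds)) {
    return(data.frame(frame = integer(), size = numeric(),
                      level_before = numeric(), level_after = numeric()))
  }
  bounds <- sort(bounds)
  seg_start <- c(1L, bounds + 1L)
  seg_end <- c(bounds, length(trace))
  lev <- vapply(seq_along(seg_start), function(k)
    mean(trace[seg_start[k]:seg_end[k]]), numeric(1))
  data.frame(frame = seg_start[-1] - 1L,          # 0-based first frame after
             size = lev[-length(lev)] - lev[-1],
             level_before = lev[-length(lev)],
             level_after = lev[-1])
}

trace_noise_sd <- function(trace) stats::mad(diff(trace)) / sqrt(2)

# Noise at the bleached end of a trace: shot noise scales with intensity, so
# the tail (background-level) portion sets the right scale for resolving
# single-molecule terminal steps.
tail_noise_sd <- function(trace, n_tail = 50L) {
  n <- length(trace)
  trace_noise_sd(trace[max(1L, n - n_tail + 1L):n])
}

is_fully_bleached <- function(trace, min_dwell = 5L) {
  n <- length(trace)
  if (n < min_dwell) return(FALSE)
  tail_lvl <- mean(trace[(n - min_dwell + 1L):n])
  abs(tail_lvl) <= max(3 * trace_noise_sd(trace), 0.05 * max(abs(trace)))
}

kde_peak <- function(x, bandwidth = NULL) {
  d <- kde_distribution(x, bandwidth = bandwidth, min_n = 2L)
  d$peaks[which.max(d$peak_heights)]
}

#' Calibrate the brightness of a single fluorophore
#'
#' `method = "terminal_steps"`: each fully-photobleached trace is
#' Chung-Kennedy filtered and step-detected; the size of its last
#' photobleaching step (the final molecule dropping to background) is
#' collected, and I_single is the mode (KDE peak) of those terminal sizes.
#' `method = "fourier_pairwise"`: I_single is the first peak of the
#' pairwise-difference distribution of the filtered trace intensities
#' (differences cluster at integer multiples of the single-molecule
#' brightness). Confidence interval by bootstrap over traces.
#'
#' @param traces List of numeric intensity traces reaching full photobleaching.
#' @param method Calibration method.
#' @param window,min_dwell Chung-Kennedy / step-detection parameters.
#' @param n_boot Bootstrap replicates for the CI.
#' @return List of class `single_molecule_brightness`: `value`, `ci`,
#'   `method`, `n_steps_used`.
#' @export
single_molecule_brightness <- function(traces,
                                       method = c("terminal_steps",
                                                  "fourier_pairwise"),
                                       window = 10L, min_dwell = 5L,
                                       n_boot = 200L) {
  method <- match.arg(method)
  stopifnot(is.list(traces), length(traces) >= 1)
  bleached <- vapply(traces, is_fully_bleached, logical(1),
                     min_dwell = min_dwell)
  if (!any(bleached)) {
    stop("no trace reaches full photobleaching (terminal level ",
         "indistinguishable from zero); cannot calibrate I_single")
  }
  traces <- traces[bleached]
  stat <- if (method == "terminal_steps") {
    terminal_sizes <- function(trs) {
      v <- vapply(trs, function(tr) {
        f <- suppressWarnings(chung_kennedy_filter(tr, window))
        ms <- 3 * tail_noise_sd(tr)
        if (ms == 0) ms <- NULL
        st <- detect_steps(f, min_step = ms, min_dwell = min_dwell)
        # terminal step: a drop that lands at a statistically-zero level
        st <- st[st$size > 0 &
                   abs(st$level_after) < max(3 * tail_noise_sd(tr), 1e-9), ,
                 drop = FALSE]
        if (!nrow(st)) return(NA_real_)
        st$size[nrow(st)]
      }, numeric(1))
      v[!is.na(v)]
    }
    vals <- terminal_sizes(traces)
    if (length(vals) < 1) stop("no photobleaching steps detected in any trace")
    list(values = vals,
         estimate = function(v) if (length(unique(v)) == 1L) v[1]
                                else kde_peak(v))
  } else {
    pairwise_vals <- function(trs) {
      unlist(lapply(trs, function(tr) {
        f <- suppressWarnings(chung_kennedy_filter(tr, window))
        f <- f[seq(1L, length(f), by = max(1L, min_dwell))]
        if (length(f) > 60L) f <- f[round(seq(1, length(f), length.out = 60))]
        d <- as.numeric(outer(f, f, "-"))
        d[d > 3 * trace_noise_sd(tr)]
      }))
    }
    first_peak <- function(d) {
      if (!length(d)) return(NA_real_)
      if (length(unique(d)) == 1L) return(d[1])
      d <- d[d <= stats::quantile(d, 0.5)]   # focus on small spacings
      dens <- stats::density(d, n = 512, from = 0)
      i <- 2:511
      pk <- dens$x[i][dens$y[i] >= dens$y[i - 1] & dens$y[i] > dens$y[i + 1] &
                        dens$y[i] > 0.05 * max(dens$y)]
      if (!length(pk)) dens$x[which.max(dens$y)] else min(pk)
    }
    vals <- pairwise_vals(traces)
    list(values = vals, estimate = first_peak)
  }
  value <- stat$estimate(stat$values)
  if (length(unique(stat$values)) == 1L) {
    ci <- c(value, value)
  } else if (method == "terminal_steps") {
    boot <- vapply(seq_len(n_boot), function(b) {
      v <- sample(stat$values, replace = TRUE)
      if (length(unique(v)) == 1L) v[1] else kde_peak(v)
    }, numeric(1))
    ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  } else {
    boot <- vapply(seq_len(n_boot), function(b)
      stat$estimate(sample(stat$values, replace = TRUE)), numeric(1))
    ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  }
  ci <- c(min(ci[1], value), max(ci[2], value))
  structure(list(value = value, ci = ci, method = method,
                 n_steps_used = length(stat$values)),
            class = "single_molecule_brightness")
}

#' Initial unbleached track intensity
#'
#' Fits a single-exponential photobleaching decay to the trace and evaluates
#' it at frame 0, which is robust to bleaching that occurred before the
#' first usable frame; falls back to the mean of the first `window` frames
#' when the fit fails.
#'
#' @param trace Numeric intensity trace.
#' @param window Fallback window, frames.
#' @param frames Optional 0-based frame indices (defaults to
#'   `0:(length(trace)-1)`); extrapolation is always to absolute frame 0.
#' @return I0 (A.U.).
#' @export
initial_intensity <- function(trace, window = 4L, frames = NULL) {
  stopifnot(length(trace) >= window)
  if (all(trace == 0)) return(0)
  if (is.null(frames)) frames <- seq_along(trace) - 1
  fallback <- mean(trace[seq_len(window)])
  # drop the fully-bleached tail: background-level frames carry no
  # information about I0 and drag the exponential fit above step-shaped
  # (low-N) traces
  cut <- 3 * tail_noise_sd(trace)
  last_sig <- max(which(trace > cut), window)
  if (last_sig < length(trace)) {
    trace <- trace[seq_len(last_sig)]
    frames <- frames[seq_len(last_sig)]
  }
  pos <- trace > 0
  if (sum(pos) < 3) return(fallback)
  init <- tryCatch({
    lf <- stats::lm(log(trace[pos]) ~ frames[pos])
    list(A = exp(unname(stats::coef(lf)[1])),
         k = max(-unname(stats::coef(lf)[2]), 1e-8))
  }, error = function(e) NULL)
  if (is.null(init)) return(fallback)
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(trace ~ A * exp(-k * frames),
                 start = list(A = init$A, k = init$k),
                 control = stats::nls.control(maxiter = 100,
                                              warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback)
  a <- unname(stats::coef(fit)["A"])
  if (!is.finite(a) || a <= 0) fallback else a
}

#' Stoichiometry of one tracked aggregate
#'
#' `S = I0 / I_single`, optionally corrected for the dark fraction of
#' fluorophores that never mature to a photoactive state (multiplies by
#' `1/(1 - dark_fraction)`).
#'
#' @param i0 Initial intensity (A.U.), from [initial_intensity()].
#' @param brightness A [single_molecule_brightness()] result or a bare
#'   positive number.
#' @param dark_fraction Dark fraction in `[0, 1)`; 0 disables the correction.
#' @return List of class `stoichiometry_estimate`: `initial_intensity`,
#'   `stoichiometry`, `dark_corrected`.
#' @export
stoichiometry <- function(i0, brightness, dark_fraction = 0) {
  val <- if (inherits(brightness, "single_molecule_brightness"))
    brightness$value else brightness
  stopifnot(val > 0, dark_fraction >= 0, dark_fraction < 1)
  s <- i0 / val
  if (dark_fraction > 0) s <- s / (1 - dark_fraction)
  structure(list(initial_intensity = i0, stoichiometry = s,
                 dark_corrected = dark_fraction > 0),
            class = "stoichiometry_estimate")
}

#' Kernel density estimate of a stoichiometry distribution
#'
#' Gaussian KDE with reflection at zero (stoichiometries are non-negative),
#' evaluated on a grid from 0 to beyond the data maximum; the density
#' integrates to 1 over the grid. Peaks are local maxima above 5% of the
#' global maximum. The default bandwidth is Silverman's rule with a floor of
#' 0.7 molecules (roughly the single-molecule intensity equivalent).
#'
#' @param values Numeric vector (>= 5 values; all-equal input yields a
#'   single delta-like peak at that value).
#' @param bandwidth Kernel sd; `NULL` for the default.
#' @param n_grid Grid resolution.
#' @param min_n Minimum number of values (internal callers may lower it).
#' @return List of class `stoichiometry_distribution`: `grid`, `density`,
#'   `bandwidth`, `peaks`, `peak_heights`.
#' @export
kde_distribution <- function(values, bandwidth = NULL, n_grid = 512L,
                             min_n = 5L) {
  stopifnot(length(values) >= min_n, all(is.finite(values)))
  if (length(unique(values)) == 1L) {
    v <- values[1]
    bw <- if (is.null(bandwidth)) max(abs(v) * 1e-3, 1e-3) else bandwidth
    grid <- seq(max(0, v - 6 * bw), v + 6 * bw, length.out = n_grid)
    dens <- stats::dnorm(grid, v, bw) + stats::dnorm(-grid, v, bw)
    return(structure(list(grid = grid, density = dens, bandwidth = bw,
                          peaks = v, peak_heights = max(dens)),
                     class = "stoichiometry_distribution"))
  }
  if (is.null(bandwidth)) bandwidth <- max(stats::bw.nrd0(values), 0.7)
  gmax <- max(max(values) * 1.2, max(values) + 5 * bandwidth)
  grid <- seq(0, gmax, length.out = n_grid)
  dens <- vapply(grid, function(g)
    mean(stats::dnorm(g, values, bandwidth) +
           stats::dnorm(-g, values, bandwidth)), numeric(1))
  i <- 2:(n_grid - 1L)
  is_peak <- dens[i] >= dens[i - 1L] & dens[i] > dens[i + 1L] &
    dens[i] > 0.05 * max(dens)
  pk <- grid[i][is_peak]
  ph <- dens[i][is_peak]
  if (dens[1] > dens[2] && dens[1] > 0.05 * max(dens)) {
    pk <- c(grid[1], pk); ph <- c(dens[1], ph)
  }
  structure(list(grid = grid, density = dens, bandwidth = bandwidth,
                 peaks = pk, peak_heights = ph),
            class = "stoichiometry_distribution")
}

#' Background-corrected intensity readout at a fixed position
#'
#' Sums the background-subtracted window intensity at one (row, col)
#' position in every frame. Used to extend photobleaching traces past the
#' point where a focus becomes too dim to localize, so the terminal
#' bleaching step down to background is observable.
#'
#' @param movie frames x rows x cols array.
#' @param position 0-based `c(row, col)`.
#' @param window_radius Half-width of the readout window, px.
#' @param psf_sigma_px Nominal PSF sigma, px (sets the aperture radius).
#' @param frames Optional subset of 0-based frame indices.
#' @return Numeric vector of background-corrected summed intensities.
#' @export
extract_trace <- function(movie, position, window_radius = 8,
                          psf_sigma_px = 0.725, frames = NULL) {
  nf <- dim(movie)[1]
  if (is.null(frames)) frames <- seq_len(nf) - 1L
  w <- as.integer(window_radius)
  r0 <- round(position[1]) + 1L; c0 <- round(position[2]) + 1L
  r0 <- min(max(r0, w + 1L), dim(movie)[2] - w)
  c0 <- min(max(c0, w + 1L), dim(movie)[3] - w)
  n <- 2L * w + 1L
  dr <- row(matrix(0, n, n)) - w - 1L
  dc <- col(matrix(0, n, n)) - w - 1L
  ring <- pmax(abs(dr), abs(dc)) >= w - 1L
  r_ap <- min(max(4, ceiling(5 * psf_sigma_px)), w)
  ap <- dr^2 + dc^2 <= r_ap^2
  n_ap <- sum(ap)
  vapply(frames, function(f) {
    win <- movie[f + 1L, (r0 - w):(r0 + w), (c0 - w):(c0 + w)]
    sum(win[ap]) - mean(win[ring]) * n_ap
  }, numeric(1))
}

#' Intensity traces of linked tracks, extended past track termination
#'
#' For each track the per-frame background-corrected summed intensity from
#' the localizations is taken as the trace; the trace is then extended by a
#' fixed-position readout at the last localized position for up to
#' `extend` further frames, so that fully-photobleached traces end at
#' background level.
#'
#' @param tracks Output of [link_tracks()] (needs `track_id`, `frame`,
#'   `row`, `col`, `summed_intensity`).
#' @param movie The movie the tracks were measured on.
#' @param extend Maximum number of frames to append.
#' @param window_radius Readout window half-width, px.
#' @return Named list (by track id) of lists with `frames` (0-based) and
#'   `intensity`.
#' @export
track_traces <- function(tracks, movie, extend = 60L, window_radius = 8) {
  nf <- dim(movie)[1]
  ids <- unique(tracks$track_id)
  out <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    fr <- tr$frame
    intensity <- tr$summed_intensity
    last <- fr[length(fr)]
    if (extend > 0 && last < nf - 1L) {
      ext_fr <- seq(last + 1L, min(nf - 1L, last + extend))
      ext <- extract_trace(movie, c(tr$row[nrow(tr)], tr$col[nrow(tr)]),
                           window_radius, frames = ext_fr)
      fr <- c(fr, ext_fr)
      intensity <- c(intensity, ext)
    }
    list(frames = fr, intensity = intensity)
  })
  names(out) <- as.character(ids)
  out
}
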