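#' Simulation configuration for synthetic Slimfield acquisitions
#'
#' Bundles the acquisition constants used by the synthetic-data generator.
#' Defaults emulate a millisecond-timescale Slimfield movie: 5 ms frames,
#' 1000 frames, 120 nm pixels, and a near-diffraction-limited point spread
#' function for 488 nm excitation through a 1.4 NA objective
#' (sigma = 0.25 * lambda / NA ~ 87 nm). The photon budget (300 detected
#' photons per fluorophore per frame over 10 photons/pixel background,
#' read noise sd 1 count) is the package's calibration point: it places the
#' single-molecule localization precision comfortably below 40 nm.
#'
#' @param pixel_size Pixel size, nm/pixel.
#' @param frame_interval Frame interval, seconds.
#' @param n_frames Number of frames in the movie.
#' @param image_shape Integer vector `c(rows, cols)`.
#' @param psf_sigma Gaussian PSF standard deviation, nm.
#' @param photons_per_fluorophore_per_frame Expected detected photons emitted
#'   by one photoactive fluorophore in one frame.
#' @param bleach_prob Per-fluorophore, per-frame probability of irreversible
#'   photobleaching.
#' @param dark_fraction Probability that a fluorophore never matures to a
#'   photoactive state (~0.07 for common fluorescent proteins).
#' @param background_photons Expected background photons per pixel per frame.
#' @param read_noise_sd Additive Gaussian camera read noise, counts.
#' @param rng_seed Integer seed; identical configs give bit-identical stacks.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(pixel_size = 120,
                       frame_interval = 0.005,
                       n_frames = 1000,
                       image_shape = c(64L, 64L),
                       psf_sigma = 87,
                       photons_per_fluorophore_per_frame = 300,
                       bleach_prob = 0.008,
                       dark_fraction = 0,
                       background_photons = 10,
                       read_noise_sd = 1,
                       rng_seed = 1L) {
  cfg <- list(
    pixel_size = pixel_size,
    frame_interval = frame_interval,
    n_frames = as.integer(n_frames),
    image_shape = as.integer(image_shape),
    psf_sigma = psf_sigma,
    photons_per_fluorophore_per_frame = photons_per_fluorophore_per_frame,
    bleach_prob = bleach_prob,
    dark_fraction = dark_fraction,
    background_photons = background_photons,
    read_noise_sd = read_noise_sd,
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$pixel_size > 0, cfg$frame_interval > 0, cfg$n_frames > 0,
    length(cfg$image_shape) == 2, all(cfg$image_shape > 0),
    cfg$psf_sigma > 0, cfg$photons_per_fluorophore_per_frame > 0,
    cfg$bleach_prob >= 0, cfg$bleach_prob <= 1,
    cfg$dark_fraction >= 0, cfg$dark_fraction < 1,
    cfg$background_photons >= 0, cfg$read_noise_sd >= 0
  )
  invisible(cfg)
}

#' Simulate a 2D Brownian trajectory with reflecting boundaries
#'
#' Per-axis displacements are independent Gaussians with variance
#' `2 * d_coeff * frame_interval`. Steps that would leave the boundary are
#' reflected: radially for a disk boundary, by step reversal for an arbitrary
#' pixel mask.
#'
#' @param d_coeff Diffusion coefficient, um^2/s.
#' @param n_frames Number of positions to generate (including the start).
#' @param frame_interval Time between frames, s.
#' @param start Numeric `c(x, y)` start position, um.
#' @param bounds `NULL` (unbounded), `disk_bounds(center, radius)`, or
#'   `mask_bounds(mask, pixel_size)`.
#' @return An `n_frames` x 2 matrix of (x, y) positions in um.
#' @export
simulate_brownian_track <- function(d_coeff, n_frames, frame_interval,
                                    start = c(0, 0), bounds = NULL) {
  stopifnot(d_coeff >= 0, n_frames >= 1, frame_interval > 0)
  if (!is.null(bounds) && !in_bounds(start, bounds)) {
    stop("start position lies outside the stated bounds")
  }
  pos <- matrix(0, nrow = n_frames, ncol = 2,
                dimnames = list(NULL, c("x", "y")))
  pos[1, ] <- start
  if (n_frames == 1L || d_coeff == 0) {
    pos[, 1] <- start[1]
    pos[, 2] <- start[2]
    return(pos)
  }
  sd_step <- sqrt(2 * d_coeff * frame_interval)
  steps <- matrix(stats::rnorm(2 * (n_frames - 1), sd = sd_step), ncol = 2)
  for (i in 2:n_frames) {
    p <- pos[i - 1, ] + steps[i - 1, ]
    if (!is.null(bounds)) p <- reflect_into(p, pos[i - 1, ], bounds)
    pos[i, ] <- p
  }
  pos
}

#' @rdname simulate_brownian_track
#' @param center Disk centre `c(x, y)`, um.
#' @param radius Disk radius, um.
#' @export
disk_bounds <- function(center, radius) {
  stopifnot(length(center) == 2, radius > 0)
  structure(list(center = center, radius = radius), class = "disk_bounds")
}

#' @rdname simulate_brownian_track
#' @param mask Logical or 0/1 matrix; TRUE/nonzero pixels are allowed.
#' @param pixel_size Pixel size of the mask, nm/pixel.
#' @export
mask_bounds <- function(mask, pixel_size) {
  stopifnot(is.matrix(mask), pixel_size > 0)
  structure(list(mask = mask != 0, pixel_size = pixel_size),
            class = "mask_bounds")
}

in_bounds <- function(p, bounds) {
  if (inherits(bounds, "disk_bounds")) {
    sqrt(sum((p - bounds$center)^2)) <= bounds$radius
  } else if (inherits(bounds, "mask_bounds")) {
    px_um <- bounds$pixel_size / 1000
    # x -> column, y -> row; 0-based pixel centres at integer coordinates
    col <- round(p[1] / px_um) + 1L
    row <- round(p[2] / px_um) + 1L
    row >= 1L && row <= nrow(bounds$mask) &&
      col >= 1L && col <= ncol(bounds$mask) &&
      bounds$mask[row, col]
  } else {
    stop("unknown bounds object")
  }
}

reflect_into <- function(p, prev, bounds) {
  if (inherits(bounds, "disk_bounds")) {
    v <- p - bounds$center
    r <- sqrt(sum(v^2))
    n <- 0
    while (r > bounds$radius && n < 50) {
      v <- v * (2 * bounds$radius - r) / r   # radial mirror about the rim
      r <- sqrt(sum(v^2))
      n <- n + 1
    }
    if (r > bounds$radius) v <- v * bounds$radius / r
    bounds$center + v
  } else if (inherits(bounds, "mask_bounds")) {
    if (in_bounds(p, bounds)) p
    else if (in_bounds(2 * prev - p, bounds)) 2 * prev - p  # reversed step
    else prev
  } else {
    stop("unknown bounds object")
  }
}

#' Simulate stochastic stepwise photobleaching of a fluorophore population
#'
#' Each non-dark fluorophore bleaches irreversibly at a geometrically
#' distributed frame (per-frame probability `bleach_prob`); a fluorophore is
#' photoactive at frame `t` (0-based) iff it is non-dark and its bleach frame
#' exceeds `t`. Dark fluorophores never emit.
#'
#' @param n_molecules Number of fluorophores.
#' @param bleach_prob Per-frame bleaching probability in `[0, 1]`.
#' @param dark_fraction Probability a fluorophore is never photoactive.
#' @param n_frames Number of frames.
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return List with `counts` (photoactive count per frame, length
#'   `n_frames`), `bleach_frame` (per fluorophore; `Inf` if never bleached
#'   within the movie, 0 for dark fluorophores) and `dark` (logical).
#' @export
simulate_photobleaching <- function(n_molecules, bleach_prob, dark_fraction = 0,
                                    n_frames, seed = NULL) {
  stopifnot(n_molecules >= 0, bleach_prob >= 0, bleach_prob <= 1,
            dark_fraction >= 0, dark_fraction < 1, n_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  dark <- stats::runif(n_molecules) < dark_fraction
  bleach_frame <- rep(Inf, n_molecules)
  live <- which(!dark)
  if (bleach_prob > 0 && length(live)) {
    # rgeom counts pre-bleach frames; fluorophore is active on frames
    # 0 .. bleach_frame-1
    bf <- stats::rgeom(length(live), bleach_prob) + 1
    bleach_frame[live] <- bf
  }
  bleach_frame[dark] <- 0
  counts <- vapply(seq_len(n_frames) - 1L,
                   function(t) sum(!dark & bleach_frame > t), integer(1))
  list(counts = counts, bleach_frame = bleach_frame, dark = dark)
}

#' Build ground-truth aggregates for a synthetic acquisition
#'
#' Draws one Brownian trajectory and one photobleaching realisation per
#' aggregate. All fluorophores of an aggregate are co-located (the aggregate
#' is treated as sub-resolution).
#'
#' @param config A [sim_config()].
#' @param n_molecules Integer vector (recycled) of true molecule counts N.
#' @param d_coeff Numeric vector (recycled) of diffusion coefficients, um^2/s.
#' @param starts Optional matrix of start positions (um); defaults to random
#'   positions inside `bounds` (or the image interior).
#' @param bounds Per-aggregate bounds (a single bounds object or a list, one
#'   per aggregate), as for [simulate_brownian_track()].
#' @param cell_ids Optional integer vector assigning each aggregate to a cell.
#' @return List of `aggregate_truth` records: `aggregate_id`,
#'   `n_molecules`, `d_coeff`, `trajectory` (um), `bleach_frame`, `dark`,
#'   `cell_id`.
#' @export
simulate_aggregates <- function(config, n_molecules, d_coeff,
                                starts = NULL, bounds = NULL, cell_ids = NULL) {
  n_agg <- max(length(n_molecules), length(d_coeff),
               if (is.null(starts)) 0 else nrow(starts),
               length(cell_ids),
               if (is.list(bounds) &&
                     !inherits(bounds, c("disk_bounds", "mask_bounds")))
                 length(bounds) else 0)
  n_molecules <- rep_len(n_molecules, n_agg)
  d_coeff <- rep_len(d_coeff, n_agg)
  if (!is.null(cell_ids)) cell_ids <- rep_len(cell_ids, n_agg)
  px_um <- config$pixel_size / 1000
  lapply(seq_len(n_agg), function(i) {
    b <- if (is.null(bounds)) NULL
         else if (inherits(bounds, c("disk_bounds", "mask_bounds"))) bounds
         else bounds[[i]]
    if (is.null(starts)) {
      st <- if (inherits(b, "disk_bounds")) {
        repeat {
          cand <- b$center + stats::runif(2, -b$radius, b$radius)
          if (in_bounds(cand, b)) break
        }
        cand
      } else {
        c(stats::runif(1, 2, (config$image_shape[2] - 3)) * px_um,
          stats::runif(1, 2, (config$image_shape[1] - 3)) * px_um)
      }
    } else st <- starts[i, ]
    traj <- simulate_brownian_track(d_coeff[i], config$n_frames,
                                    config$frame_interval, start = st,
                                    bounds = b)
    pb <- simulate_photobleaching(n_molecules[i], config$bleach_prob,
                                  config$dark_fraction, config$n_frames)
    structure(list(aggregate_id = i, n_molecules = n_molecules[i],
                   d_coeff = d_coeff[i], trajectory = traj,
                   bleach_frame = pb$bleach_frame, dark = pb$dark,
                   cell_id = if (is.null(cell_ids)) NA_integer_ else cell_ids[i]),
              class = "aggregate_truth")
  })
}

active_counts <- function(truth, n_frames) {
  vapply(seq_len(n_frames) - 1L,
         function(t) sum(!truth$dark & truth$bleach_frame > t), integer(1))
}

# Expected photon image of `photons` emitted at (x, y) um: separable
# integrated Gaussian over the pixel grid (pixel centres at 0-based integers).
psf_image <- function(rows, cols, x_um, y_um, sigma_px, photons, px_um,
                      win = 6L) {
  cx <- x_um / px_um
  cy <- y_um / px_um
  r0 <- max(1L, floor(cy) + 1L - win)
  r1 <- min(rows, floor(cy) + 1L + win)
  c0 <- max(1L, floor(cx) + 1L - win)
  c1 <- min(cols, floor(cx) + 1L + win)
  if (r0 > r1 || c0 > c1) return(NULL)
  rr <- (r0:r1) - 1L
  cc <- (c0:c1) - 1L
  fy <- stats::pnorm(rr + 0.5, cy, sigma_px) - stats::pnorm(rr - 0.5, cy, sigma_px)
  fx <- stats::pnorm(cc + 0.5, cx, sigma_px) - stats::pnorm(cc - 0.5, cx, sigma_px)
  list(rows = r0:r1, cols = c0:c1, img = photons * outer(fy, fx))
}

#' Render a synthetic movie from ground-truth aggregates
#'
#' Each photoactive fluorophore contributes an integrated 2D Gaussian of
#' width `psf_sigma` centred on its aggregate's position. With `noise = TRUE`
#' each pixel is `Poisson(signal + background) + N(0, read_noise_sd)`, clipped
#' at zero and quantised to integer counts; with `noise = FALSE` the expected
#' photon image is returned unquantised (for photon-conservation checks).
#'
#' @param config A [sim_config()]; `config$rng_seed` (when non-NULL) seeds the
#'   noise draw so identical configs give bit-identical movies.
#' @param truths List of `aggregate_truth` records (see
#'   [simulate_aggregates()]).
#' @param cell_mask Optional label matrix (0 background, k = cell k).
#' @param noise Apply the camera noise model?
#' @return List of class `synthetic_stack`: `movie` (frames x rows x cols
#'   array), `config`, `truths`, `cell_mask`.
#' @export
render_stack <- function(config, truths, cell_mask = NULL, noise = TRUE) {
  validate_sim_config(config)
  rows <- config$image_shape[1]; cols <- config$image_shape[2]
  px_um <- config$pixel_size / 1000
  sigma_px <- config$psf_sigma / config$pixel_size
  nf <- config$n_frames
  for (tr in truths) {
    if (nrow(tr$trajectory) != nf)
      stop("trajectory length does not match config n_frames")
    xpx <- tr$trajectory[, 1] / px_um
    ypx <- tr$trajectory[, 2] / px_um
    if (any(xpx < -0.5 | xpx > cols - 0.5 | ypx < -0.5 | ypx > rows - 0.5))
      stop("aggregate trajectory leaves the image")
  }
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  signal <- array(0, dim = c(nf, rows, cols))
  counts <- lapply(truths, active_counts, n_frames = nf)
  win <- max(6L, ceiling(6 * sigma_px))
  for (f in seq_len(nf)) {
    for (i in seq_along(truths)) {
      n_act <- counts[[i]][f]
      if (n_act == 0) next
      ph <- n_act * config$photons_per_fluorophore_per_frame
      g <- psf_image(rows, cols, truths[[i]]$trajectory[f, 1],
                     truths[[i]]$trajectory[f, 2], sigma_px, ph, px_um, win)
      if (!is.null(g)) signal[f, g$rows, g$cols] <-
          signal[f, g$rows, g$cols] + g$img
    }
  }
  if (noise) {
    lambda <- signal + config$background_photons
    movie <- array(stats::rpois(length(lambda), lambda), dim = dim(lambda))
    if (config$read_noise_sd > 0) {
      movie <- movie + round(stats::rnorm(length(movie),
                                          sd = config$read_noise_sd))
    }
    movie[movie < 0] <- 0
    storage.mode(movie) <- "integer"
  } else {
    movie <- signal + config$background_photons
  }
  structure(list(movie = movie, config = config, truths = truths,
                 cell_mask = cell_mask),
            class = "synthetic_stack")
}

#' Simulate a Slimfield acquisition of diffusing, photobleaching aggregates
#'
#' Convenience wrapper: lays out `n_cells` disk-shaped cells on a grid,
#' places one aggregate per cell, simulates motion and photobleaching, and
#' renders the noisy movie. The cell mask is returned as a label image.
#'
#' @param config A [sim_config()].
#' @param n_molecules True molecule count per aggregate (recycled).
#' @param d_coeff True diffusion coefficient(s), um^2/s.
#' @param n_cells Number of cells (disks) in the field.
#' @param cell_radius_px Cell radius, pixels.
#' @return A `synthetic_stack` with `cell_mask` set and aggregate `cell_id`s.
#' @export
simulate_slimfield_stack <- function(config, n_molecules, d_coeff,
                                     n_cells = 4, cell_radius_px = 12) {
  rows <- config$image_shape[1]; cols <- config$image_shape[2]
  px_um <- config$pixel_size / 1000
  grid_n <- ceiling(sqrt(n_cells))
  cell_radius_px <- min(cell_radius_px, min(rows, cols) / (2 * grid_n) - 1)
  if (cell_radius_px < 3)
    stop("image too small for ", n_cells, " cells")
  centers <- expand.grid(
    gy = seq_len(grid_n), gx = seq_len(grid_n))[seq_len(n_cells), ]
  cy <- (centers$gy - 0.5) * rows / grid_n
  cx <- (centers$gx - 0.5) * cols / grid_n
  mask <- matrix(0L, rows, cols)
  for (k in seq_len(n_cells)) {
    rr <- outer((seq_len(rows) - 1) - (cy[k] - 0.5), rep(1, cols))
    cc <- outer(rep(1, rows), (seq_len(cols) - 1) - (cx[k] - 0.5))
    inside <- rr^2 + cc^2 <= cell_radius_px^2
    mask[inside & mask == 0L] <- k
  }
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  bounds <- lapply(seq_len(n_cells), function(k)
    disk_bounds(c((cx[k] - 0.5) * px_um, (cy[k] - 0.5) * px_um),
                (cell_radius_px - 1.5) * px_um))
  truths <- simulate_aggregates(config, n_molecules, d_coeff,
                                bounds = bounds, cell_ids = seq_len(n_cells))
  cfg2 <- config
  cfg2$rng_seed <- if (is.null(config$rng_seed)) NULL else
    (config$rng_seed %% 1000000L) + 7L  # separate stream for camera noise
  render_stack(cfg2, truths, cell_mask = mask, noise = TRUE)
}

#' Simulate a dual-colour confocal time-lapse of a budding mother/daughter pair
#'
#' Emulates a 90-minute confocal time-lapse at 10-minute intervals during
#' budding: channel 1 carries the aggregate reporter, channel 2 an organelle
#' marker. The bud appears at the second timepoint and grows linearly; the
#' organelle transfers a copy into the bud at the organelle's characteristic
#' time (vacuole ~20 min into budding, nucleus ~60 min). Under the default
#' `"retain"` policy all aggregates stay in the mother; `"transfer_final"`
#' moves one aggregate into the bud at the last timepoint. Confocal settings
#' minimise photobleaching, so no per-frame bleaching is applied.
#'
#' @param config A [sim_config()]; `n_frames` is the number of timepoints
#'   (default 10 = 0..90 min) and `frame_interval` the interval in seconds
#'   (default 600).
#' @param n_aggregates Aggregates in the mother cell.
#' @param n_molecules Molecules per aggregate (confocal-scale, no bleaching).
#' @param organelle `"vacuole"` or `"nucleus"`.
#' @param inheritance_policy `"retain"` or `"transfer_final"`.
#' @param mother_radius_px,bud_max_radius_px Geometry of the pair, pixels.
#' @return A `synthetic_stack` whose `movie` is `ch1` and which additionally
#'   carries `ch2` (organelle channel), per-frame `cell_masks` (label 1 =
#'   mother, 2 = bud), `organelle_masks`, `lineage`
#'   (`c("1" = "mother", "2" = "daughter")`), `organelle`,
#'   `organelle_transfer_frame` and `time_min`.
#' @export
simulate_confocal_timelapse <- function(config = sim_config(
                                          frame_interval = 600, n_frames = 10,
                                          image_shape = c(64L, 96L),
                                          bleach_prob = 0, rng_seed = 1L),
                                        n_aggregates = 3,
                                        n_molecules = 200,
                                        organelle = c("vacuole", "nucleus"),
                                        inheritance_policy = c("retain",
                                                               "transfer_final"),
                                        mother_radius_px = 18,
                                        bud_max_radius_px = 11) {
  organelle <- match.arg(organelle)
  inheritance_policy <- match.arg(inheritance_policy)
  validate_sim_config(config)
  if (config$bleach_prob != 0)
    stop("confocal fixtures assume no per-frame photobleaching")
  rows <- config$image_shape[1]; cols <- config$image_shape[2]
  px_um <- config$pixel_size / 1000
  nf <- config$n_frames
  time_min <- (seq_len(nf) - 1L) * config$frame_interval / 60
  transfer_min <- if (organelle == "vacuole") 20 else 60
  transfer_frame <- which(time_min >= transfer_min)[1]
  if (is.na(transfer_frame))
    stop("time-lapse too short for the organelle transfer time")
  mother_c <- c(rows / 2, cols * 0.3)        # (row, col), 1-based centre
  bud_dir <- c(0, 1)
  # the bud appears at the second timepoint with a minimal visible radius
  # and grows linearly to its final size
  bud_r <- c(0, 3 + (bud_max_radius_px - 3) * (seq_len(nf - 1L) - 1L) /
               (nf - 2L))
  disk_mask <- function(center, radius) {
    if (radius <= 0) return(matrix(FALSE, rows, cols))
    rr <- outer(seq_len(rows) - center[1], rep(1, cols))
    cc <- outer(rep(1, rows), seq_len(cols) - center[2])
    rr^2 + cc^2 <= radius^2
  }
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  # aggregate positions: fixed random spots well inside the mother, on the
  # half away from the bud so PSF tails do not spill into the bud ROI
  th <- stats::runif(n_aggregates, pi / 2 + 0.3, 3 * pi / 2 - 0.3)
  rad <- sqrt(stats::runif(n_aggregates)) * (mother_radius_px - 4)
  agg_rc <- cbind(mother_c[1] + rad * sin(th), mother_c[2] + rad * cos(th))
  cell_masks <- vector("list", nf)
  organelle_masks <- vector("list", nf)
  ch1 <- array(0, dim = c(nf, rows, cols))
  ch2 <- array(0, dim = c(nf, rows, cols))
  sigma_px <- config$psf_sigma / config$pixel_size
  truths <- list()
  org_r <- mother_radius_px * 0.45
  org_c_mother <- mother_c + c(0, -mother_radius_px * 0.3)
  for (f in seq_len(nf)) {
    bud_c <- mother_c + bud_dir * (mother_radius_px + bud_r[f])
    m_mother <- disk_mask(mother_c, mother_radius_px)
    m_bud <- disk_mask(bud_c, bud_r[f]) & !m_mother
    lab <- matrix(0L, rows, cols)
    lab[m_mother] <- 1L
    lab[m_bud] <- 2L
    cell_masks[[f]] <- lab
    om <- disk_mask(org_c_mother, org_r)
    if (f >= transfer_frame && bud_r[f] > 0) {
      om <- om | (disk_mask(bud_c, max(1.5, bud_r[f] * 0.5)) & m_bud)
    }
    organelle_masks[[f]] <- om
    ch2[f, , ][om] <- 100
    for (a in seq_len(n_aggregates)) {
      rc <- agg_rc[a, ]
      if (inheritance_policy == "transfer_final" && a == 1L && f == nf) {
        rc <- bud_c
      }
      g <- psf_image(rows, cols, (rc[2] - 0.5) * px_um, (rc[1] - 0.5) * px_um,
                     sigma_px * 3,  # confocal PSF is broader
                     n_molecules * config$photons_per_fluorophore_per_frame,
                     px_um, win = 12L)
      if (!is.null(g)) ch1[f, g$rows, g$cols] <- ch1[f, g$rows, g$cols] + g$img
      if (f == 1L) {
        traj <- matrix(rep(c((rc[2] - 0.5) * px_um, (rc[1] - 0.5) * px_um), nf),
                       ncol = 2, byrow = TRUE,
                       dimnames = list(NULL, c("x", "y")))
        truths[[a]] <- structure(
          list(aggregate_id = a, n_molecules = n_molecules, d_coeff = 0,
               trajectory = traj, bleach_frame = rep(Inf, n_molecules),
               dark = rep(FALSE, n_molecules), cell_id = 1L),
          class = "aggregate_truth")
      } else if (inheritance_policy == "transfer_final" && a == 1L && f == nf) {
        truths[[a]]$trajectory[nf, ] <- c((rc[2] - 0.5) * px_um,
                                          (rc[1] - 0.5) * px_um)
        truths[[a]]$cell_id <- c(1L, final = 2L)
      }
    }
  }
  noisify <- function(x) {
    y <- array(stats::rpois(length(x), x + config$background_photons),
               dim = dim(x))
    storage.mode(y) <- "integer"
    y
  }
  structure(list(movie = noisify(ch1), ch2 = noisify(ch2), config = config,
                 truths = truths, cell_mask = cell_masks[[1]],
                 cell_masks = cell_masks, organelle_masks = organelle_masks,
                 lineage = c("1" = "mother", "2" = "daughter"),
                 organelle = organelle,
                 organelle_transfer_frame = transfer_frame,
                 time_min = time_min),
            class = "synthetic_stack")
}
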