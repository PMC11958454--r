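#' Stoichiometry-recovery experiment on synthetic Slimfield stacks
#'
#' Simulates `n_aggregates` diffusing aggregates (one per disk-shaped cell,
#' `n_cells_per_stack` cells per field), each carrying `n_true` fluorophores
#' that photobleach stochastically, and runs the full quantification chain:
#' per-cell foci detection on the first frame, iterative Gaussian
#' re-localization through the movie, track linking, intensity-trace
#' extraction (extended past track termination so the terminal bleaching
#' step is observable), a single pooled single-molecule brightness
#' calibration from the terminal steps of all fully-bleached traces, and
#' per-aggregate stoichiometry from the exponential-fit initial intensity.
#'
#' @param n_true True molecule count per aggregate.
#' @param n_aggregates Total aggregates to simulate.
#' @param d_coeff True diffusion coefficient, um^2/s.
#' @param seed Integer seed for the whole experiment.
#' @param config Base [sim_config()]; its `rng_seed` is re-derived per stack
#'   from `seed`.
#' @param n_cells_per_stack Cells (= aggregates) per field of view.
#' @param pipeline [pipeline_config()] used for the analysis stages.
#' @return List: `stoichiometries` (per recovered aggregate), `mean_s`,
#'   `i_single` (pooled calibration), `n_traces`, `n_true`.
#' @export
stoichiometry_recovery_experiment <- function(n_true, n_aggregates = 100,
                                              d_coeff = 0.99, seed = 1L,
                                              config = sim_config(),
                                              n_cells_per_stack = 4L,
                                              pipeline = pipeline_config()) {
  n_stacks <- ceiling(n_aggregates / n_cells_per_stack)
  px <- config$pixel_size
  trk <- pipeline$tracking
  det <- pipeline$detection
  stc <- pipeline$stoichiometry
  all_traces <- list()
  for (s in seq_len(n_stacks)) {
    cfg <- config
    cfg$rng_seed <- (seed * 20011L + s * 101L) %% 2000000011L
    stack <- simulate_slimfield_stack(cfg, n_true, d_coeff,
                                      n_cells = n_cells_per_stack)
    foci <- detect_foci(stack$movie[1, , ], stack$cell_mask,
                        threshold_method = det$threshold_method,
                        min_area_px = det$min_area_px,
                        min_snr = det$min_snr, pixel_size = px)
    if (!nrow(foci)) next
    locs <- track_stack(stack$movie, cbind(foci$row, foci$col),
                        window_radius = trk$window_radius,
                        psf_sigma_px = trk$psf_sigma_px, pixel_size = px)
    tracks <- link_tracks(locs, max_disp = trk$max_disp)
    len <- table(tracks$track_id)
    keep <- as.integer(names(len)[len >= trk$min_track_length])
    if (!length(keep)) next
    traces <- track_traces(tracks[tracks$track_id %in% keep, , drop = FALSE],
                           stack$movie, extend = stc$trace_extend,
                           window_radius = trk$window_radius)
    all_traces <- c(all_traces, traces)
  }
  if (length(all_traces) < 10)
    stop("too few usable traces recovered (", length(all_traces), ")")
  set.seed(seed)
  calib <- single_molecule_brightness(lapply(all_traces, `[[`, "intensity"),
                                      method = stc$calibration,
                                      window = stc$ck_window,
                                      min_dwell = stc$min_dwell)
  s_hat <- vapply(all_traces, function(tr) {
    i0 <- initial_intensity(tr$intensity, frames = tr$frames)
    stoichiometry(i0, calib, stc$dark_fraction)$stoichiometry
  }, numeric(1))
  list(stoichiometries = unname(s_hat), mean_s = mean(s_hat),
       i_single = calib$value, n_traces = length(s_hat), n_true = n_true)
}

#' Diffusion-recovery experiment from the initial MSD gradient
#'
#' Simulates Brownian tracks at a known diffusion coefficient, perturbs the
#' positions with Gaussian localization noise, and estimates each track's D
#' from the weighted initial MSD gradient. The default noise (8 nm per
#' axis) is the localization precision of the iterative Gaussian fit at the
#' simulator's default single-molecule photon budget.
#'
#' @param d_true True diffusion coefficient, um^2/s.
#' @param n_tracks Number of tracks.
#' @param n_frames Frames per track.
#' @param frame_interval Frame interval, s.
#' @param loc_noise_nm Per-axis localization noise sd, nm.
#' @param pixel_size Pixel size, nm.
#' @param n_points MSD points used for the gradient.
#' @param seed Integer seed.
#' @return List: `d_estimates`, `mean_d`, `d_true`, `n_tracks`.
#' @export
diffusion_recovery_experiment <- function(d_true = 0.99, n_tracks = 200L,
                                          n_frames = 60L,
                                          frame_interval = 0.005,
                                          loc_noise_nm = 8, pixel_size = 120,
                                          n_points = 4L, seed = 1L) {
  set.seed(seed)
  px_um <- pixel_size / 1000
  d_hat <- vapply(seq_len(n_tracks), function(i) {
    tr <- simulate_brownian_track(d_true, n_frames, frame_interval)
    tr <- tr + stats::rnorm(length(tr), sd = loc_noise_nm / 1000)
    df <- data.frame(frame = seq_len(n_frames) - 1L,
                     row = tr[, 2] / px_um, col = tr[, 1] / px_um)
    estimate_diffusion(compute_msd(df, pixel_size, frame_interval),
                       n_points)$d_coeff
  }, numeric(1))
  list(d_estimates = d_hat, mean_d = mean(d_hat), d_true = d_true,
       n_tracks = n_tracks)
}

#' Localization-precision experiment at the default photon budget
#'
#' Renders isolated single-fluorophore foci at random sub-pixel positions
#' under the default camera noise model and localizes each with the
#' iterative Gaussian fit; reports the RMS 2D centre error.
#'
#' @param n_foci Number of independent foci.
#' @param config [sim_config()] supplying PSF, photon budget and noise.
#' @param seed Integer seed.
#' @return List: `rms_error_nm`, `errors_nm` (per accepted focus),
#'   `n_rejected`.
#' @export
localization_precision_experiment <- function(n_foci = 500L,
                                              config = sim_config(),
                                              seed = 1L) {
  set.seed(seed)
  px_um <- config$pixel_size / 1000
  cfg <- config
  cfg$n_frames <- 1L
  cfg$image_shape <- c(32L, 32L)
  cfg$bleach_prob <- 0
  cfg$rng_seed <- NULL
  sigma_px <- cfg$psf_sigma / cfg$pixel_size
  errs <- vapply(seq_len(n_foci), function(i) {
    p <- c(15.5, 15.5) * px_um + stats::runif(2, -0.5, 0.5) * px_um
    tru <- simulate_aggregates(cfg, 1, 0, starts = matrix(p, 1))
    stack <- render_stack(cfg, tru, noise = TRUE)
    loc <- localize_focus(stack$movie[1, , ], c(15, 15),
                          psf_sigma_px = sigma_px,
                          pixel_size = cfg$pixel_size, quiet = TRUE)
    if (is.null(loc)) return(NA_real_)
    1000 * sqrt((loc$col * px_um - p[1])^2 + (loc$row * px_um - p[2])^2)
  }, numeric(1))
  list(rms_error_nm = sqrt(mean(errs^2, na.rm = TRUE)),
       errors_nm = errs[!is.na(errs)], n_rejected = sum(is.na(errs)))
}
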