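default_pipeline_config <- function() {
  list(
    acquisition = list(pixel_size = 120, frame_interval = 0.005),
    detection = list(threshold_method = "otsu", min_area_px = 4L,
                     percentile = 0.975, min_snr = 5),
    tracking = list(max_disp = 5, window_radius = 8L, msd_n_points = 4L,
                    psf_sigma_px = 0.725, min_track_length = 8L),
    stoichiometry = list(calibration = "terminal_steps", dark_fraction = 0,
                         ck_window = 10L, min_dwell = 5L, trace_extend = 60L),
    analysis = list(coloc_distance = 250, iqr_k = 1.5,
                    test = "mann_whitney"),
    seed = 1L
  )
}

merge_validate <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key", if (length(unknown) > 1) "s", ": ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]))
      merge_validate(defaults[[k]], user[[k]], paste0(path, k, "$"))
    else user[[k]]
  }
  defaults
}

#' Build and validate a pipeline configuration
#'
#' Starts from the documented defaults and overrides them with a named list
#' or a YAML file. Unknown keys are rejected before any computation
#' (fail-fast); every tunable of the detection, tracking, stoichiometry and
#' analysis stages is reachable here.
#'
#' @param overrides Named list of overrides, or `NULL`.
#' @param yaml_file Optional YAML file of overrides (applied before
#'   `overrides`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(overrides = NULL, yaml_file = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(yaml_file)) cfg <- merge_validate(cfg, yaml::read_yaml(yaml_file))
  cfg <- merge_validate(cfg, overrides)
  stopifnot(cfg$acquisition$pixel_size > 0, cfg$acquisition$frame_interval > 0,
            cfg$detection$min_area_px >= 1, cfg$tracking$max_disp > 0,
            cfg$stoichiometry$dark_fraction >= 0,
            cfg$stoichiometry$dark_fraction < 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full quantification pipeline on one acquisition
#'
#' Executes detect -> track -> stoichiometry -> diffusion -> summary on a
#' movie plus cell mask, writing every intermediate table and a run
#' manifest to `out_dir`. Foci are detected per cell on the first frame,
#' followed through the movie by iterative Gaussian re-localization, linked
#' into tracks, and their intensity traces calibrated against the
#' single-molecule brightness from terminal photobleaching steps.
#'
#' @param input A `synthetic_stack`, or a list with `movie` path and `mask`
#'   path (TIFF files).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param condition Condition label recorded in the summary.
#' @return List of class `pipeline_result`: tables `foci`, `tracks`,
#'   `diffusion`, `stoichiometry`, `summary`, `calibration` and `manifest`.
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         out_dir = NULL, condition = "condition") {
  stopifnot(inherits(config, "pipeline_config"))
  digests <- character(0)
  if (inherits(input, "synthetic_stack")) {
    movie <- input$movie
    mask <- input$cell_mask
  } else {
    stopifnot(is.list(input), !is.null(input$movie))
    digests <- vapply(unlist(input), function(p)
      unname(tools::md5sum(p)), character(1))
    movie <- read_stack(input$movie)
    mask <- if (!is.null(input$mask)) read_stack(input$mask)[1, , ] else NULL
  }
  if (is.null(mask)) mask <- matrix(1L, dim(movie)[2], dim(movie)[3])
  set.seed(config$seed)
  px <- config$acquisition$pixel_size
  rois <- rois_from_labels(mask, px)
  det <- config$detection
  foci <- detect_foci(movie[1, , ], rois, threshold_method = det$threshold_method,
                      min_area_px = det$min_area_px,
                      percentile = det$percentile, min_snr = det$min_snr,
                      pixel_size = px, frame = 0L)
  trk <- config$tracking
  tracks <- data.frame()
  diffusion <- data.frame()
  stoich <- data.frame()
  calib <- NULL
  if (nrow(foci)) {
    locs <- track_stack(movie, cbind(foci$row, foci$col),
                        window_radius = trk$window_radius,
                        psf_sigma_px = trk$psf_sigma_px, pixel_size = px)
    tracks <- link_tracks(locs, max_disp = trk$max_disp)
    if (nrow(tracks)) {
      diffusion <- estimate_diffusion_tracks(
        tracks, px, config$acquisition$frame_interval,
        n_points = trk$msd_n_points, min_length = trk$min_track_length)
      st <- config$stoichiometry
      len <- table(tracks$track_id)
      keep <- as.integer(names(len)[len >= trk$min_track_length])
      traces <- track_traces(tracks[tracks$track_id %in% keep, , drop = FALSE],
                             movie, extend = st$trace_extend,
                             window_radius = trk$window_radius)
      calib <- tryCatch(
        single_molecule_brightness(lapply(traces, `[[`, "intensity"),
                                   method = st$calibration,
                                   window = st$ck_window,
                                   min_dwell = st$min_dwell),
        error = function(e) {
          warning("brightness calibration failed: ", conditionMessage(e))
          NULL
        })
      if (!is.null(calib)) {
        stoich <- do.call(rbind, lapply(names(traces), function(id) {
          tr <- traces[[id]]
          if (length(tr$intensity) < 4) return(NULL)
          i0 <- initial_intensity(tr$intensity, frames = tr$frames)
          s <- stoichiometry(i0, calib, st$dark_fraction)
          data.frame(track_id = as.integer(id), i0 = i0,
                     stoichiometry = s$stoichiometry,
                     dark_corrected = s$dark_corrected)
        }))
        if (is.null(stoich)) stoich <- data.frame()
      }
    }
  }
  summary_tab <- condition_summary(
    condition, foci,
    data.frame(cell_id = vapply(rois, function(r) r$cell_id, numeric(1))),
    stoichiometries = if (nrow(stoich)) stoich$stoichiometry else NULL,
    diffusions = if (nrow(diffusion)) diffusion$d_coeff else NULL)
  manifest <- list(
    package_version = as.character(utils::packageVersion("aggretrack")),
    config = unclass(config),
    input_digests = as.list(digests),
    row_counts = list(foci = nrow(foci), tracks = nrow(tracks),
                      diffusion = nrow(diffusion),
                      stoichiometry = nrow(stoich)),
    calibration = if (is.null(calib)) NULL else
      list(value = calib$value, ci = calib$ci, method = calib$method,
           n_steps_used = calib$n_steps_used),
    timestamp = format(Sys.time(), usetz = TRUE))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(foci, file.path(out_dir, "foci.csv"))
    write_table(tracks, file.path(out_dir, "tracks.csv"))
    write_table(diffusion, file.path(out_dir, "diffusion.csv"))
    write_table(stoich, file.path(out_dir, "stoichiometry.csv"))
    write_table(summary_tab, file.path(out_dir, "condition_summary.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  structure(list(foci = foci, tracks = tracks, diffusion = diffusion,
                 stoichiometry = stoich, summary = summary_tab,
                 calibration = calib, manifest = manifest),
            class = "pipeline_result")
}
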