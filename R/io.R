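#' Read a multi-page TIFF stack
#'
#' @param path TIFF file (8- or 16-bit unsigned; other bit depths are
#'   rejected).
#' @return Integer array frames x rows x cols, with attribute
#'   `bits_per_sample`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
    error = function(e) stop("failed to parse TIFF '", path, "': ",
                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  for (i in seq_along(pages)) {
    bits <- attr(pages[[i]], "bits.per.sample")
    if (!is.null(bits) && !bits %in% c(8L, 16L))
      stop("unsupported bit depth (", bits, ") on page ", i, " of ", path,
           "; only 8- and 16-bit unsigned TIFFs are supported")
    if (length(dim(pages[[i]])) != 2)
      stop("page ", i, " of ", path, " is not a single-channel image")
  }
  bits <- attr(pages[[1]], "bits.per.sample")
  arr <- array(0L, dim = c(length(pages), nrow(pages[[1]]),
                           ncol(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  storage.mode(arr) <- "integer"
  attr(arr, "bits_per_sample") <- if (is.null(bits)) 16L else bits
  arr
}

#' Write a movie as a multi-page TIFF
#'
#' @param movie frames x rows x cols integer array (or a matrix for a
#'   single image); values must fit the bit depth.
#' @param path Output file.
#' @param bits 8 or 16.
#' @return `path`, invisibly.
#' @export
write_stack <- function(movie, path, bits = 16L) {
  stopifnot(bits %in% c(8L, 16L))
  if (is.matrix(movie)) movie <- array(movie, dim = c(1, dim(movie)))
  mx <- 2^bits - 1
  if (min(movie) < 0 || max(movie) > mx)
    stop("movie values outside [0, ", mx, "] cannot be written at ", bits,
         " bits")
  pages <- lapply(seq_len(dim(movie)[1]), function(f) movie[f, , ] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Write records as a CSV table
#'
#' An empty record set produces a header-only CSV; write/read round-trips
#' are lossless for numeric and character columns.
#'
#' @param records Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.csv(path)
}

#' Write a synthetic stack with its ground-truth sidecars
#'
#' Writes `<prefix>_C1.tif` (and `<prefix>_C2.tif` for two-channel
#' fixtures), `<prefix>_mask.tif` (16-bit label image),
#' `<prefix>_truth.csv` (one row per aggregate per frame: frame,
#' aggregate_id, x_um, y_um, n_active) and `<prefix>_bleach.csv` (one row
#' per fluorophore: aggregate_id, fluorophore, bleach_frame, dark).
#'
#' @param stack A `synthetic_stack`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the files written, invisibly.
#' @export
write_synthetic_stack <- function(stack, dir, prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(movie = file.path(dir, paste0(prefix, "_C1.tif")))
  write_stack(pmin(stack$movie, 65535L), paths[["movie"]])
  if (!is.null(stack$ch2)) {
    paths[["ch2"]] <- file.path(dir, paste0(prefix, "_C2.tif"))
    write_stack(pmin(stack$ch2, 65535L), paths[["ch2"]])
  }
  if (!is.null(stack$cell_mask)) {
    paths[["mask"]] <- file.path(dir, paste0(prefix, "_mask.tif"))
    m <- stack$cell_mask
    storage.mode(m) <- "integer"
    write_stack(m, paths[["mask"]])
  }
  nf <- stack$config$n_frames
  truth <- do.call(rbind, lapply(stack$truths, function(tr) {
    data.frame(frame = seq_len(nf) - 1L, aggregate_id = tr$aggregate_id,
               x_um = tr$trajectory[, 1], y_um = tr$trajectory[, 2],
               n_active = active_counts(tr, nf))
  }))
  paths[["truth"]] <- file.path(dir, paste0(prefix, "_truth.csv"))
  write_table(truth, paths[["truth"]])
  bleach <- do.call(rbind, lapply(stack$truths, function(tr) {
    data.frame(aggregate_id = tr$aggregate_id,
               fluorophore = seq_along(tr$bleach_frame),
               bleach_frame = tr$bleach_frame, dark = tr$dark)
  }))
  paths[["bleach"]] <- file.path(dir, paste0(prefix, "_bleach.csv"))
  write_table(bleach, paths[["bleach"]])
  invisible(paths)
}
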