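test_that("label mask passthrough yields identical ROIs", {
  m <- matrix(0L, 16, 16)
  m[2:5, 2:5] <- 1L; m[8:12, 8:12] <- 2L; m[2:4, 10:13] <- 3L
  rois <- segment_cells(m)
  expect_length(rois, 3)
  for (k in 1:3) expect_identical(rois[[k]]$mask, m == k)
  expect_equal(rois[[2]]$area_um2, 25 * 0.12^2)
})

test_that("radial segmentation recovers a rimmed disk cell (IoU >= 0.9)", {
  set.seed(1)
  img <- matrix(100, 64, 64)
  d <- sqrt(outer((1:64 - 32)^2, (1:64 - 32)^2, "+"))
  img[d >= 19 & d <= 21] <- 20
  img <- img + matrix(rnorm(64^2), 64)
  rois <- segment_cells(img, seeds = matrix(c(31, 31), 1),
                        radius_bounds = c(5, 30))
  expect_length(rois, 1)
  true_mask <- d < 20
  iou <- sum(rois[[1]]$mask & true_mask) / sum(rois[[1]]$mask | true_mask)
  expect_gte(iou, 0.9)
})

test_that("a seed with no enclosing boundary yields no ROI, with a message", {
  expect_message(
    rois <- segment_cells(matrix(100, 32, 32), seeds = matrix(c(15, 15), 1)),
    "no enclosing boundary")
  expect_length(rois, 0)
})

test_that("two seeds in one region give disjoint ROIs covering it", {
  set.seed(2)
  img <- matrix(100, 64, 64)
  d <- sqrt(outer((1:64 - 32)^2, (1:64 - 32)^2, "+"))
  img[d >= 19 & d <= 21] <- 20
  img <- img + matrix(rnorm(64^2, 0, 0.5), 64)
  rois <- segment_cells(img, seeds = rbind(c(27, 31), c(35, 31)),
                        radius_bounds = c(5, 30))
  expect_length(rois, 2)
  expect_equal(sum(rois[[1]]$mask & rois[[2]]$mask), 0)
  un <- rois[[1]]$mask | rois[[2]]$mask
  true_mask <- d < 20
  expect_gte(sum(un & true_mask) / sum(un | true_mask), 0.85)
})

test_that("component labelling is 8-connected", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE   # diagonal neighbours
  expect_equal(max(label_components(m)), 1L)
  m[5, 5] <- TRUE
  expect_equal(max(label_components(m)), 2L)
})

test_that("detection inside cells: uniform ROI is empty; rendered spots are found", {
  cells <- one_cell(c(32L, 32L))
  expect_equal(nrow(detect_foci(matrix(7, 32, 32), cells)), 0L)

  # one bright rendered Gaussian spot: 1 focus, centroid and intensity match
  cfg <- quiet_config(n_frames = 1L)
  cfg$background_photons <- 2
  tru <- immobile_truth(cfg, 50, 1.9, 1.85)   # 15k photons, peak ~ 50x bg
  st <- render_stack(cfg, tru, noise = FALSE)
  # mean threshold sits near background, so the component captures nearly
  # the whole PSF integral (Otsu clips the tails by construction)
  f <- detect_foci(st$movie[1, , ], cells, threshold_method = "mean",
                   min_snr = 0)
  expect_equal(nrow(f), 1L)
  expect_lt(abs(f$row - 1.85 / 0.12), 0.5)
  expect_lt(abs(f$col - 1.9 / 0.12), 0.5)
  signal <- 50 * cfg$photons_per_fluorophore_per_frame
  expect_equal(f$integrated_intensity_bgsub, signal, tolerance = 0.05)

  # two spots 6 psf-sigma apart resolve as two foci
  sep_um <- 6 * cfg$psf_sigma / 1000
  tru2 <- simulate_aggregates(cfg, c(50, 50), 0,
                              starts = rbind(c(1.9, 1.85),
                                             c(1.9 + sep_um, 1.85)))
  st2 <- render_stack(cfg, tru2, noise = FALSE)
  expect_equal(nrow(detect_foci(st2$movie[1, , ], cells, min_snr = 0)), 2L)
})

test_that("per-ROI thresholding is invariant to pixels outside the cell", {
  set.seed(3)
  cfg <- sim_config(n_frames = 1, image_shape = c(48L, 48L), rng_seed = 11L)
  tru <- immobile_truth(cfg, 40, 1.4, 1.4)
  img <- render_stack(cfg, tru)$movie[1, , ]
  mask <- matrix(0L, 48, 48); mask[1:24, 1:24] <- 1L
  f1 <- detect_foci(img, mask)
  img2 <- img
  img2[30:48, 30:48] <- 60000L   # garbage far outside cell 1
  f2 <- detect_foci(img2, mask)
  expect_equal(f1, f2)
})

test_that("integrated intensity is additive over a split focus mask", {
  set.seed(4)
  img <- matrix(sample.int(1000, 100), 10, 10)
  whole <- sum(img[3:6, 3:6])
  part1 <- sum(img[3:6, 3:4]); part2 <- sum(img[3:6, 5:6])
  expect_identical(part1 + part2, whole)
})

test_that("raising min_area_px never increases the focus count", {
  set.seed(5)
  cfg <- sim_config(n_frames = 1, image_shape = c(64L, 64L), rng_seed = 12L)
  st <- simulate_slimfield_stack(cfg, 30, 0, n_cells = 4)
  img <- st$movie[1, , ]
  counts <- vapply(c(1, 2, 4, 8, 16, 40), function(a)
    nrow(detect_foci(img, st$cell_mask, min_area_px = a)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection recall and precision >= 0.95 on default-SNR stacks", {
  set.seed(6)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (s in 1:10) {
    cfg <- sim_config(n_frames = 1, image_shape = c(64L, 64L),
                      rng_seed = 100L + s)
    st <- simulate_slimfield_stack(cfg, 30, 0, n_cells = 4)
    f <- detect_foci(st$movie[1, , ], st$cell_mask)
    px_um <- cfg$pixel_size / 1000
    truth <- t(vapply(st$truths, function(tr)
      c(tr$trajectory[1, 2] / px_um, tr$trajectory[1, 1] / px_um),
      numeric(2)))  # (row, col) px
    matched <- logical(nrow(truth))
    for (i in seq_len(nrow(f))) {
      dd <- sqrt((truth[, 1] - f$row[i])^2 + (truth[, 2] - f$col[i])^2)
      j <- which.min(dd)
      if (dd[j] <= 3 && !matched[j]) { matched[j] <- TRUE; tp <- tp + 1L }
      else fp <- fp + 1L
    }
    fn <- fn + sum(!matched)
  }
  expect_gte(tp / (tp + fn), 0.95)
  expect_gte(tp / (tp + fp), 0.95)
})

test_that("aggregate-positive fraction implements the definition", {
  foci <- data.frame(cell_id = c(rep(1:19, 2), 19))
  expect_equal(aggregate_positive_fraction(foci, 1:100), 19)
  expect_equal(aggregate_positive_fraction(foci[0, , drop = FALSE], 1:10), 0)
  expect_equal(aggregate_positive_fraction(data.frame(cell_id = 1:5), 1:5), 100)
  expect_error(aggregate_positive_fraction(foci, integer(0)), "zero cells")
})

test_that("IQR outlier removal: fences, idempotence, short-input warning", {
  expect_equal(remove_outliers_iqr(1:5), 1:5)
  expect_equal(remove_outliers_iqr(c(1, 2, 3, 4, 100)), c(1, 2, 3, 4))
  once <- remove_outliers_iqr(c(1, 2, 3, 4, 100))
  expect_equal(remove_outliers_iqr(once), once)
  expect_warning(out <- remove_outliers_iqr(c(1, 2, 3)), "fewer than 4")
  expect_equal(out, c(1, 2, 3))
})
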