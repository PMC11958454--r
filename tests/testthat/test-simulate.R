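test_that("Brownian steps have the prescribed variance and zero-D tracks stay put", {
  set.seed(1)
  tr <- simulate_brownian_track(1.0, 10001, 0.005)
  expect_equal(var(diff(tr[, 1])), 0.01, tolerance = 0.05)
  expect_equal(var(diff(tr[, 2])), 0.01, tolerance = 0.05)

  still <- simulate_brownian_track(0, 50, 0.005, start = c(1.2, 3.4))
  expect_true(all(still[, 1] == 1.2) && all(still[, 2] == 3.4))
})

test_that("reflecting disk bounds confine the walk and bad starts are rejected", {
  set.seed(2)
  b <- disk_bounds(c(0, 0), 1)
  tr <- simulate_brownian_track(1.0, 10000, 0.005, start = c(0, 0), bounds = b)
  expect_true(all(sqrt(rowSums(tr^2)) <= 1 + 1e-12))
  expect_error(simulate_brownian_track(1, 10, 0.005, start = c(5, 0),
                                       bounds = b),
               "outside")
})

test_that("photobleaching counts follow geometric survival and edge cases", {
  pb0 <- simulate_photobleaching(50, 0, 0, 100, seed = 1)
  expect_true(all(pb0$counts == 50L))
  pb1 <- simulate_photobleaching(50, 1, 0, 100, seed = 1)
  expect_equal(pb1$counts, c(50L, rep(0L, 99)))

  set.seed(3)
  # mean photoactive count at frame t ~ N * (1-p)^t
  at <- replicate(1000, simulate_photobleaching(100, 0.01, 0, 151)$counts[151])
  expected <- 100 * 0.99^150
  se <- sd(at) / sqrt(length(at))
  expect_lt(abs(mean(at) - expected), 3 * se)
})

test_that("bleaching is monotone and the dark fraction is respected", {
  set.seed(4)
  for (i in 1:20) {
    pb <- simulate_photobleaching(30, runif(1, 0, 0.2), runif(1, 0, 0.3), 50)
    expect_true(all(diff(pb$counts) <= 0))
    expect_true(all(pb$bleach_frame[pb$dark] == 0))
  }
  pb <- simulate_photobleaching(20000, 0.01, 0.07, 5, seed = 5)
  se <- sqrt(0.07 * 0.93 / 20000)
  expect_lt(abs(mean(pb$dark) - 0.07), 3 * se)
})

test_that("rendering conserves photons in no-noise mode", {
  cfg <- quiet_config()
  tru <- immobile_truth(cfg, 1, 1.9, 1.85)
  st <- render_stack(cfg, tru, noise = FALSE)
  for (f in 1:cfg$n_frames) {
    expect_equal(sum(st$movie[f, , ]),
                 cfg$photons_per_fluorophore_per_frame, tolerance = 0.01)
  }
  # several aggregates, with bleaching: total = sum(active) * photons
  cfg2 <- quiet_config(n_frames = 40L, shape = c(48L, 48L))
  cfg2$bleach_prob <- 0.05
  set.seed(6)
  tru2 <- simulate_aggregates(cfg2, c(5, 3), 0,
                              starts = rbind(c(1.5, 1.5), c(4.0, 4.0)))
  st2 <- render_stack(cfg2, tru2, noise = FALSE)
  for (f in c(1L, 10L, 40L)) {
    active <- sum(vapply(tru2, function(tr)
      sum(!tr$dark & tr$bleach_frame > f - 1), numeric(1)))
    expect_equal(sum(st2$movie[f, , ]),
                 active * cfg2$photons_per_fluorophore_per_frame,
                 tolerance = 0.01)
  }
})

test_that("rendering with no aggregates and no noise gives an all-zero movie", {
  cfg <- quiet_config()
  st <- render_stack(cfg, list(), noise = FALSE)
  expect_true(all(st$movie == 0))
})

test_that("identical configs give bit-identical stacks", {
  cfg <- sim_config(n_frames = 5, image_shape = c(24L, 24L), rng_seed = 9L)
  tru <- immobile_truth(cfg, 10, 1.2, 1.2)
  a <- render_stack(cfg, tru)
  b <- render_stack(cfg, tru)
  expect_identical(a$movie, b$movie)
  s1 <- simulate_slimfield_stack(cfg, 20, 0.5, n_cells = 2)
  s2 <- simulate_slimfield_stack(cfg, 20, 0.5, n_cells = 2)
  expect_identical(s1$movie, s2$movie)
  expect_identical(s1$truths[[1]]$trajectory, s2$truths[[1]]$trajectory)
})

test_that("trajectories outside the image are rejected at render time", {
  cfg <- quiet_config()
  tru <- immobile_truth(cfg, 1, 100, 100)   # far outside a 32x32 field
  expect_error(render_stack(cfg, tru), "leaves the image")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(bleach_prob = 1.5))
  expect_error(sim_config(dark_fraction = 1))
  expect_error(sim_config(pixel_size = -1))
})

test_that("confocal fixture: organelle transfer timing and aggregate retention", {
  ct_v <- simulate_confocal_timelapse(organelle = "vacuole")
  ct_n <- simulate_confocal_timelapse(organelle = "nucleus")
  in_bud <- function(ct) vapply(seq_along(ct$organelle_masks), function(f)
    any(ct$organelle_masks[[f]] != 0 & ct$cell_masks[[f]] == 2L), logical(1))
  # vacuole: present in the bud from the ~20 min timepoint onward
  expect_equal(which(in_bud(ct_v))[1], ct_v$organelle_transfer_frame)
  expect_equal(ct_v$time_min[ct_v$organelle_transfer_frame], 20)
  # nucleus: absent from the bud before the ~60 min timepoint
  expect_true(all(!in_bud(ct_n)[ct_n$time_min < 60]))
  # retained aggregates: no ground-truth position in the bud at the end
  last_mask <- ct_v$cell_masks[[length(ct_v$cell_masks)]]
  px_um <- ct_v$config$pixel_size / 1000
  for (tr in ct_v$truths) {
    p <- tr$trajectory[nrow(tr$trajectory), ]
    lab <- last_mask[round(p[2] / px_um) + 1L, round(p[1] / px_um) + 1L]
    expect_equal(lab, 1L)
  }
})

test_that("mask bounds keep trajectories inside their cell", {
  cfg <- sim_config(n_frames = 300, image_shape = c(64L, 64L), rng_seed = 7L)
  st <- simulate_slimfield_stack(cfg, 10, 1.5, n_cells = 4)
  px_um <- cfg$pixel_size / 1000
  for (tr in st$truths) {
    labs <- st$cell_mask[cbind(round(tr$trajectory[, 2] / px_um) + 1L,
                               round(tr$trajectory[, 1] / px_um) + 1L)]
    expect_true(all(labs == tr$cell_id))
  }
})
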