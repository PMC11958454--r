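test_that("noiseless localization recovers a sub-pixel centre to 1e-2 px", {
  cfg <- quiet_config(n_frames = 1L)
  # true centre (row, col) px = (y, x)/pixel: (20.30, 41.70) px
  cfg$image_shape <- c(40L, 60L)
  tru <- immobile_truth(cfg, 10, 41.70 * 0.12, 20.30 * 0.12)
  st <- render_stack(cfg, tru, noise = FALSE)
  loc <- localize_focus(st$movie[1, , ], c(20, 42))
  expect_lt(abs(loc$row - 20.30), 1e-2)
  expect_lt(abs(loc$col - 41.70), 1e-2)
  expect_gt(loc$fitted_sigma, 0)
  expect_gt(loc$precision_nm, 0)
})

test_that("a flat window is rejected with a warning, not silently dropped", {
  img <- matrix(10, 32, 32)
  expect_warning(loc <- localize_focus(img, c(15, 15)), "rejected")
  expect_null(loc)
  expect_error(localize_focus(img, c(2, 2)), "outside the image")
})

test_that("localization is equivariant under integer pixel translation", {
  cfg <- sim_config(n_frames = 1, image_shape = c(48L, 48L), rng_seed = 21L)
  tru <- immobile_truth(cfg, 20, 2.0, 1.9)
  img <- render_stack(cfg, tru)$movie[1, , ]
  sh <- matrix(as.integer(cfg$background_photons), 48, 48)
  sh[6:48, 4:48] <- img[1:43, 1:45]   # translate by (+5, +3)
  l0 <- localize_focus(img, c(16, 17))
  l1 <- localize_focus(sh, c(21, 20))
  expect_equal(l1$row, l0$row + 5, tolerance = 1e-9)
  expect_equal(l1$col, l0$col + 3, tolerance = 1e-9)
})

test_that("localization error scales as 1/sqrt(photons)", {
  set.seed(22)
  rms_at <- function(n_mol, reps) {
    errs <- replicate(reps, {
      cfg <- sim_config(n_frames = 1, image_shape = c(32L, 32L),
                        rng_seed = NULL)
      p <- c(1.86, 1.86) + runif(2, -0.06, 0.06)
      tru <- immobile_truth(cfg, n_mol, p[1], p[2])
      st <- render_stack(cfg, tru)
      l <- localize_focus(st$movie[1, , ], c(15, 15), quiet = TRUE)
      if (is.null(l)) return(NA)
      sqrt((l$col * 0.12 - p[1])^2 + (l$row * 0.12 - p[2])^2) * 1000
    })
    sqrt(mean(errs^2, na.rm = TRUE))
  }
  r1 <- rms_at(1, 250)
  r4 <- rms_at(4, 250)   # 4x the photons -> half the error
  expect_equal(r1 / r4, 2, tolerance = 0.2)
})

test_that("greedy linking keeps one track per focus and respects max_disp", {
  # one slow focus across 20 frames -> one track
  set.seed(23)
  locs <- data.frame(frame = 0:19, row = 10 + cumsum(rnorm(20, 0, 0.3)),
                     col = 12 + cumsum(rnorm(20, 0, 0.3)))
  tr <- link_tracks(locs, max_disp = 5)
  expect_equal(length(unique(tr$track_id)), 1L)

  # a jump beyond max_disp starts a new track
  locs2 <- data.frame(frame = 0:9, row = c(rep(5, 5), rep(25, 5)),
                      col = 5)
  tr2 <- link_tracks(locs2, max_disp = 5)
  expect_equal(length(unique(tr2$track_id)), 2L)
  expect_equal(unname(table(tr2$track_id)), c(5L, 5L), ignore_attr = TRUE)
})

test_that("well-separated tracks link with zero identity switches and match the brute-force optimum", {
  set.seed(24)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  for (rep in 1:5) {
    n <- sample(2:4, 1)
    starts <- cbind(runif(n, 10, 90), runif(n, 10, 90))
    while (min(dist(starts)) < 25) starts <- cbind(runif(n, 10, 90),
                                                   runif(n, 10, 90))
    locs <- do.call(rbind, lapply(0:9, function(f)
      data.frame(frame = f, row = starts[, 1] + rnorm(n, 0, 0.5),
                 col = starts[, 2] + rnorm(n, 0, 0.5), truth = seq_len(n))))
    linked <- link_tracks(locs, max_disp = 5)
    # zero switches: each track id maps to exactly one ground-truth identity
    expect_true(all(tapply(linked$truth, linked$track_id,
                           function(x) length(unique(x))) == 1))
    # greedy frame-to-frame cost equals the optimal assignment cost
    for (f in 1:9) {
      a <- linked[linked$frame == f - 1, ]
      b <- linked[linked$frame == f, ]
      d <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j)
        sqrt((a$row[i] - b$row[j])^2 + (a$col[i] - b$col[j])^2))
      greedy_cost <- sum(d[cbind(match(b$track_id, a$track_id),
                                 seq_len(nrow(b)))])
      best <- min(vapply(perms(seq_len(nrow(b))), function(p)
        sum(d[cbind(seq_len(nrow(a)), p)]), numeric(1)))
      expect_equal(greedy_cost, best, tolerance = 1e-9)
    }
  }
})

test_that("MSD closed forms: static, ballistic and Brownian tracks", {
  still <- data.frame(frame = 0:49, row = 10, col = 20)
  m <- compute_msd(still, 120, 0.005)
  expect_true(all(m$msd == 0))

  v <- 2.0  # um/s along x
  bal <- data.frame(frame = 0:49, row = 10,
                    col = (0:49) * v * 0.005 / 0.12)
  mb <- compute_msd(bal, 120, 0.005)
  expect_equal(mb$msd, (v * mb$dt)^2, tolerance = 1e-9)

  set.seed(25)
  tr <- simulate_brownian_track(1.0, 10000, 0.005)
  df <- data.frame(frame = 0:9999, row = tr[, 2] / 0.12, col = tr[, 1] / 0.12)
  m1 <- compute_msd(df, 120, 0.005)
  expect_equal(m1$msd[1], 4 * 1.0 * 0.005, tolerance = 0.1)
  expect_error(compute_msd(still[1, ], 120, 0.005), "at least 2")
})

test_that("diffusion fit recovers an exact line and flags short input", {
  msd <- data.frame(dt = (1:6) * 0.005, msd = 4 * 0.99 * (1:6) * 0.005,
                    n_pairs = 100:95)
  est <- estimate_diffusion(msd, 4)
  expect_equal(est$d_coeff, 0.99, tolerance = 1e-12)
  expect_equal(est$intercept, 0, tolerance = 1e-12)
  expect_warning(e2 <- estimate_diffusion(msd[1:3, ], 4), "fewer MSD points")
  expect_equal(e2$n_points_used, 3L)
})

test_that("static emitter: D near zero with intercept ~ 4 sigma_loc^2", {
  set.seed(26)
  sig <- 0.03  # um localization noise per axis
  ints <- replicate(400, {
    df <- data.frame(frame = 0:29, row = rnorm(30, 0, sig / 0.12),
                     col = rnorm(30, 0, sig / 0.12))
    est <- estimate_diffusion(compute_msd(df, 120, 0.005), 4)
    c(est$d_coeff, est$intercept)
  })
  expect_lt(abs(mean(ints[1, ])), 0.05)
  expect_equal(mean(ints[2, ]), 4 * sig^2, tolerance = 0.3)
})

test_that("MSD-gradient D is unbiased over simulated ensembles", {
  set.seed(27)
  for (d_true in c(0.1, 0.5, 1.0)) {
    ex <- diffusion_recovery_experiment(d_true, n_tracks = 300L,
                                        n_frames = 60L, seed = d_true * 100)
    se <- sd(ex$d_estimates) / sqrt(ex$n_tracks)
    expect_lt(abs(ex$mean_d - d_true), 3 * se)
  }
})
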