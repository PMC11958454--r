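test_that("colocalization: inside, far away, and the geometric null", {
  mask <- matrix(FALSE, 64, 64)
  mask[20:30, 20:30] <- TRUE
  inside <- data.frame(row = 25, col = 25)
  expect_equal(colocalize(inside, mask)$n_colocalized, 1L)
  # ~1 um from the mask edge at 120 nm pixels: not colocalized at 250 nm
  far <- data.frame(row = 25, col = 39)
  expect_equal(colocalize(far, mask, max_distance = 250)$n_colocalized, 0L)
  expect_error(colocalize(inside[0, , drop = FALSE], mask), "zero foci")

  # uniform random foci in a cell: fraction ~ dilated-mask area fraction
  set.seed(1)
  cell <- matrix(TRUE, 64, 64)
  dil_px <- 250 / 120
  dist_to <- EBImage::distmap(matrix(as.numeric(!mask), 64))@.Data
  p_geo <- mean(dist_to <= dil_px)
  n <- 1000
  foci <- data.frame(row = sample.int(64, n, TRUE) - 1,
                     col = sample.int(64, n, TRUE) - 1)
  fr <- colocalize(foci, mask)$fraction / 100
  se <- sqrt(p_geo * (1 - p_geo) / n)
  expect_lt(abs(fr - p_geo), 3 * se)
})

test_that("colocalized fraction is non-decreasing in the distance threshold", {
  set.seed(2)
  mask <- matrix(FALSE, 64, 64); mask[10:20, 40:55] <- TRUE
  foci <- data.frame(row = runif(50, 0, 63), col = runif(50, 0, 63))
  fr <- vapply(c(0, 120, 250, 500, 1000, 2000), function(d)
    colocalize(foci, mask, max_distance = d)$fraction, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("mother/daughter summaries: means, empty roles, generator ratio", {
  foci <- data.frame(cell_id = c(1, 1, 2),
                     area_um2 = c(1.0, 1.0, 0.4),
                     integrated_intensity = c(100, 100, 50))
  roles <- data.frame(cell_id = 1:2, role = c("mother", "daughter"))
  st <- mother_daughter_stats(foci, roles)
  expect_equal(st$mean_area_um2[st$role == "mother"], 1.0)
  expect_equal(st$mean_area_um2[st$role == "daughter"], 0.4)

  only_m <- foci[foci$cell_id == 1, ]
  st2 <- mother_daughter_stats(only_m, roles)
  expect_true(st2$empty[st2$role == "daughter"])
  expect_true(is.na(st2$mean_area_um2[st2$role == "daughter"]))
  expect_error(mother_daughter_stats(data.frame(cell_id = 9, area_um2 = 1,
                                                integrated_intensity = 1),
                                     roles), "role-annotated")

  # generator-set mother:daughter area ratio recovered within 15%
  set.seed(3)
  big <- data.frame(cell_id = 1, area_um2 = rnorm(60, 1.0, 0.1),
                    integrated_intensity = rnorm(60, 500, 20))
  small <- data.frame(cell_id = 2, area_um2 = rnorm(60, 0.4, 0.05),
                      integrated_intensity = rnorm(60, 200, 15))
  st3 <- mother_daughter_stats(rbind(big, small), roles)
  ratio <- st3$mean_area_um2[st3$role == "mother"] /
    st3$mean_area_um2[st3$role == "daughter"]
  expect_lt(abs(ratio - 2.5) / 2.5, 0.15)
})

test_that("inheritance scoring: retention, transfer, conservation, skipped masks", {
  set.seed(4)
  ct <- simulate_confocal_timelapse()
  fbt <- lapply(seq_along(ct$cell_masks), function(f)
    detect_foci(ct$movie[f, , ], ct$cell_masks[[f]]))
  ih <- inheritance_score(fbt, ct$cell_masks, ct$organelle_masks)
  expect_equal(ih$inherited_fraction, 0)
  # organelle flag first true at the 20-min timepoint (vacuole)
  expect_equal(which(ih$per_timepoint$organelle_in_bud)[1] - 1L,
               ct$organelle_transfer_frame - 1L)
  # conservation: mother + bud equals total detected foci at each timepoint
  totals <- vapply(fbt, nrow, integer(1))
  expect_equal(ih$per_timepoint$n_mother + ih$per_timepoint$n_bud, totals)

  ct2 <- simulate_confocal_timelapse(inheritance_policy = "transfer_final")
  fbt2 <- lapply(seq_along(ct2$cell_masks), function(f)
    detect_foci(ct2$movie[f, , ], ct2$cell_masks[[f]]))
  ih2 <- inheritance_score(fbt2, ct2$cell_masks, ct2$organelle_masks)
  last <- nrow(ih2$per_timepoint)
  tot <- ih2$per_timepoint$n_mother[last] + ih2$per_timepoint$n_bud[last]
  expect_equal(ih2$inherited_fraction, ih2$per_timepoint$n_bud[last] / tot)
  expect_gt(ih2$inherited_fraction, 0)

  masks <- ct$cell_masks; masks[4] <- list(NULL)
  expect_warning(ih3 <- inheritance_score(fbt, masks, ct$organelle_masks),
                 "skipped")
  expect_equal(nrow(ih3$per_timepoint), length(fbt) - 1L)
})

test_that("t-test wrapper: Welch, identical samples, degenerate flag", {
  set.seed(5)
  a <- rnorm(20); b <- rnorm(20, 1)
  ours <- compare_conditions(a, b, "student_t")
  ref <- t.test(a, b, var.equal = FALSE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value)

  same <- compare_conditions(c(2, 2, 2), c(2, 2, 2), "student_t")
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)
  idn <- compare_conditions(a, a, "student_t")
  expect_equal(idn$statistic, 0, tolerance = 1e-12)
  expect_equal(idn$p_value, 1)
})

test_that("Mann-Whitney U equals the brute-force statistic and exact p for n,m <= 8", {
  set.seed(6)
  for (rep in 1:20) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    a <- round(runif(n, 0, 50), 1); b <- round(runif(m, 0, 50), 1)
    if (any(duplicated(c(a, b)))) next
    ours <- compare_conditions(a, b, "mann_whitney")
    expect_equal(ours$statistic, brute_force_u(a, b))
    expect_equal(ours$p_value, brute_force_u_pvalue(a, b), tolerance = 1e-9)
  }
  # fully separated 3-vs-3: smallest attainable two-sided exact p = 0.1
  sep <- compare_conditions(c(1, 2, 3), c(10, 11, 12), "mann_whitney")
  expect_equal(sep$p_value, 0.1)
})

test_that("two-sided p is symmetric under sample exchange", {
  set.seed(7)
  for (rep in 1:10) {
    a <- rnorm(sample(4:12, 1)); b <- rnorm(sample(4:12, 1), 0.5)
    for (tst in c("student_t", "mann_whitney")) {
      expect_equal(compare_conditions(a, b, tst)$p_value,
                   compare_conditions(b, a, tst)$p_value, tolerance = 1e-12)
    }
  }
})

test_that("fold changes reproduce the printed-arithmetic conventions", {
  fc <- fold_changes(157, 290)
  expect_equal(fc$percent_increase, 100 * (290 - 157) / 157)
  expect_equal(fc$factor, 290 / 157)
  fd <- fold_changes(0.99, 0.36)
  expect_equal(fd$percent_of, 100 * 0.36 / 0.99)
  expect_equal(fd$percent_decrease, 100 * (0.99 - 0.36) / 0.99)
  eq <- fold_changes(5, 5)
  expect_equal(eq$percent_increase, 0)
  expect_equal(eq$factor, 1)
  expect_error(fold_changes(0, 3), "zero denominator")
})

test_that("condition summary aggregates counts, fractions and replicate sd", {
  foci <- data.frame(cell_id = c(1, 1, 3, 5), area_um2 = c(1, 1.2, 0.5, 0.8),
                     integrated_intensity = c(10, 12, 5, 8))
  cells <- data.frame(cell_id = 1:6, field = rep(1:2, each = 3))
  cs <- condition_summary("ctrl", foci, cells)
  expect_equal(cs$n_cells, 6L)
  expect_equal(cs$pct_positive, 50)
  # per-field positives: field1 {1,3} of 3 -> 66.7%; field2 {5} of 3 -> 33.3%
  expect_equal(cs$pct_positive_sd, sd(c(200 / 3, 100 / 3)))
})
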