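test_that("generation is deterministic in the seed", {
  p <- swim_params(duration = 30, seed = 42, wall_affinity = 2)
  t1 <- generate_trajectory(p, default_arena)
  t2 <- generate_trajectory(p, default_arena)
  expect_identical(t1$x_mm, t2$x_mm)
  expect_identical(t1$y_mm, t2$y_mm)
  t3 <- generate_trajectory(swim_params(duration = 30, seed = 43,
                                        wall_affinity = 2), default_arena)
  expect_false(identical(t1$x_mm, t3$x_mm))
})

test_that("mean_speed = 0 freezes the larva", {
  p <- swim_params(duration = 10, mean_speed = 0, seed = 1)
  tr <- generate_trajectory(p, default_arena)
  expect_equal(length(unique(tr$x_mm)), 1L)
  expect_equal(length(unique(tr$y_mm)), 1L)
  s <- summarize_kinematics(tr)
  expect_equal(s$activity_fraction, 0)
})

test_that("positions stay strictly inside the well", {
  for (wa in c(0, 5)) {
    p <- swim_params(duration = 60, wall_affinity = wa, mean_speed = 30,
                     heading_persistence = 0.5, seed = 9 + wa)
    tr <- generate_trajectory(p, default_arena)
    expect_true(all(traj_radius(tr) < default_arena$well_radius))
    expect_equal(nrow(tr), 60 * 30)
  }
})

test_that("interval durations follow the truncated power laws (KS <= 0.02)", {
  p <- swim_params(duration = 3000, k_rest = 2.0, k_bout = 2.5, seed = 4)
  tr <- generate_trajectory(p, default_arena)
  active <- attr(tr, "active_true")
  r <- rle(active)
  for (lab in c(TRUE, FALSE)) {
    durs <- r$lengths[r$values == lab]
    k <- if (lab) p$k_bout else p$k_rest
    support <- 1:(3000 * 30)
    cdf <- cumsum(support^-k) / sum(support^-k)
    ecdf_v <- ecdf(durs)(support)
    expect_lt(max(abs(ecdf_v - cdf)), 0.02)
    expect_gt(length(durs), 5e3)
  }
})

test_that("wall_affinity = 0 gives area-uniform occupancy", {
  trajs <- lapply(1:10, function(i)
    generate_trajectory(swim_params(duration = 600, wall_affinity = 0,
                                    seed = 20 + i), default_arena))
  pooled_outer <- mean(sapply(trajs, function(t)
    zone_occupancy(t, default_arena)$pct_outer))
  expect_lt(abs(pooled_outer - 64), 2)

  # chi-squared on 10 equal-area annuli; thin to ~decorrelated samples
  # (consecutive frames are autocorrelated and would invalidate the test)
  r2 <- unlist(lapply(trajs, function(t) {
    idx <- seq(1, nrow(t), by = 21)
    traj_radius(t)[idx]^2
  }))
  R2 <- default_arena$well_radius^2
  bins <- findInterval(r2 / R2, seq(0, 1, by = 0.1),
                       rightmost.closed = TRUE, all.inside = TRUE)
  p <- suppressWarnings(chisq.test(tabulate(bins, 10)))$p.value
  expect_gt(p, 0.01)
})

test_that("expected_activity matches realized activity on long recordings", {
  # max_interval caps the heavy tail; without it a single realization
  # systematically undershoots the truncated-mean expectation because the
  # mean is carried by bouts too rare to appear in 2000 s
  p <- swim_params(duration = 2000, k_rest = 2.5, k_bout = 2.2,
                   max_interval = 10, seed = 15)
  tr <- generate_trajectory(p, default_arena)
  expect_lt(abs(attr(tr, "activity_true_pct") - expected_activity(p)), 3)
})

test_that("parameter validation rejects bad inputs", {
  expect_error(swim_params(k_rest = -1), "k_rest")
  expect_error(swim_params(heading_persistence = 2), "heading_persistence")
  expect_error(swim_params(frame_rate = 30, min_duration = 0.001),
               "min_duration")
  expect_error(swim_params(wall_affinity = -0.5), "wall_affinity")
})

test_that("simulate_cohort assigns stratified affinities deterministically", {
  p <- swim_params(duration = 5, wall_affinity = 2, seed = 1)
  co <- simulate_cohort(p, 6, default_arena, affinity_sdlog = 1, seed = 50)
  expect_length(co, 6)
  expect_named(co, sprintf("larva_%02d", 1:6))
  wa <- attr(co, "wall_affinities")
  expect_equal(wa, 2 * qlnorm((1:6 - 0.5) / 6, -0.5, 1))
  co2 <- simulate_cohort(p, 6, default_arena, affinity_sdlog = 1, seed = 50)
  expect_identical(co[[3]]$x_mm, co2[[3]]$x_mm)
  # sdlog = 0 gives identical animals up to the per-larva seed
  co0 <- simulate_cohort(p, 3, default_arena, affinity_sdlog = 0, seed = 50)
  expect_equal(attr(co0, "wall_affinities"), rep(2, 3))
})

test_that("cohort presets encode the intended contrasts", {
  pr <- cohort_presets(duration = 60)
  expect_s3_class(pr$wt, "swim_params")
  expect_s3_class(pr$mutant, "swim_params")
  expect_gt(pr$wt$k_rest, pr$mutant$k_rest)
  expect_lt(pr$wt$k_bout, pr$mutant$k_bout)
  expect_gt(pr$wt$mean_speed, pr$mutant$mean_speed)
  expect_gt(pr$wt$wall_affinity, pr$mutant$wall_affinity)
  expect_gt(expected_activity(pr$wt), expected_activity(pr$mutant))
})
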