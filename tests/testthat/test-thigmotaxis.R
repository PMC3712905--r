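test_that("zone occupancy handles pure-center and boundary cases", {
  tr <- make_traj(rep(0, 10), rep(0, 10))
  z <- zone_occupancy(tr, default_arena)
  expect_equal(z$pct_inner, 100)
  expect_equal(z$pct_outer, 0)
  expect_equal(z$random_outer_pct, 64)
  # exactly r = inner_radius counts as outer (half-open zones)
  tb <- make_traj(rep(4.5, 10), rep(0, 10))
  expect_equal(zone_occupancy(tb, default_arena)$pct_outer, 100)
  # percentages always sum to 100
  p <- generate_trajectory(swim_params(duration = 20, seed = 3),
                           default_arena)
  zz <- zone_occupancy(p, default_arena)
  expect_equal(zz$pct_inner + zz$pct_outer, 100)
})

test_that("density map normalizes and localizes a static larva", {
  tr <- make_traj(rep(3, 10), rep(3, 10))
  m <- occupancy_density_map(tr, default_arena, n_bins = 10)
  expect_equal(sum(m$grid), 1)
  expect_equal(sum(m$grid > 0), 1L)
  expect_equal(max(m$grid), 1)
  expect_error(occupancy_density_map(tr, default_arena, n_bins = 1),
               "n_bins")
})

test_that("wall arrival events follow the crossing rule", {
  # never near the wall
  far <- make_traj(rep(0, 50), rep(0, 50))
  expect_equal(nrow(wall_arrival_events(far, default_arena)), 0L)
  # glued to the wall from frame 0: one initial event at frame 0
  glued <- make_traj(rep(7.2, 50), rep(0, 50))
  ev <- wall_arrival_events(glued, default_arena)
  expect_equal(ev$frame, 0L)
  expect_true(ev$initial)
  # sawtooth crossing the 7.0 mm circle 5 times
  one_tooth <- c(seq(6, 7.3, by = 0.1), seq(7.2, 6.1, by = -0.1))
  saw <- radial_traj(rep(one_tooth, 5))
  expect_equal(nrow(wall_arrival_events(saw, default_arena)), 5L)
})

test_that("stay probability is 1 for a cohort that never leaves", {
  glued <- make_traj(rep(7.2, 40 * 30), rep(0, 40 * 30))
  sc <- wall_stay_curve(list(glued), default_arena)
  expect_equal(sc$p_stay[1], 1)
  expect_true(all(sc$p_stay == 1))
  expect_equal(length(sc$t_s), default_arena$window * 30 + 1)
})

test_that("stay curve matches a known exponential hazard", {
  lam <- 0.2
  fr <- 10
  times <- withr::with_seed(21, rexp(500, lam))
  cohort <- stay_time_cohort(times, default_arena, fr = fr)
  sc <- wall_stay_curve(cohort, default_arena)
  # exact oracle: the curve is the survivor function of the frame-quantized
  # stay times encoded in the cohort
  n_stay <- pmax(1L, round(times * fr))
  oracle <- vapply(round(sc$t_s * fr), function(j) mean(n_stay > j),
                   numeric(1))
  expect_equal(sc$p_stay, oracle)
  # and it tracks the continuous survival within a 4-sigma binomial envelope
  # plus the frame-quantization allowance
  p_true <- exp(-lam * sc$t_s)
  env <- 4 * sqrt(p_true * (1 - p_true) / 500) + lam / fr
  expect_true(all(abs(sc$p_stay - p_true) <= env))
})

test_that("instantaneous mode allows returns and differs from continuous", {
  # larva leaves the band briefly and comes back into the stay band without
  # re-entering the reach band (which would start a second event)
  radii <- c(rep(7.3, 10), rep(6, 5), rep(6.7, 300))
  tr <- radial_traj(radii, fr = 10)
  cont <- wall_stay_curve(list(tr), default_arena, mode = "continuous")
  inst <- wall_stay_curve(list(tr), default_arena, mode = "instantaneous")
  i5 <- which.min(abs(cont$t_s - 5))
  expect_equal(cont$p_stay[i5], 0)   # left for good in continuous terms
  expect_equal(inst$p_stay[i5], 1)   # but is present at t = 5 s
})

test_that("censored events drop out of the stay denominator", {
  fr <- 10
  # arrival 5 s before the recording ends; window is 30 s
  radii <- c(rep(5, 10), rep(7.3, 5 * fr))
  tr <- radial_traj(radii, fr = fr)
  ev <- wall_arrival_events(tr, default_arena)
  expect_true(ev$censored)
  sc <- wall_stay_curve(list(tr), default_arena)
  i10 <- which.min(abs(sc$t_s - 10))
  expect_equal(sc$n_events[i10], 0L)
  expect_true(is.na(sc$p_stay[i10]))
})

test_that("stay-curve group comparison flags a clear difference", {
  fast <- stay_time_cohort(withr::with_seed(1, rexp(150, 1)),
                           default_arena)
  slow <- stay_time_cohort(withr::with_seed(2, rexp(150, 0.05)),
                           default_arena)
  cmp <- compare_stay_curves(wall_stay_curve(fast, default_arena),
                             wall_stay_curve(slow, default_arena))
  i5 <- which.min(abs(cmp$t_s - 5))
  expect_lt(cmp$p_value[i5], 0.001)
  same <- compare_stay_curves(wall_stay_curve(fast, default_arena),
                              wall_stay_curve(fast, default_arena))
  expect_gt(same$p_value[i5], 0.99)
})

test_that("crossing analysis reproduces a radial outward swim", {
  fr <- 10
  # start inside, cross the 4.5 mm circle, move outward at 1 mm/s
  radii <- c(seq(4.0, 4.45, by = 0.1), seq(4.5, 7.4, by = 0.1),
             rep(7.4, 200))
  tr <- radial_traj(radii, fr = fr)
  cm <- crossing_trajectories(tr, default_arena)
  expect_equal(cm$n_crossings, 1L)
  # reaches < 0.5 mm from the wall when r > 7.0, i.e. 26 frames = 2.6 s
  # after the crossing
  reach_t <- cm$p_reach$t_s[which(cm$p_reach$p_reach_wall >= 1)[1]]
  expect_equal(reach_t, 2.6, tolerance = 0.11)
  # each populated time slice normalizes to 1
  rs <- rowSums(cm$map)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-9))
  # immediate return: crossing counted, wall never reached
  back <- radial_traj(c(4.4, 4.6, 4.4, rep(4.0, 100)), fr = fr)
  cm2 <- crossing_trajectories(back, default_arena)
  expect_true(all(cm2$p_reach$p_reach_wall == 0, na.rm = TRUE))
  expect_error(crossing_trajectories(make_traj(rep(0, 10), rep(0, 10)),
                                     default_arena),
               "crossings")
})

test_that("center-to-wall paths obey geometry and the triangle inequality", {
  # larva that never enters the center disc
  outer <- make_traj(rep(5, 50), rep(0, 50))
  expect_equal(nrow(center_to_wall_paths(outer, default_arena)), 0L)
  # paths from simulated swimming satisfy path >= straight
  tr <- generate_trajectory(swim_params(duration = 300, seed = 77,
                                        wall_affinity = 1), default_arena)
  paths <- center_to_wall_paths(tr, default_arena)
  expect_gt(nrow(paths), 0)
  expect_true(all(paths$path_mm >= paths$straight_mm - 1e-9))
})

test_that("path extraction is invariant to rotation about the center", {
  tr <- generate_trajectory(swim_params(duration = 120, seed = 5),
                            default_arena)
  th <- 1.1
  rot <- trajectory(cos(th) * tr$x_mm - sin(th) * tr$y_mm,
                    sin(th) * tr$x_mm + cos(th) * tr$y_mm,
                    frame_rate = frame_rate(tr))
  p1 <- center_to_wall_paths(tr, default_arena)
  p2 <- center_to_wall_paths(rot, default_arena)
  expect_equal(p1$start_frame, p2$start_frame)
  expect_equal(p1$path_mm, p2$path_mm, tolerance = 1e-9)
  # occupancy is rotation-invariant too
  expect_equal(zone_occupancy(tr, default_arena)$pct_outer,
               zone_occupancy(rot, default_arena)$pct_outer)
})
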