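static_stack <- function(n = 5, x = 2, y = -1, noise = 0, seed = 1) {
  tr <- make_traj(rep(x, n), rep(y, n))
  render_frames(tr, default_arena, image_size = 64, blob_sigma = 1.5,
                noise_sd = noise, seed = seed)
}

test_that("static noiseless trajectory renders identical frames", {
  fs <- static_stack()
  expect_length(fs$frames, 5)
  for (f in fs$frames) expect_identical(f, fs$frames[[1]])
  expect_true(all(fs$frames[[1]] >= 0 & fs$frames[[1]] <= 1))
})

test_that("blob at the well center is tracked to the image center", {
  fs <- static_stack(x = 0, y = 0)
  bg <- matrix(fs$frames[[1]][1, 1], nrow(fs$frames[[1]]),
               ncol(fs$frames[[1]]))
  pos <- detect_centroid(fs$frames[[1]], bg)
  ctr <- (64 + 1) / 2
  expect_lt(abs(pos[1] - ctr), 0.1)
  expect_lt(abs(pos[2] - ctr), 0.1)
})

test_that("frame equal to background yields a missing detection", {
  bg <- matrix(0.8, 32, 32)
  expect_true(all(is.na(detect_centroid(bg, bg))))
  expect_error(detect_centroid(matrix(0, 16, 16), bg), "shape")
})

test_that("largest connected component wins", {
  bg <- matrix(0.8, 48, 48)
  fr <- bg
  fr[10:16, 10:16] <- 0.2   # 49 px blob
  fr[30:33, 30:34] <- 0.2   # 20 px blob
  pos <- detect_centroid(fr, bg)
  expect_equal(unname(pos[1]), 13, tolerance = 1e-6)
  expect_equal(unname(pos[2]), 13, tolerance = 1e-6)
})

test_that("median background recovers the true background", {
  p <- swim_params(duration = 2, frame_rate = 30, seed = 6)
  tr <- generate_trajectory(p, default_arena)
  fs <- render_frames(tr, default_arena, image_size = 64, noise_sd = 0)
  bg <- estimate_background(fs$frames)
  expect_lt(max(abs(bg - fs$frames[[1]][1, 1])), 1 / 255)
  # single frame: background is that frame
  expect_identical(estimate_background(fs$frames[1]), fs$frames[[1]])
  expect_error(estimate_background(list()), "frame")
})

test_that("render -> track round trip recovers positions within 0.5 px", {
  p <- swim_params(duration = 100 / 30, frame_rate = 30, seed = 8)
  tr <- generate_trajectory(p, default_arena)
  fs <- render_frames(tr, default_arena, image_size = 96, blob_sigma = 1.5,
                      noise_sd = 0)
  tt <- track(fs)
  tol_mm <- 0.5 * fs$meta$mm_per_px
  err <- sqrt((tt$x_mm - tr$x_mm)^2 + (tt$y_mm - tr$y_mm)^2)
  expect_equal(nrow(tt), 100)
  expect_lt(sqrt(mean(err^2)), tol_mm)
  expect_true(all(err < 2 * tol_mm))
  expect_true(all(traj_radius(tt) <= default_arena$well_radius * 1.02))
})

test_that("short detection gaps are interpolated, long gaps flagged", {
  tr <- make_traj(seq(-3, 3, length.out = 40), rep(0, 40))
  fs <- render_frames(tr, default_arena, image_size = 64, noise_sd = 0)
  bg_val <- fs$frames[[1]][1, 1]
  blank <- matrix(bg_val, 64, 64)
  fs$frames[[10]] <- blank
  fs$frames[[11]] <- blank
  tt <- track(fs, tracking_config(max_gap_fill = 3))
  expect_true(all(tt$flags[10:11] == "interpolated"))
  expect_equal(tt$x_mm[10],
               tt$x_mm[9] + (tt$x_mm[12] - tt$x_mm[9]) / 3,
               tolerance = 0.05)
  for (i in 20:29) fs$frames[[i]] <- blank
  tt2 <- track(fs, tracking_config(max_gap_fill = 3))
  expect_true(all(tt2$flags[20:29] == "missing"))
  expect_true(all(is.na(tt2$x_mm[20:29])))
})

test_that("mostly-empty stacks are a hard error", {
  tr <- make_traj(rep(1, 10), rep(1, 10))
  fs <- render_frames(tr, default_arena, image_size = 64, noise_sd = 0)
  blank <- matrix(fs$frames[[1]][1, 1], 64, 64)
  for (i in 1:6) fs$frames[[i]] <- blank
  expect_error(track(fs, tracking_config(max_gap_fill = 0)), "unusable")
})

test_that("frame stacks round-trip through PNG + JSON sidecar", {
  fs <- static_stack(n = 3)
  dir <- file.path(tempdir(), "stack_rt")
  write_frame_stack(fs, dir)
  expect_true(file.exists(file.path(dir, "stack.json")))
  back <- read_frame_stack(dir)
  expect_equal(back$meta$mm_per_px, fs$meta$mm_per_px, tolerance = 1e-9)
  expect_length(back$frames, 3)
  # PNG round trip is exact up to 8-bit quantization
  expect_lt(max(abs(back$frames[[2]] - fs$frames[[2]])), 1 / 255 + 1e-9)
  unlink(dir, recursive = TRUE)
})

test_that("blobs outside the image are rejected at render time", {
  tr <- make_traj(20, 0)
  expect_error(render_frames(tr, default_arena, image_size = 64),
               "outside")
})
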