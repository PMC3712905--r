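#' Render a trajectory as a synthetic grayscale frame stack
#'
#' Produces one frame per trajectory sample: a dark Gaussian blob (the larva,
#' as seen under transmitted light) on a bright uniform well background, with
#' optional Gaussian pixel noise. The mm-to-pixel mapping is stored in the
#' stack metadata so the tracker can map centroids back to well-centered mm
#' coordinates. Pixel convention: matrix rows run top to bottom (y down),
#' columns left to right (x right); `y_mm` increases upward.
#'
#' @param traj A `trajectory`.
#' @param arena An `arena_geometry`.
#' @param image_size Image side length in pixels (square frames).
#' @param blob_sigma Gaussian blob standard deviation, px.
#' @param noise_sd Gaussian pixel noise standard deviation (intensity units,
#'   full scale = 1).
#' @param mm_per_px Scale; default fits the well with a 2-px margin.
#' @param bg_level Background intensity in [0, 1].
#' @param blob_amplitude Blob darkness (subtracted at its peak).
#' @param seed Integer seed for the pixel noise.
#' @return An object of class `frame_stack`: list with `frames` (list of
#'   numeric matrices in [0, 1]) and `meta` (list with `frame_rate_hz`,
#'   `mm_per_px`, `well_center_px` = c(x, y), `well_radius_px`).
#' @export
render_frames <- function(traj, arena, image_size = 96, blob_sigma = 1.5,
                          noise_sd = 0, mm_per_px = NULL,
                          bg_level = 0.85, blob_amplitude = 0.6, seed = 1L) {
  stop_if(!inherits(traj, "trajectory"), "`traj` must be a trajectory")
  stop_if(!inherits(arena, "arena_geometry"), "`arena` must be arena_geometry")
  check_number(image_size, "image_size", lower = 8)
  check_number(blob_sigma, "blob_sigma", lower = 1e-3)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (is.null(mm_per_px))
    mm_per_px <- 2 * arena$well_radius / (image_size - 4)
  stop_if(2 * arena$well_radius / mm_per_px > image_size,
          "image_size does not cover the arena at this mm_per_px")
  ctr <- (image_size + 1) / 2
  col_c <- ctr + traj$x_mm / mm_per_px
  row_c <- ctr - traj$y_mm / mm_per_px
  ok <- !is.na(col_c)
  stop_if(any(col_c[ok] < 1 | col_c[ok] > image_size |
              row_c[ok] < 1 | row_c[ok] > image_size),
          "blob falls outside the image")
  half <- ceiling(4 * blob_sigma)
  n <- nrow(traj)
  frames <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      f <- matrix(bg_level, image_size, image_size)
      if (ok[i]) {
        rc <- row_c[i]; cc <- col_c[i]
        rs <- max(1L, floor(rc - half)):min(image_size, ceiling(rc + half))
        cs <- max(1L, floor(cc - half)):min(image_size, ceiling(cc + half))
        g <- exp(-(outer((rs - rc)^2, (cs - cc)^2, "+")) /
                   (2 * blob_sigma^2))
        f[rs, cs] <- f[rs, cs] - blob_amplitude * g
      }
      if (noise_sd > 0)
        f <- f + matrix(stats::rnorm(image_size^2, 0, noise_sd),
                        image_size, image_size)
      pmin(pmax(f, 0), 1)
    })
  })
  structure(list(frames = frames,
                 meta = list(frame_rate_hz = frame_rate(traj),
                             mm_per_px = mm_per_px,
                             well_center_px = c(ctr, ctr),
                             well_radius_px = arena$well_radius / mm_per_px)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Frame stack: %d frames of %dx%d px at %g Hz, %.4f mm/px\n",
              length(x$frames), d[1], d[2], x$meta$frame_rate_hz,
              x$meta$mm_per_px))
  invisible(x)
}

#' Write and read frame stacks on disk
#'
#' A stack directory holds zero-padded numbered PNG files
#' (`frame_000001.png`, ...) plus a `stack.json` sidecar with the metadata
#' fields `frame_rate_hz`, `mm_per_px`, `well_center_px`, `well_radius_px`.
#' The sidecar can be hand-written for real recordings.
#'
#' @param stack A `frame_stack`.
#' @param dir Directory path (created if needed).
#' @return `read_frame_stack()` returns a `frame_stack`;
#'   `write_frame_stack()` returns `dir` invisibly.
#' @export
write_frame_stack <- function(stack, dir) {
  stop_if(!inherits(stack, "frame_stack"), "`stack` must be a frame_stack")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(stack$frames))
    png::writePNG(stack$frames[[i]],
                  file.path(dir, sprintf("frame_%06d.png", i)))
  jsonlite::write_json(stack$meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(dir) {
  sidecar <- file.path(dir, "stack.json")
  stop_if(!file.exists(sidecar), "missing stack.json sidecar in ", dir)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("frame_rate_hz", "mm_per_px", "well_center_px", "well_radius_px")
  stop_if(!all(need %in% names(meta)),
          "sidecar must define frame_rate_hz, mm_per_px, well_center_px, ",
          "well_radius_px")
  files <- sort(list.files(dir, pattern = "\\.(png|PNG)$", full.names = TRUE))
  stop_if(length(files) == 0L, "no PNG frames found in ", dir)
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  })
  structure(list(frames = frames, meta = meta), class = "frame_stack")
}
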