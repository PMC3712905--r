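#' Centroid-tracking configuration
#'
#' @param background_method How to build the static background:
#'   `"median_stack"` (per-pixel median of a frame subsample, default),
#'   `"first_frame"`, or `"provided"` (pass your own image to [track()]).
#' @param threshold_sd Detection threshold as a multiple of the robust
#'   spread (1.4826 x MAD) of the background-subtracted frame. Blob pixels
#'   are outliers of that difference image by construction.
#' @param min_blob_area Minimum connected-component area in px^2.
#' @param max_gap_fill Maximum run of detection gaps (frames) filled by
#'   linear interpolation; longer gaps are flagged missing.
#' @param polarity `"dark"` for a dark larva on a bright transmitted-light
#'   background (default), `"bright"` for the inverse.
#' @return An object of class `tracking_config`.
#' @export
tracking_config <- function(background_method = c("median_stack",
                                                  "first_frame", "provided"),
                            threshold_sd = 6, min_blob_area = 3,
                            max_gap_fill = 3,
                            polarity = c("dark", "bright")) {
  background_method <- match.arg(background_method)
  polarity <- match.arg(polarity)
  check_number(threshold_sd, "threshold_sd", lower = 1e-9)
  check_number(min_blob_area, "min_blob_area", lower = 1)
  check_number(max_gap_fill, "max_gap_fill", lower = 0)
  structure(list(background_method = background_method,
                 threshold_sd = threshold_sd,
                 min_blob_area = as.integer(min_blob_area),
                 max_gap_fill = as.integer(max_gap_fill),
                 polarity = polarity),
            class = "tracking_config")
}

#' Estimate the static background of a frame stack
#'
#' Per-pixel median across a uniform subsample of at most `max_frames`
#' frames. The median is robust as long as the larva occupies any given
#' pixel in fewer than half of the sampled frames.
#'
#' @param frames A `frame_stack` or list of numeric matrices.
#' @param max_frames Maximum number of frames entering the median.
#' @return A numeric matrix.
#' @export
estimate_background <- function(frames, max_frames = 200L) {
  if (inherits(frames, "frame_stack")) frames <- frames$frames
  stop_if(length(frames) == 0L, "empty frame stack")
  if (length(frames) == 1L) return(frames[[1]])
  idx <- unique(round(seq(1, length(frames),
                          length.out = min(max_frames, length(frames)))))
  arr <- simplify2array(frames[idx])
  apply(arr, c(1, 2), stats::median)
}

#' Detect the larva centroid in a single frame
#'
#' Thresholds the background-subtracted frame at `threshold_sd` times the
#' robust spread (1.4826 x MAD), keeps connected components of at least
#' `min_blob_area` px inside the well mask, and returns the
#' intensity-weighted centroid of the largest component.
#'
#' @param frame,background Numeric matrices of identical shape.
#' @param config A `tracking_config`.
#' @param well_mask Optional logical matrix restricting detection to the
#'   well interior.
#' @return Numeric `c(x_px, y_px)` (column, row; 1-based, continuous) or
#'   `NULL` if no blob is found.
#' @export
detect_centroid <- function(frame, background, config = tracking_config(),
                            well_mask = NULL) {
  stop_if(!identical(dim(frame), dim(background)),
          "frame and background shapes differ")
  diffimg <- if (config$polarity == "dark") background - frame
             else frame - background
  spread <- stats::mad(diffimg, center = 0)
  thr <- config$threshold_sd * max(spread, 1e-6)
  mask <- diffimg > thr
  if (!is.null(well_mask)) mask <- mask & well_mask
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  if (sizes[big] < config$min_blob_area) return(NULL)
  sel <- lab == big
  w <- diffimg[sel]
  rows <- row(frame)[sel]; cols <- col(frame)[sel]
  c(x_px = sum(cols * w) / sum(w), y_px = sum(rows * w) / sum(w))
}

#' Track a single larva through a frame stack
#'
#' Runs background estimation and per-frame centroid detection, maps pixel
#' centroids into well-centered mm coordinates using the stack metadata,
#' linearly interpolates detection gaps up to `max_gap_fill` frames
#' (flagged `"interpolated"`), and flags longer gaps `"missing"`.
#'
#' @param stack A `frame_stack` (in memory or from [read_frame_stack()]).
#' @param config A `tracking_config`.
#' @param background Background image when
#'   `config$background_method == "provided"`.
#' @return A `trajectory` (flags column distinguishes ok / interpolated /
#'   missing samples).
#' @export
track <- function(stack, config = tracking_config(), background = NULL) {
  stop_if(!inherits(stack, "frame_stack"), "`stack` must be a frame_stack")
  meta <- stack$meta
  frames <- stack$frames
  n <- length(frames)
  stop_if(n == 0L, "empty frame stack")
  bg <- switch(config$background_method,
    median_stack = estimate_background(frames),
    first_frame = frames[[1]],
    provided = {
      stop_if(is.null(background),
              "background_method 'provided' requires `background`")
      background
    })
  d <- dim(frames[[1]])
  cx <- meta$well_center_px[1]; cy <- meta$well_center_px[2]
  well_mask <- (col(frames[[1]]) - cx)^2 + (row(frames[[1]]) - cy)^2 <=
    (meta$well_radius_px * 1.02)^2
  xs <- rep(NA_real_, n); ys <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- detect_centroid(frames[[i]], bg, config, well_mask)
    if (!is.null(p)) {
      xs[i] <- (p[["x_px"]] - cx) * meta$mm_per_px
      ys[i] <- (cy - p[["y_px"]]) * meta$mm_per_px
    }
  }
  miss <- is.na(xs)
  stop_if(mean(miss) > 0.5,
          "unusable recording: more than 50% of frames without detection")
  flags <- ifelse(miss, "missing", "ok")
  if (any(miss)) {
    runs <- logical_runs(miss)
    runs <- runs[runs$value, , drop = FALSE]
    for (ri in seq_len(nrow(runs))) {
      s <- runs$start[ri] + 1L; e <- runs$end[ri]  # 1-based inclusive
      len <- e - s + 1L
      interior <- s > 1L && e < n
      if (len <= config$max_gap_fill && interior) {
        xs[s:e] <- xs[s - 1L] + (xs[e + 1L] - xs[s - 1L]) *
          seq_len(len) / (len + 1)
        ys[s:e] <- ys[s - 1L] + (ys[e + 1L] - ys[s - 1L]) *
          seq_len(len) / (len + 1)
        flags[s:e] <- "interpolated"
      }
    }
  }
  trajectory(xs, ys, meta$frame_rate_hz, flags = flags)
}
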