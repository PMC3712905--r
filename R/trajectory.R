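#' Trajectory container
#'
#' A trajectory is a data.frame with columns `frame` (0-based), `time_s`,
#' `x_mm`, `y_mm` (well-centered coordinates, x rightward, y upward) and
#' `flags` (`"ok"`, `"interpolated"` or `"missing"`), sampled uniformly at
#' `frame_rate` Hz. Missing samples have `NA` coordinates.
#'
#' @param x_mm,y_mm Numeric position vectors (mm, well-centered).
#' @param frame_rate Sampling rate in Hz.
#' @param flags Optional character vector of per-sample quality flags.
#' @return An object of classes `trajectory` and `data.frame`.
#' @export
trajectory <- function(x_mm, y_mm, frame_rate, flags = NULL) {
  check_number(frame_rate, "frame_rate", lower = 1e-9)
  n <- length(x_mm)
  stop_if(length(y_mm) != n, "x_mm and y_mm must have equal length")
  stop_if(n < 1L, "trajectory needs at least one sample")
  if (is.null(flags)) flags <- ifelse(is.na(x_mm) | is.na(y_mm),
                                      "missing", "ok")
  stop_if(length(flags) != n, "flags must match position length")
  stop_if(!all(flags %in% c("ok", "interpolated", "missing")),
          "flags must be ok|interpolated|missing")
  df <- data.frame(frame = seq_len(n) - 1L,
                   time_s = (seq_len(n) - 1L) / frame_rate,
                   x_mm = as.numeric(x_mm), y_mm = as.numeric(y_mm),
                   flags = flags, stringsAsFactors = FALSE)
  attr(df, "frame_rate") <- frame_rate
  class(df) <- c("trajectory", "data.frame")
  df
}

#' @export
print.trajectory <- function(x, ...) {
  fr <- attr(x, "frame_rate")
  cat(sprintf("Trajectory: %d frames at %g Hz (%.1f s), %d missing\n",
              nrow(x), fr, nrow(x) / fr, sum(x$flags == "missing")))
  invisible(x)
}

#' @rdname trajectory
#' @param traj A `trajectory` object.
#' @export
frame_rate <- function(traj) {
  fr <- attr(traj, "frame_rate")
  stop_if(is.null(fr), "object carries no frame_rate attribute")
  fr
}

#' Radial distance of each sample from the well center
#'
#' @param traj A `trajectory`.
#' @return Numeric vector of radii, mm (`NA` for missing samples).
#' @export
traj_radius <- function(traj) sqrt(traj$x_mm^2 + traj$y_mm^2)

#' Read and write trajectory CSV files
#'
#' The on-disk format has header `frame,time_s,x_mm,y_mm` (plus an optional
#' `flags` column), 0-based frames, well-centered mm coordinates.
#'
#' @param traj A `trajectory`.
#' @param path File path.
#' @return `read_trajectory_csv()` returns a `trajectory`;
#'   `write_trajectory_csv()` returns `path` invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stop_if(!inherits(traj, "trajectory"), "`traj` must be a trajectory")
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param frame_rate Sampling rate in Hz; if `NULL`, inferred from the
#'   `time_s` column spacing.
#' @export
read_trajectory_csv <- function(path, frame_rate = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time_s", "x_mm", "y_mm")
  stop_if(!all(need %in% names(df)),
          "trajectory CSV must have columns frame,time_s,x_mm,y_mm")
  if (is.null(frame_rate)) {
    dt <- diff(df$time_s)
    stop_if(length(dt) < 1L || any(abs(dt - dt[1]) > 1e-6),
            "cannot infer frame rate: time steps not uniform")
    frame_rate <- 1 / dt[1]
  }
  trajectory(df$x_mm, df$y_mm, frame_rate,
             flags = if ("flags" %in% names(df)) df$flags else NULL)
}
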