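#' Segment a displacement sequence into active bouts and rests
#'
#' Core segmentation rule, operating directly on a per-frame displacement
#' vector (mm/frame): frames whose displacement exceeds `movement_threshold`
#' are movement; movement runs separated by at most `merge_gap` rest frames
#' are merged; active runs shorter than `min_bout` frames are reclassified as
#' rest. The result strictly alternates active and rest intervals and
#' partitions `[0, n)` (half-open, 0-based frames).
#'
#' @param disp Per-frame displacements, mm/frame (`NA` allowed; `NA` frames
#'   never count as movement).
#' @param movement_threshold Displacement threshold, mm/frame.
#' @param min_bout Minimum bout length, frames.
#' @param merge_gap Maximum within-bout gap to merge, frames.
#' @return An object of class `activity_segmentation`: data.frame with
#'   columns `start`, `end` (half-open), `label` (`"active"`/`"rest"`), plus
#'   attribute `threshold_used`.
#' @examples
#' d <- c(0, 0, .3, .3, 0, .3, .3, .3, 0, 0, 0, 0)
#' segment_displacements(d, 0.1, min_bout = 2, merge_gap = 1)
#' @export
segment_displacements <- function(disp, movement_threshold = 0.1,
                                  min_bout = 2L, merge_gap = 2L) {
  check_number(movement_threshold, "movement_threshold", lower = 0)
  check_number(min_bout, "min_bout", lower = 0)
  check_number(merge_gap, "merge_gap", lower = 0)
  n <- length(disp)
  stop_if(n < 2L, "need at least 2 frames to segment")
  stop_if(all(is.na(disp)), "all samples missing")
  moving <- !is.na(disp) & disp > movement_threshold

  # merge movement runs separated by short gaps
  if (merge_gap > 0 && any(moving) && any(!moving)) {
    runs <- logical_runs(moving)
    for (i in seq_len(nrow(runs))) {
      if (!runs$value[i] && i > 1L && i < nrow(runs) &&
          (runs$end[i] - runs$start[i]) <= merge_gap)
        moving[(runs$start[i] + 1L):runs$end[i]] <- TRUE
    }
  }
  # drop active runs below the minimum bout length
  if (min_bout > 1 && any(moving)) {
    runs <- logical_runs(moving)
    for (i in seq_len(nrow(runs))) {
      if (runs$value[i] && (runs$end[i] - runs$start[i]) < min_bout)
        moving[(runs$start[i] + 1L):runs$end[i]] <- FALSE
    }
  }
  runs <- logical_runs(moving)
  seg <- data.frame(start = runs$start, end = runs$end,
                    label = ifelse(runs$value, "active", "rest"),
                    stringsAsFactors = FALSE)
  attr(seg, "threshold_used") <- movement_threshold
  attr(seg, "n_frames") <- n
  class(seg) <- c("activity_segmentation", "data.frame")
  seg
}

#' Segment a trajectory into active bouts and rests
#'
#' Computes per-frame displacements (frame i holds the step from frame i-1;
#' the first frame inherits the second frame's displacement so that a
#' continuously moving trajectory is 100% active) and applies
#' [segment_displacements()]. Displacements touching missing samples are
#' `NA` and never count as movement.
#'
#' @param traj A `trajectory`.
#' @inheritParams segment_displacements
#' @return An `activity_segmentation`.
#' @export
segment_activity <- function(traj, movement_threshold = 0.1,
                             min_bout = 2L, merge_gap = 2L) {
  stop_if(!inherits(traj, "trajectory"), "`traj` must be a trajectory")
  stop_if(nrow(traj) < 2L, "trajectory has fewer than 2 samples")
  stop_if(all(traj$flags == "missing"), "all samples missing")
  d <- c(NA_real_, sqrt(diff(traj$x_mm)^2 + diff(traj$y_mm)^2))
  d[1] <- d[2]
  d[traj$flags == "missing"] <- NA_real_
  seg <- segment_displacements(d, movement_threshold, min_bout, merge_gap)
  attr(seg, "frame_rate") <- frame_rate(traj)
  seg
}

seg_durations <- function(seg, label, frame_rate) {
  sel <- seg$label == label
  (seg$end[sel] - seg$start[sel]) / frame_rate
}

#' Summarize kinematics of a segmented trajectory
#'
#' Activity fraction (percent of frames in active intervals), mean bout
#' velocity (mean over active frames of displacement times frame rate), and
#' power-law fits of the rest and bout duration distributions.
#'
#' @param traj A `trajectory`.
#' @param seg An `activity_segmentation` for `traj` (default: computed with
#'   standard thresholds).
#' @param fit_method Estimator for [fit_power_law()].
#' @param min_intervals Minimum interval count required before a duration
#'   law is fitted; fewer yields an `NULL` fit.
#' @return An object of class `kinematics_summary`: list with
#'   `activity_fraction` (percent), `mean_bout_velocity` (mm/s; `NA` when no
#'   active frames), `rest_fit`, `bout_fit` (`power_law_fit` or `NULL`),
#'   `n_bouts`, `n_rests`.
#' @export
summarize_kinematics <- function(traj, seg = segment_activity(traj),
                                 fit_method = c("loglog_regression",
                                                "discrete_mle"),
                                 min_intervals = 10L) {
  stop_if(!inherits(traj, "trajectory"), "`traj` must be a trajectory")
  stop_if(!inherits(seg, "activity_segmentation"),
          "`seg` must be an activity_segmentation")
  stop_if(attr(seg, "n_frames") != nrow(traj),
          "segmentation does not match this trajectory")
  fit_method <- match.arg(fit_method)
  fr <- frame_rate(traj)
  n <- nrow(traj)
  active <- logical(n)
  for (i in which(seg$label == "active"))
    active[(seg$start[i] + 1L):seg$end[i]] <- TRUE
  activity_fraction <- 100 * sum(active) / n

  d <- c(NA_real_, sqrt(diff(traj$x_mm)^2 + diff(traj$y_mm)^2))
  d[1] <- d[2]
  d[traj$flags == "missing"] <- NA_real_
  mean_bout_velocity <- if (any(active) && any(!is.na(d[active])))
    mean(d[active], na.rm = TRUE) * fr else NA_real_

  rests <- seg_durations(seg, "rest", fr)
  bouts <- seg_durations(seg, "active", fr)
  tryfit <- function(x) {
    if (length(x) < min_intervals) return(NULL)
    tryCatch(fit_power_law(x, method = fit_method, frame_rate = fr,
                           x_max = n),
             error = function(e) NULL)
  }
  structure(list(activity_fraction = activity_fraction,
                 mean_bout_velocity = mean_bout_velocity,
                 rest_fit = tryfit(rests), bout_fit = tryfit(bouts),
                 n_bouts = length(bouts), n_rests = length(rests)),
            class = "kinematics_summary")
}

#' @export
print.kinematics_summary <- function(x, ...) {
  cat(sprintf("Activity: %.1f%% of frames; mean bout velocity: %s mm/s\n",
              x$activity_fraction,
              if (is.na(x$mean_bout_velocity)) "NA"
              else sprintf("%.2f", x$mean_bout_velocity)))
  cat(sprintf("  %d bouts, %d rests; k_bout = %s, k_rest = %s\n",
              x$n_bouts, x$n_rests,
              if (is.null(x$bout_fit)) "NA" else sprintf("%.3f", x$bout_fit$k),
              if (is.null(x$rest_fit)) "NA" else sprintf("%.3f",
                                                         x$rest_fit$k)))
  invisible(x)
}

#' Per-larva kinematics summary table for a set of trajectories
#'
#' @param trajs Named list of `trajectory` objects (names become larva ids).
#' @param ... Passed to [segment_activity()].
#' @param fit_method Estimator for the duration-law fits.
#' @return data.frame with one row per larva: `larva_id`, `activity_pct`,
#'   `mean_bout_velocity_mms`, `k_rest`, `k_bout`, `n_bouts`, `n_rests`,
#'   `gof_rest`, `gof_bout`. Larvae with fewer than 10 intervals get `NA`
#'   fits.
#' @export
analyze_kinematics <- function(trajs, ...,
                               fit_method = c("loglog_regression",
                                              "discrete_mle")) {
  fit_method <- match.arg(fit_method)
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  ids <- names(trajs)
  if (is.null(ids)) ids <- sprintf("larva_%02d", seq_along(trajs))
  rows <- lapply(seq_along(trajs), function(i) {
    s <- summarize_kinematics(trajs[[i]],
                              segment_activity(trajs[[i]], ...),
                              fit_method = fit_method)
    data.frame(larva_id = ids[i],
               activity_pct = s$activity_fraction,
               mean_bout_velocity_mms = s$mean_bout_velocity,
               k_rest = if (is.null(s$rest_fit)) NA_real_ else s$rest_fit$k,
               k_bout = if (is.null(s$bout_fit)) NA_real_ else s$bout_fit$k,
               n_bouts = s$n_bouts, n_rests = s$n_rests,
               gof_rest = if (is.null(s$rest_fit)) NA_real_
                          else s$rest_fit$gof,
               gof_bout = if (is.null(s$bout_fit)) NA_real_
                          else s$bout_fit$gof,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
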