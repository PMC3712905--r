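#' Group contraction times into coiling events
#'
#' Successive trunk contractions separated by less than `gap_threshold`
#' seconds belong to a single spontaneous motor event; the event onset is
#' the first contraction time.
#'
#' @param contraction_times Sorted contraction times, s.
#' @param gap_threshold Grouping gap, s (default 1).
#' @param duration Recording duration, s.
#' @return A `coiling_series`.
#' @examples
#' s <- group_contractions(c(1.0, 1.2, 10, 20), gap_threshold = 0.5,
#'                         duration = 300)
#' s$events$n_contractions  # 2 1 1
#' @export
group_contractions <- function(contraction_times, gap_threshold = 1.0,
                               duration) {
  check_number(gap_threshold, "gap_threshold", lower = 0)
  check_number(duration, "duration", lower = 1e-9)
  if (length(contraction_times) == 0L)
    return(coiling_series(numeric(0), integer(0), duration))
  stop_if(is.unsorted(contraction_times),
          "contraction times must be sorted")
  stop_if(any(contraction_times < 0 | contraction_times > duration),
          "contraction times must lie within [0, duration]")
  gaps <- diff(contraction_times)
  new_event <- c(TRUE, gaps >= gap_threshold)
  grp <- cumsum(new_event)
  onsets <- tapply(contraction_times, grp, min)
  counts <- tabulate(grp)
  coiling_series(as.numeric(onsets), counts, duration)
}

#' Summarize a coiling-event series
#'
#' @param series A `coiling_series`.
#' @return List of class `coiling_summary` with `events_per_min`,
#'   `pct_multi` (percent of events with more than one contraction; `NA`
#'   when there are no events), and `has_any_multi`.
#' @export
summarize_coiling <- function(series) {
  stop_if(!inherits(series, "coiling_series"),
          "`series` must be a coiling_series")
  n <- nrow(series$events)
  multi <- sum(series$events$n_contractions > 1L)
  structure(list(events_per_min = n / (series$duration / 60),
                 pct_multi = if (n > 0) 100 * multi / n else NA_real_,
                 has_any_multi = multi > 0, n_events = n),
            class = "coiling_summary")
}

#' @export
print.coiling_summary <- function(x, ...) {
  cat(sprintf("Coiling: %.2f events/min; %s%% multi-contraction events\n",
              x$events_per_min,
              if (is.na(x$pct_multi)) "NA" else sprintf("%.2f", x$pct_multi)))
  invisible(x)
}

#' Measure C-bend (coiling) durations from a curvature trace
#'
#' An event is detected at the first sample whose absolute deviation from
#' baseline exceeds `deviation_threshold`; its onset is then backtracked to
#' the first sample of the excursion out of the rest band (the sample after
#' the last one within `return_tolerance`), and it ends at the first
#' subsequent sample whose deviation has returned within
#' `return_tolerance` — the period between the first deviation of the trunk
#' from rest and its return to the initial position, with detection and
#' onset deliberately decoupled so that the measured duration does not
#' shrink with the detection threshold. Events still deviated at the end of the trace
#' are flagged incomplete and excluded from duration statistics. When
#' stimulus times are supplied, only the first complete event after each
#' stimulus is reported (later contractions of a multi-contraction response
#' are ignored).
#'
#' Measurements are invariant to the sign of the trace (left vs right
#' coils). Default thresholds are 3 (detection) and 1 (return) baseline
#' noise standard deviations, the noise SD being estimated robustly as the
#' MAD of the trace unless given.
#'
#' @param trace A `curvature_trace`, or numeric vector of curvature values.
#' @param deviation_threshold Onset threshold, curvature units (default
#'   `3 * baseline_sd`).
#' @param return_tolerance Return-to-rest tolerance, curvature units
#'   (default `1 * baseline_sd`); must be below `deviation_threshold`.
#' @param baseline Resting-state value (default: median of the trace).
#' @param baseline_sd Baseline noise SD (default: MAD of the trace; a small
#'   floor avoids a zero threshold on noiseless traces).
#' @param frame_rate Sampling rate, Hz (taken from the trace object when
#'   available).
#' @param stimulus_times Optional stimulus onset times, s.
#' @param smooth_window Odd moving-average window (frames) applied before
#'   thresholding (default 1 = no smoothing). Single-sample threshold
#'   crossings are noise-sensitive; a short window makes durations of short
#'   pulses stable under measurement noise without affecting noiseless
#'   traces.
#' @return data.frame of class `cbend_measures` with `onset_s`,
#'   `duration_ms`, `peak_amplitude`, `complete` (one row per event; with
#'   stimuli, one row per stimulus that evoked a response).
#' @export
measure_cbend <- function(trace, deviation_threshold = NULL,
                          return_tolerance = NULL, baseline = NULL,
                          baseline_sd = NULL, frame_rate = NULL,
                          stimulus_times = NULL, smooth_window = 1L) {
  if (inherits(trace, "curvature_trace")) {
    if (is.null(frame_rate)) frame_rate <- trace$frame_rate
    values <- trace$values
  } else {
    values <- as.numeric(trace)
  }
  stop_if(is.null(frame_rate), "`frame_rate` is required for plain vectors")
  check_number(frame_rate, "frame_rate", lower = 1e-9)
  check_number(smooth_window, "smooth_window", lower = 1)
  smooth_window <- as.integer(smooth_window)
  stop_if(smooth_window %% 2L == 0L, "`smooth_window` must be odd")
  stop_if(length(values) < 3L, "trace too short")
  if (smooth_window > 1L) {
    half <- smooth_window %/% 2L
    padded <- c(rep(values[1], half), values,
                rep(values[length(values)], half))
    values <- as.numeric(stats::filter(padded,
                                       rep(1 / smooth_window, smooth_window),
                                       sides = 2))[(half + 1L):
                                                   (half + length(values))]
  }
  if (is.null(baseline)) baseline <- stats::median(values)
  if (is.null(baseline_sd))
    baseline_sd <- max(stats::mad(values), 1e-9 + 1e-4 * max(abs(values -
                                                                   baseline)))
  if (is.null(deviation_threshold)) deviation_threshold <- 3 * baseline_sd
  if (is.null(return_tolerance)) return_tolerance <- 1 * baseline_sd
  stop_if(deviation_threshold <= return_tolerance,
          "`deviation_threshold` must exceed `return_tolerance`")

  dev <- abs(values - baseline)
  n <- length(dev)
  events <- list()
  i <- 1L
  while (i <= n) {
    if (dev[i] > deviation_threshold) {
      # backtrack to the start of the excursion out of the rest band
      inside <- which(dev[seq_len(i - 1L)] <= return_tolerance)
      i0 <- if (length(inside)) inside[length(inside)] + 1L else 1L
      rest <- if (i < n) which(dev[(i + 1L):n] <= return_tolerance)
              else integer(0)
      if (length(rest)) {
        j <- i + rest[1]
        events[[length(events) + 1L]] <- data.frame(
          onset_s = (i0 - 1L) / frame_rate,
          duration_ms = 1000 * (j - i0) / frame_rate,
          peak_amplitude = max(dev[i0:j]),
          complete = TRUE)
        i <- j + 1L
      } else {
        events[[length(events) + 1L]] <- data.frame(
          onset_s = (i0 - 1L) / frame_rate,
          duration_ms = NA_real_,
          peak_amplitude = max(dev[i0:n]),
          complete = FALSE)
        break
      }
    } else {
      i <- i + 1L
    }
  }
  out <- if (length(events)) do.call(rbind, events)
         else data.frame(onset_s = numeric(0), duration_ms = numeric(0),
                         peak_amplitude = numeric(0), complete = logical(0))
  if (!is.null(stimulus_times) && nrow(out)) {
    picked <- lapply(sort(stimulus_times), function(s) {
      cand <- out[out$onset_s >= s, , drop = FALSE]
      if (nrow(cand)) cand[1, , drop = FALSE] else NULL
    })
    out <- unique(do.call(rbind, picked))
  }
  class(out) <- c("cbend_measures", "data.frame")
  out
}
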