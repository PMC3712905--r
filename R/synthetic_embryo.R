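#' Parameters of the synthetic coiling-event generator
#'
#' Early zebrafish embryos produce spontaneous trunk contractions (coiling).
#' Events arrive as a homogeneous Poisson process; each event carries
#' 1 + Geometric(`p_extra_contraction`) contractions, so
#' `p_extra_contraction = 0` yields single-contraction events only.
#'
#' @param event_rate Events per minute (>= 0).
#' @param p_extra_contraction Probability in [0, 1) that an event gains each
#'   additional contraction.
#' @param duration Recording length, s (default 300: 5-min recordings).
#' @param frame_rate Sampling rate, Hz (default 20).
#' @param seed Integer seed.
#' @return An object of class `coiling_params`.
#' @export
coiling_params <- function(event_rate = 5, p_extra_contraction = 0,
                           duration = 300, frame_rate = 20, seed = 1L) {
  check_number(event_rate, "event_rate", lower = 0)
  check_number(p_extra_contraction, "p_extra_contraction", 0, 1 - 1e-12)
  check_number(duration, "duration", lower = 1e-9)
  check_number(frame_rate, "frame_rate", lower = 1e-9)
  check_number(seed, "seed")
  structure(list(event_rate = event_rate,
                 p_extra_contraction = p_extra_contraction,
                 duration = duration, frame_rate = frame_rate,
                 seed = as.integer(seed)),
            class = "coiling_params")
}

#' Coiling-event series container
#'
#' @param onsets Event onset times, s, strictly increasing, within duration.
#' @param n_contractions Integer count of contractions per event (>= 1).
#' @param duration Recording duration, s.
#' @return An object of class `coiling_series`.
#' @export
coiling_series <- function(onsets, n_contractions, duration) {
  check_number(duration, "duration", lower = 1e-9)
  stop_if(length(onsets) != length(n_contractions),
          "onsets and n_contractions must have equal length")
  if (length(onsets)) {
    stop_if(is.unsorted(onsets, strictly = TRUE),
            "event onsets must be strictly increasing")
    stop_if(any(onsets < 0 | onsets > duration),
            "event onsets must lie within [0, duration]")
    stop_if(any(n_contractions < 1), "n_contractions must be >= 1")
  }
  structure(list(duration = duration,
                 events = data.frame(onset = as.numeric(onsets),
                                     n_contractions =
                                       as.integer(n_contractions))),
            class = "coiling_series")
}

#' @export
print.coiling_series <- function(x, ...) {
  cat(sprintf("Coiling series: %d events over %g s\n",
              nrow(x$events), x$duration))
  invisible(x)
}

#' Generate a synthetic coiling-event series
#'
#' @param params A `coiling_params` object.
#' @return A `coiling_series`.
#' @export
generate_coiling_series <- function(params) {
  stop_if(!inherits(params, "coiling_params"),
          "`params` must be coiling_params")
  withr::with_seed(params$seed, {
    n <- stats::rpois(1, params$event_rate * params$duration / 60)
    onsets <- sort(stats::runif(n, 0, params$duration))
    # collapse numerically coincident onsets (theoretical measure zero)
    onsets <- unique(onsets)
    n <- length(onsets)
    extra <- if (params$p_extra_contraction > 0)
      stats::rgeom(n, 1 - params$p_extra_contraction) else integer(n)
    coiling_series(onsets, 1L + extra, params$duration)
  })
}

#' Specification of a synthetic body-curvature trace
#'
#' A curvature trace is a zero-baseline time series with half-sine deflection
#' pulses (the trunk bending away from and back to rest) plus Gaussian noise.
#'
#' @param duration Trace length, s.
#' @param pulse_onsets Pulse onset times, s.
#' @param pulse_durations Pulse durations, s (same length as onsets).
#' @param pulse_amplitude Peak deflection, arbitrary curvature units.
#' @param noise_sd Gaussian noise standard deviation, same units.
#' @param frame_rate Sampling rate, Hz (default 100).
#' @param seed Integer seed.
#' @return An object of class `curvature_spec`.
#' @export
curvature_spec <- function(duration, pulse_onsets = numeric(0),
                           pulse_durations = numeric(0),
                           pulse_amplitude = 1, noise_sd = 0,
                           frame_rate = 100, seed = 1L) {
  check_number(duration, "duration", lower = 1e-9)
  check_number(pulse_amplitude, "pulse_amplitude")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(frame_rate, "frame_rate", lower = 1e-9)
  check_number(seed, "seed")
  stop_if(length(pulse_onsets) != length(pulse_durations),
          "pulse_onsets and pulse_durations must have equal length")
  if (length(pulse_onsets)) {
    o <- order(pulse_onsets)
    on <- pulse_onsets[o]; du <- pulse_durations[o]
    stop_if(any(du <= 0), "pulse durations must be positive")
    stop_if(any(on < 0) || any(on + du > duration),
            "pulses must fit within the trace")
    if (length(on) > 1L)
      stop_if(any(on[-1] < (on + du)[-length(on)]),
              "pulses must not overlap")
    pulse_onsets <- on; pulse_durations <- du
  }
  structure(list(duration = duration, pulse_onsets = pulse_onsets,
                 pulse_durations = pulse_durations,
                 pulse_amplitude = pulse_amplitude, noise_sd = noise_sd,
                 frame_rate = frame_rate, seed = as.integer(seed)),
            class = "curvature_spec")
}

#' Generate a synthetic curvature trace
#'
#' @param spec A `curvature_spec` object.
#' @return An object of class `curvature_trace`: list with `frame_rate`,
#'   `time_s`, `values`, `baseline` (0).
#' @export
generate_curvature_trace <- function(spec) {
  stop_if(!inherits(spec, "curvature_spec"), "`spec` must be curvature_spec")
  withr::with_seed(spec$seed, {
    n <- as.integer(round(spec$duration * spec$frame_rate))
    t <- (seq_len(n) - 1L) / spec$frame_rate
    v <- numeric(n)
    for (i in seq_along(spec$pulse_onsets)) {
      o <- spec$pulse_onsets[i]; d <- spec$pulse_durations[i]
      in_p <- t >= o & t <= o + d
      v[in_p] <- v[in_p] + spec$pulse_amplitude * sin(pi * (t[in_p] - o) / d)
    }
    if (spec$noise_sd > 0) v <- v + stats::rnorm(n, 0, spec$noise_sd)
    structure(list(frame_rate = spec$frame_rate, time_s = t,
                   values = v, baseline = 0),
              class = "curvature_trace")
  })
}
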