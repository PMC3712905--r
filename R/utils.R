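# internal helpers shared across modules

stop_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_len = FALSE) {
  if (allow_zero_len && length(x) == 0L) return(invisible(x))
  stop_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
          sprintf("`%s` must be a single finite number", name))
  stop_if(x < lower || x > upper,
          sprintf("`%s` must be in [%g, %g], got %g", name, lower, upper, x))
  invisible(x)
}

# signed angular difference a - b wrapped to (-pi, pi]
ang_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

# run-length intervals of a logical vector: data.frame(start, end, value)
# with half-open [start, end) 0-based frame indexing
logical_runs <- function(x) {
  stopifnot(is.logical(x), length(x) >= 1L)
  r <- rle(x)
  end <- cumsum(r$lengths)
  start <- c(0L, end[-length(end)])
  data.frame(start = start, end = end, value = r$values)
}
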