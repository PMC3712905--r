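# shared fixtures for the test suite

default_arena <- arena_geometry()

# trajectory from explicit coordinates
make_traj <- function(x, y, fr = 30) trajectory(x, y, frame_rate = fr)

# trajectory moving radially at fixed angle through the given radii
radial_traj <- function(radii, fr = 30, angle = 0) {
  trajectory(radii * cos(angle), radii * sin(angle), frame_rate = fr)
}

# cohort of trajectories whose wall residence times are draws from a known
# leave-time sampler (seconds); each event is embedded in its own trajectory:
# approach from the well interior, sit just inside the reach band for the
# drawn time, then move back inside. `fr` low keeps these cheap.
stay_time_cohort <- function(stay_times_s, arena, fr = 10) {
  R <- arena$well_radius
  lapply(stay_times_s, function(ts) {
    n_stay <- max(1L, round(ts * fr))
    n_tail <- round((arena$window + 2) * fr)
    radii <- c(rep(5, 5), rep(R - 0.2, n_stay), rep(5, n_tail))
    radial_traj(radii, fr = fr)
  })
}
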