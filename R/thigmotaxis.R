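#' Zone occupancy of a trajectory
#'
#' Classifies every non-missing frame as inner (radial distance strictly
#' below `inner_radius`) or outer (the boundary circle counts as outer) and
#' reports time percentages together with the area-derived random reference
#' (the outer percentage an area-uniform occupancy would give).
#'
#' @param traj A `trajectory`.
#' @param arena An `arena_geometry`.
#' @return List of class `occupancy_result` with `pct_outer`, `pct_inner`,
#'   `random_outer_pct`, `n_frames`.
#' @export
zone_occupancy <- function(traj, arena) {
  stop_if(!inherits(traj, "trajectory"), "`traj` must be a trajectory")
  stop_if(!inherits(arena, "arena_geometry"), "`arena` must be arena_geometry")
  ok <- traj$flags != "missing"
  stop_if(!any(ok), "empty trajectory: no usable frames")
  r <- traj_radius(traj)[ok]
  pct_inner <- 100 * mean(r < arena$inner_radius)
  structure(list(pct_outer = 100 - pct_inner, pct_inner = pct_inner,
                 random_outer_pct = arena$random_outer_pct,
                 n_frames = sum(ok)),
            class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf("Outer ring: %.1f%% of time (inner %.1f%%); random case %.1f%%\n",
              x$pct_outer, x$pct_inner, x$random_outer_pct))
  invisible(x)
}

# fraction of each square bin covered by the well, by regular subsampling
bin_well_area <- function(x_edges, y_edges, well_radius, sub = 16L) {
  nx <- length(x_edges) - 1L; ny <- length(y_edges) - 1L
  out <- matrix(0, nx, ny)
  for (i in seq_len(nx)) {
    xs <- seq(x_edges[i], x_edges[i + 1], length.out = sub + 1L)
    xs <- (xs[-1] + xs[-length(xs)]) / 2
    for (j in seq_len(ny)) {
      ys <- seq(y_edges[j], y_edges[j + 1], length.out = sub + 1L)
      ys <- (ys[-1] + ys[-length(ys)]) / 2
      out[i, j] <- mean(outer(xs^2, ys^2, "+") <= well_radius^2)
    }
  }
  out
}

#' Pooled positional density map over the well
#'
#' 2-D occupancy histogram over square bins spanning the well, pooled over
#' trajectories and normalized to total mass 1 (the proportion of larva-time
#' at each position).
#'
#' @param trajs A `trajectory` or list of them.
#' @param arena An `arena_geometry`.
#' @param n_bins Number of bins per axis (>= 2).
#' @return List of class `density_map` with `grid` (x by y matrix summing to
#'   1), `x_edges`, `y_edges`, `n_larvae`, and `well_area_fraction` (per-bin
#'   fraction of bin area inside the well, the uniform-occupancy reference).
#' @export
occupancy_density_map <- function(trajs, arena, n_bins = 20L) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  stop_if(length(trajs) < 1L, "need at least one trajectory")
  stop_if(n_bins < 2L, "n_bins must be >= 2")
  R <- arena$well_radius
  edges <- seq(-R, R, length.out = n_bins + 1L)
  grid <- matrix(0, n_bins, n_bins)
  for (tr in trajs) {
    ok <- tr$flags != "missing"
    ix <- findInterval(tr$x_mm[ok], edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
    iy <- findInterval(tr$y_mm[ok], edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
    for (k in seq_along(ix)) grid[ix[k], iy[k]] <- grid[ix[k], iy[k]] + 1
  }
  total <- sum(grid)
  stop_if(total == 0, "no usable positions")
  structure(list(grid = grid / total, x_edges = edges, y_edges = edges,
                 n_larvae = length(trajs),
                 well_area_fraction = bin_well_area(edges, edges, R)),
            class = "density_map")
}

#' Per-frame distance to the well wall
#'
#' @param traj A `trajectory`.
#' @param arena An `arena_geometry`.
#' @return Numeric vector, mm (`NA` where the sample is missing).
#' @export
dist_to_wall <- function(traj, arena) {
  d <- arena$well_radius - traj_radius(traj)
  d[traj$flags == "missing"] <- NA_real_
  d
}

#' Wall-arrival events of a trajectory
#'
#' Frames (0-based) where the distance to the wall crosses below
#' `edge_reach` from above. A recording that starts inside the reach band
#' yields an event at frame 0. Events whose observation window
#' (`arena$window` seconds) extends past the recording end are marked
#' censored.
#'
#' @param traj A `trajectory`.
#' @param arena An `arena_geometry`.
#' @return data.frame with columns `frame` (0-based arrival frame),
#'   `censored`, `initial` (event already in the band at frame 0). May have
#'   zero rows.
#' @export
wall_arrival_events <- function(traj, arena) {
  stop_if(!inherits(traj, "trajectory"), "`traj` must be a trajectory")
  d <- dist_to_wall(traj, arena)
  inb <- !is.na(d) & d < arena$edge_reach
  prev_out <- c(TRUE, !inb[-length(inb)])
  ev <- which(inb & prev_out)
  W <- round(arena$window * frame_rate(traj))
  data.frame(frame = ev - 1L,
             censored = (ev - 1L + W) > (nrow(traj) - 1L),
             initial = ev == 1L)
}

# shared event-following machinery: for each event index (1-based frame),
# observe `in_state` over the following W frames; returns leave time in
# frames (first t >= 1 with !in_state), NA if never within horizon, plus the
# horizon (frames observable, <= W)
follow_events <- function(state, events, W) {
  n <- length(state)
  leave <- integer(0); horizon <- integer(0)
  for (i in events) {
    h <- min(W, n - i)
    lv <- NA_integer_
    if (h >= 1L) {
      seg <- state[(i + 1L):(i + h)]
      hit <- which(!seg | is.na(seg))
      if (length(hit)) lv <- hit[1]
    }
    leave <- c(leave, lv); horizon <- c(horizon, h)
  }
  data.frame(leave = leave, horizon = horizon)
}

#' Probability of remaining next to the wall after arrival
#'
#' For a cohort of trajectories, finds all wall-arrival events
#' (distance-to-wall crossing below `edge_reach`) and computes, for each
#' time t in the observation window, the probability that the larva has
#' remained continuously within the wall-stay band (< `edge_stay` mm from
#' the wall) since arrival. Events truncated by the end of the recording
#' drop out of the denominator past their truncation point. `p_stay(0) = 1`
#' by construction.
#'
#' `mode = "instantaneous"` instead reports the fraction of larvae inside
#' the band at time t regardless of intermediate excursions.
#'
#' @param trajs A `trajectory` or list of them.
#' @param arena An `arena_geometry`.
#' @param mode `"continuous"` (default) or `"instantaneous"`.
#' @return List of class `wall_stay_curve` with `t_s`, `p_stay`, `n_events`
#'   (denominator per timepoint), and the per-event table in `$events`.
#' @export
wall_stay_curve <- function(trajs, arena,
                            mode = c("continuous", "instantaneous")) {
  mode <- match.arg(mode)
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  fr <- frame_rate(trajs[[1]])
  W <- round(arena$window * fr)
  ev_tabs <- list(); inst <- list()
  for (tr in trajs) {
    stop_if(abs(frame_rate(tr) - fr) > 1e-9,
            "all trajectories must share one frame rate")
    d <- dist_to_wall(tr, arena)
    inb_reach <- !is.na(d) & d < arena$edge_reach
    prev_out <- c(TRUE, !inb_reach[-length(inb_reach)])
    events <- which(inb_reach & prev_out)
    if (!length(events)) next
    in_stay <- !is.na(d) & d < arena$edge_stay
    ev_tabs[[length(ev_tabs) + 1L]] <- follow_events(in_stay, events, W)
    if (mode == "instantaneous") {
      n <- length(d)
      inst[[length(inst) + 1L]] <- t(vapply(events, function(i) {
        out <- rep(NA, W + 1L); out[1] <- TRUE
        h <- min(W, n - i)
        if (h >= 1L) out[2:(h + 1L)] <- in_stay[(i + 1L):(i + h)]
        out
      }, logical(W + 1L)))
    }
  }
  stop_if(length(ev_tabs) == 0L, "no wall-arrival events in this cohort")
  ev <- do.call(rbind, ev_tabs)
  t_s <- (0:W) / fr
  if (mode == "continuous") {
    leave <- ev$leave; horizon <- ev$horizon
    p <- numeric(W + 1L); nn <- integer(W + 1L)
    for (t in 0:W) {
      known_dep <- !is.na(leave) & leave <= t
      still <- (is.na(leave) | leave > t) & horizon >= t
      unknown <- is.na(leave) & horizon < t
      nn[t + 1L] <- sum(!unknown)
      p[t + 1L] <- if (nn[t + 1L] > 0) sum(still) / nn[t + 1L] else NA_real_
    }
  } else {
    m <- do.call(rbind, inst)
    nn <- colSums(!is.na(m))
    p <- colSums(m, na.rm = TRUE) / pmax(nn, 1L)
    p[nn == 0] <- NA_real_
    ev <- NULL
  }
  structure(list(t_s = t_s, p_stay = p, n_events = nn, mode = mode,
                 events = ev),
            class = "wall_stay_curve")
}

#' Per-timepoint comparison of two wall-stay curves
#'
#' Two-proportion test (still at wall vs departed) at each timepoint of the
#' shared observation window.
#'
#' @param a,b `wall_stay_curve` objects (continuous mode).
#' @return data.frame with `t_s`, `p_stay_a`, `p_stay_b`, `n_a`, `n_b`,
#'   `p_value`.
#' @export
compare_stay_curves <- function(a, b) {
  stop_if(!inherits(a, "wall_stay_curve") || !inherits(b, "wall_stay_curve"),
          "inputs must be wall_stay_curve objects")
  m <- min(length(a$t_s), length(b$t_s))
  pv <- vapply(seq_len(m), function(i) {
    na <- a$n_events[i]; nb <- b$n_events[i]
    if (na < 2 || nb < 2) return(NA_real_)
    xa <- round(a$p_stay[i] * na); xb <- round(b$p_stay[i] * nb)
    if ((xa + xb) %in% c(0L, na + nb)) return(1)
    suppressWarnings(stats::prop.test(c(xa, xb), c(na, nb))$p.value)
  }, numeric(1))
  data.frame(t_s = a$t_s[seq_len(m)],
             p_stay_a = a$p_stay[seq_len(m)], p_stay_b = b$p_stay[seq_len(m)],
             n_a = a$n_events[seq_len(m)], n_b = b$n_events[seq_len(m)],
             p_value = pv)
}

#' Trajectories after crossing from the inner to the outer zone
#'
#' Aligns all inner-to-outer crossings of the `inner_radius` circle at t = 0
#' and computes, over the following observation window, the per-timepoint
#' distribution of distance from the well edge plus the cumulative fraction
#' of crossings that have reached the wall (< `edge_reach`).
#'
#' @param trajs A `trajectory` or list of them.
#' @param arena An `arena_geometry`.
#' @param bin_width Distance-from-edge bin width, mm.
#' @return List of class `crossing_map` with `map` (time x distance matrix,
#'   each time slice normalized to mass 1), `t_s`, `dist_edges`, and
#'   `p_reach` (data.frame `t_s`, `p_reach_wall`, `n`).
#' @export
crossing_trajectories <- function(trajs, arena, bin_width = 0.25) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  fr <- frame_rate(trajs[[1]])
  W <- round(arena$window * fr)
  R <- arena$well_radius
  dist_edges <- seq(0, R, by = bin_width)
  if (dist_edges[length(dist_edges)] < R) dist_edges <- c(dist_edges, R)
  nb <- length(dist_edges) - 1L
  counts <- matrix(0, W + 1L, nb)
  reach_time <- integer(0); horizon <- integer(0)
  for (tr in trajs) {
    r <- traj_radius(tr)
    r[tr$flags == "missing"] <- NA_real_
    inside <- !is.na(r) & r < arena$inner_radius
    outside <- !is.na(r) & r >= arena$inner_radius
    cross <- which(outside & c(FALSE, inside[-length(inside)]))
    if (!length(cross)) next
    d <- R - r
    n <- length(d)
    for (i in cross) {
      h <- min(W, n - i)
      horizon <- c(horizon, h)
      seg <- d[i:(i + h)]
      tt <- which(!is.na(seg))
      bi <- findInterval(seg[tt], dist_edges, rightmost.closed = TRUE,
                         all.inside = TRUE)
      for (k in seq_along(tt))
        counts[tt[k], bi[k]] <- counts[tt[k], bi[k]] + 1
      hit <- which(!is.na(seg) & seg < arena$edge_reach)
      reach_time <- c(reach_time,
                      if (length(hit)) hit[1] - 1L else NA_integer_)
    }
  }
  stop_if(length(horizon) == 0L, "no inner-to-outer crossings in this cohort")
  rs <- rowSums(counts)
  map <- counts / ifelse(rs > 0, rs, 1)
  t_s <- (0:W) / fr
  p_reach <- vapply(0:W, function(t) {
    known <- (!is.na(reach_time) & reach_time <= t) | horizon >= t
    if (!any(known)) return(NA_real_)
    sum(!is.na(reach_time) & reach_time <= t) / sum(known)
  }, numeric(1))
  n_at <- vapply(0:W, function(t)
    sum((!is.na(reach_time) & reach_time <= t) | horizon >= t), numeric(1))
  structure(list(map = map, t_s = t_s, dist_edges = dist_edges,
                 p_reach = data.frame(t_s = t_s, p_reach_wall = p_reach,
                                      n = n_at),
                 n_crossings = length(horizon)),
            class = "crossing_map")
}

#' Center-to-wall path lengths
#'
#' Extracts swim paths from the central disc (area fraction
#' `center_disc_area_fraction` of the well) to the wall: a path starts at
#' the last frame inside the disc before a wall contact and ends at the
#' first subsequent frame within `edge_reach` of the wall, with no
#' intermediate disc re-entry. Path length is the summed step length over
#' that span; being a trajectory integral, it is independent of activity and
#' velocity. Paths containing missing samples are discarded.
#'
#' @param traj A `trajectory`.
#' @param arena An `arena_geometry`.
#' @return data.frame (possibly 0 rows) with `start_frame`, `end_frame`
#'   (0-based), `path_mm`, `straight_mm`, `duration_s`.
#' @export
center_to_wall_paths <- function(traj, arena) {
  stop_if(!inherits(traj, "trajectory"), "`traj` must be a trajectory")
  fr <- frame_rate(traj)
  r <- traj_radius(traj)
  miss <- traj$flags == "missing"
  r[miss] <- NA_real_
  in_disc <- !is.na(r) & r < arena$center_disc_radius
  at_wall <- !is.na(r) & (arena$well_radius - r) < arena$edge_reach
  n <- nrow(traj)
  out <- list()
  last_disc <- NA_integer_
  for (i in seq_len(n)) {
    if (in_disc[i]) {
      last_disc <- i
    } else if (at_wall[i] && !is.na(last_disc)) {
      span <- last_disc:i
      if (!any(miss[span])) {
        dx <- diff(traj$x_mm[span]); dy <- diff(traj$y_mm[span])
        out[[length(out) + 1L]] <- data.frame(
          start_frame = last_disc - 1L, end_frame = i - 1L,
          path_mm = sum(sqrt(dx^2 + dy^2)),
          straight_mm = sqrt((traj$x_mm[i] - traj$x_mm[last_disc])^2 +
                               (traj$y_mm[i] - traj$y_mm[last_disc])^2),
          duration_s = (i - last_disc) / fr)
      }
      last_disc <- NA_integer_
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(start_frame = integer(0), end_frame = integer(0),
                  path_mm = numeric(0), straight_mm = numeric(0),
                  duration_s = numeric(0))
}
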