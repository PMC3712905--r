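#' Circular-well arena geometry
#'
#' Bundles the well radius and the derived zone/threshold radii used
#' throughout the thigmotaxis analyses. Defaults correspond to a 15-mm
#' diameter well with an inner disc of radius 4.5 mm (36% of the area, so the
#' outer ring covers the remaining 64%), a wall-reach band of 0.5 mm, a
#' wall-stay band of 1 mm, a central disc covering 5% of the well area, and a
#' 30-s observation window after wall arrival or zone crossing.
#'
#' @param well_radius Well radius in mm.
#' @param inner_radius Radius of the inner zone in mm; positions at
#'   `r < inner_radius` are "inner", everything else "outer" (the boundary
#'   circle itself counts as outer).
#' @param edge_reach Distance-from-wall threshold (mm) defining "reached the
#'   wall edge".
#' @param edge_stay Distance-from-wall threshold (mm) defining "next to the
#'   wall" for stay-probability curves.
#' @param center_disc_area_fraction Area fraction of the central disc used as
#'   the start region for center-to-wall paths.
#' @param window Observation window in seconds for wall-arrival and crossing
#'   analyses.
#' @return An object of class `arena_geometry`.
#' @examples
#' a <- arena_geometry()
#' a$random_outer_pct  # 64
#' @export
arena_geometry <- function(well_radius = 7.5, inner_radius = 4.5,
                           edge_reach = 0.5, edge_stay = 1.0,
                           center_disc_area_fraction = 0.05,
                           window = 30) {
  check_number(well_radius, "well_radius", lower = 1e-9)
  check_number(inner_radius, "inner_radius", lower = 1e-9)
  check_number(edge_reach, "edge_reach", lower = 0)
  check_number(edge_stay, "edge_stay", lower = 0)
  check_number(center_disc_area_fraction, "center_disc_area_fraction",
               lower = 1e-9, upper = 1 - 1e-9)
  check_number(window, "window", lower = 0)
  stop_if(inner_radius >= well_radius,
          "`inner_radius` must be smaller than `well_radius`")
  stop_if(edge_reach > edge_stay,
          "`edge_reach` must not exceed `edge_stay`")
  stop_if(edge_stay >= well_radius,
          "`edge_stay` must be smaller than `well_radius`")
  out <- list(
    well_radius = well_radius,
    inner_radius = inner_radius,
    edge_reach = edge_reach,
    edge_stay = edge_stay,
    center_disc_area_fraction = center_disc_area_fraction,
    center_disc_radius = well_radius * sqrt(center_disc_area_fraction),
    window = window,
    inner_area_fraction = (inner_radius / well_radius)^2,
    random_outer_pct = (1 - (inner_radius / well_radius)^2) * 100
  )
  class(out) <- "arena_geometry"
  out
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat("Circular arena: well radius", x$well_radius, "mm\n")
  cat("  inner zone radius", x$inner_radius, "mm (",
      round(100 * x$inner_area_fraction, 1), "% of area )\n")
  cat("  wall reach <", x$edge_reach, "mm; wall stay <", x$edge_stay, "mm\n")
  cat("  center disc radius", round(x$center_disc_radius, 3), "mm (",
      100 * x$center_disc_area_fraction, "% of area )\n")
  cat("  observation window", x$window, "s\n")
  invisible(x)
}
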