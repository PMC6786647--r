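#' Tongue movement schedule
#'
#' A trapezoidal articulation schedule for the tongue tip: a linear ascent of
#' duration `t1` starting at `t_int`, a plateau of duration `t2` at the
#' maximum height `h_max`, and a linear descent at the same speed.  All
#' schedule times are dimensionless, expressed in units of the mean sibilant
#' duration `t_s`; conversions to seconds happen only at the signal boundary.
#'
#' @param speed Tongue ascent speed, mm/s.  Must be positive.
#' @param t_int Start of the ascent, units of `t_s` (negative: the tongue
#'   starts rising before the frication onset at t = 0).
#' @param t2 Plateau duration at maximum height, units of `t_s`.
#' @param t1 Ascent duration, units of `t_s`.  Defaults to
#'   [ascent_duration()] of `speed`, and is checked for consistency with it
#'   (travel = speed x time) to within 0.5\% when supplied.
#' @param h_max Maximum tongue height, mm.  Default 3.
#' @param t_s Normalisation duration, ms.  Default 175 (mean duration of [s]).
#' @param descent_speed Descent speed magnitude, mm/s.  Defaults to `speed`
#'   (symmetric trapezoid).
#'
#' @return An object of class `"tongue_schedule"`.
#' @seealso [schedule_from_table()] for the three calibrated schedules,
#'   [tongue_height()] to evaluate the trajectory.
#' @export
tongue_schedule <- function(speed, t_int, t2, t1 = NULL, h_max = 3, t_s = 175,
                            descent_speed = speed) {
  if (!is.numeric(speed) || length(speed) != 1L || speed <= 0)
    stop_invalid("`speed` must be a single positive number (mm/s), got %s",
                 format(speed))
  if (h_max <= 0) stop_invalid("`h_max` must be positive (mm)")
  if (t_s <= 0) stop_invalid("`t_s` must be positive (ms)")
  if (t2 < 0) stop_invalid("`t2` must be nonnegative (units of t_s)")
  if (descent_speed <= 0) stop_invalid("`descent_speed` must be positive")
  t1_exact <- ascent_duration(speed, h_max, t_s)
  if (is.null(t1)) {
    t1 <- t1_exact
  } else if (abs(t1 - t1_exact) > 0.005 * t1_exact) {
    stop_invalid(
      "`t1` = %g is inconsistent with speed %g mm/s over %g mm (expected %.4g)",
      t1, speed, h_max, t1_exact)
  }
  structure(
    list(speed = speed, descent_speed = descent_speed, h_max = h_max,
         t_s = t_s, t_int = t_int, t1 = t1, t2 = t2),
    class = "tongue_schedule")
}

#' @export
print.tongue_schedule <- function(x, ...) {
  cat(sprintf(
    "Tongue schedule: %g mm/s, h_max = %g mm, t_s = %g ms\n", x$speed,
    x$h_max, x$t_s))
  cat(sprintf("  ascent  [%0.3f, %0.3f] t/t_s\n", x$t_int, x$t_int + x$t1))
  cat(sprintf("  plateau [%0.3f, %0.3f] t/t_s\n", x$t_int + x$t1,
              x$t_int + x$t1 + x$t2))
  cat(sprintf("  descent [%0.3f, %0.3f] t/t_s\n", x$t_int + x$t1 + x$t2,
              x$t_int + x$t1 + x$t2 + descent_duration(x)))
  invisible(x)
}

# descent duration, units of t_s
descent_duration <- function(sched) {
  ascent_duration(sched$descent_speed, sched$h_max, sched$t_s)
}

#' Ascent duration of a linear tongue movement
#'
#' Time for the tongue to travel `h_max` at constant `speed`, expressed in
#' units of `t_s`.  The tabulated schedules satisfy this identity: e.g.
#' 3 mm at 40 mm/s is 75 ms = 0.429 x 175 ms.
#'
#' @param speed Tongue speed, mm/s.
#' @param h_max Travel distance, mm.  Default 3.
#' @param t_s Normalisation duration, ms.  Default 175.
#' @return Dimensionless duration t1 in units of `t_s`.
#' @export
ascent_duration <- function(speed, h_max = 3, t_s = 175) {
  if (any(speed <= 0)) stop_invalid("`speed` must be positive (mm/s)")
  1000 * h_max / (speed * t_s)
}

#' Tongue height along a schedule
#'
#' Evaluates the trapezoidal height trajectory: 0 before the ascent start,
#' linear rise to `h_max`, plateau, linear fall at the descent speed, 0
#' after.  Continuous and piecewise linear; a total function of `t`.
#'
#' @param t Time(s) in units of `t_s` (vectorised).
#' @param sched A [tongue_schedule()].
#' @return Height(s), mm, in `[0, h_max]`.
#' @export
tongue_height <- function(t, sched) {
  stopifnot(inherits(sched, "tongue_schedule"))
  a0 <- sched$t_int
  a1 <- a0 + sched$t1
  d0 <- a1 + sched$t2
  d1 <- d0 + descent_duration(sched)
  h <- numeric(length(t))
  up <- t > a0 & t < a1
  h[up] <- sched$h_max * (t[up] - a0) / sched$t1
  h[t >= a1 & t <= d0] <- sched$h_max
  dn <- t > d0 & t < d1
  h[dn] <- sched$h_max * (d1 - t[dn]) / descent_duration(sched)
  h
}

#' Movement phase along a schedule
#'
#' @param t Time(s) in units of `t_s`.
#' @param sched A [tongue_schedule()].
#' @return Character vector: `"pre"`, `"ascent"`, `"plateau"`, `"descent"` or
#'   `"post"` per time point.
#' @export
tongue_phase <- function(t, sched) {
  stopifnot(inherits(sched, "tongue_schedule"))
  a0 <- sched$t_int
  a1 <- a0 + sched$t1
  d0 <- a1 + sched$t2
  d1 <- d0 + descent_duration(sched)
  ph <- rep("pre", length(t))
  ph[t >= a0 & t < a1] <- "ascent"
  ph[t >= a1 & t <= d0] <- "plateau"
  ph[t > d0 & t < d1] <- "descent"
  ph[t >= d1] <- "post"
  ph
}

#' Simplified vocal-tract geometry
#'
#' Dimensions of the rectangular flow channel of the physical model: the
#' tongue-palate constriction, the teeth gap and the lip section.  The
#' constriction area is affine in tongue height,
#' `A_c(h) = area_offset + channel_span * (h_max - h)` mm^2, which gives the
#' fully raised area `area_offset` (8 mm^2, the 8 x 1 mm slit) at
#' `h = h_max` and 83 mm^2 with the tongue lowered.
#'
#' @param constriction_width Transverse width of the constriction slit, mm.
#' @param constriction_height_at_hmax Slit height with the tongue fully
#'   raised, mm.
#' @param channel_span Transverse channel width entering the area formula, mm.
#' @param area_offset Constant term of the area formula (area at `h_max`),
#'   mm^2.
#' @param lip_half_height Half the lip opening height (duct radius away from
#'   the constriction in the vortex-ring mapping), mm.
#' @param teeth_axial_gap Axial gap between the teeth (constriction length in
#'   the vortex-ring mapping), mm.
#' @param h_max Tongue height at full constriction, mm.
#' @return An object of class `"tract_geometry"`.
#' @export
tract_geometry <- function(constriction_width = 8,
                           constriction_height_at_hmax = 1,
                           channel_span = 25,
                           area_offset = 8,
                           lip_half_height = 4,
                           teeth_axial_gap = 1,
                           h_max = 3) {
  dims <- c(constriction_width = constriction_width,
            constriction_height_at_hmax = constriction_height_at_hmax,
            channel_span = channel_span, area_offset = area_offset,
            lip_half_height = lip_half_height,
            teeth_axial_gap = teeth_axial_gap, h_max = h_max)
  bad <- names(dims)[dims <= 0]
  if (length(bad))
    stop_invalid("tract dimensions must be strictly positive: %s",
                 paste(bad, collapse = ", "))
  structure(as.list(dims), class = "tract_geometry")
}

#' Constriction area from tongue height
#'
#' Affine area of the flow channel at the tongue-palate constriction,
#' strictly decreasing in height.  Heights outside `[0, h_max]` are an error
#' rather than clamped, so schedule bugs surface immediately.
#'
#' @param h Tongue height(s), mm, in `[0, h_max]`.
#' @param geom A [tract_geometry()].
#' @return Area(s), mm^2.
#' @export
constriction_area <- function(h, geom = tract_geometry()) {
  stopifnot(inherits(geom, "tract_geometry"))
  if (any(h < 0 | h > geom$h_max))
    stop_invalid("tongue height must lie in [0, %g] mm, got %s", geom$h_max,
                 paste(format(h[h < 0 | h > geom$h_max]), collapse = ", "))
  geom$area_offset + geom$channel_span * (geom$h_max - h)
}

#' Mean velocity at the constriction
#'
#' The quasi-steady bulk jet speed: volume flow rate divided by constriction
#' area.  With flow in cm^3/s and area in mm^2 the ratio is already in m/s
#' (1 cm^3/s / 1 mm^2 = 1 m/s), so no further conversion is applied.
#'
#' @param Q Volume flow rate(s), cm^3/s.  Nonnegative.
#' @param h Tongue height(s), mm.
#' @param geom A [tract_geometry()].
#' @return Mean constriction velocity, m/s.
#' @export
mean_constriction_velocity <- function(Q, h, geom = tract_geometry()) {
  if (any(Q < 0)) stop_invalid("flow rate `Q` must be nonnegative (cm^3/s)")
  Q / constriction_area(h, geom)
}

# printed schedule table: t1, t2, t_int in units of t_s per tongue speed
.schedule_table <- list(
  `40` = c(t1 = 0.429, t2 = 0.714, t_int = -0.383),
  `20` = c(t1 = 0.857, t2 = 0.514, t_int = -0.760),
  `10` = c(t1 = 1.714, t2 = 0.200, t_int = -1.457)
)

#' Calibrated tongue schedules for the three measured speeds
#'
#' Returns the articulation timing calibrated for the physical model at
#' tongue speeds 10, 20 and 40 mm/s: the ascent start `t_int`, ascent
#' duration `t1` (travel / speed) and plateau duration `t2`, all in units of
#' `t_s` = 175 ms.  `t2` shortens as the tongue slows, which keeps the sound
#' duration near `t_s`.
#'
#' @param speed Tongue speed, one of 10, 20 or 40 mm/s.
#' @return A [tongue_schedule()].
#' @export
schedule_from_table <- function(speed) {
  key <- as.character(speed)
  row <- .schedule_table[[key]]
  if (is.null(row))
    stop_invalid("no calibrated schedule for speed %s mm/s; supported: %s",
                 format(speed),
                 paste(names(.schedule_table), collapse = ", "))
  tongue_schedule(speed = speed, t_int = row[["t_int"]], t2 = row[["t2"]],
                  t1 = row[["t1"]])
}
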