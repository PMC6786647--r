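#' Vortex-ring sound-estimate parameters
#'
#' Parameters of the vortex-ring amplitude estimate for a constricted
#' axisymmetric duct: a ring of radius `R_v` and core diameter `delta_v`
#' convecting at speed U_c through a constriction of radius `R_min` inside a
#' duct of radius `R_p` and axial constriction length `H`.  The estimate is
#' a proportionality; `calib` is a dimensionless constant (default 1) that
#' rescales pressure linearly and therefore shifts all SPL curves by a
#' constant without changing their shape.
#'
#' @param rho_inf Ambient air density, kg/m^3.  Default 1.2.
#' @param R_v Vortex-ring radius, mm.  Default 0.1.
#' @param delta_v Vortex-core diameter, mm.  Default 0.05.  Must be below
#'   `2 * R_v`.
#' @param R_p Duct radius away from the constriction (half the lip opening
#'   height), mm.  Default 4.
#' @param H Axial constriction length (gap between the teeth), mm.
#'   Default 1.
#' @param calib Dimensionless proportionality constant.  Default 1.
#' @return An object of class `"vortex_sound_params"`.
#' @export
vortex_sound_params <- function(rho_inf = 1.2, R_v = 0.1, delta_v = 0.05,
                                R_p = 4, H = 1, calib = 1) {
  vals <- c(rho_inf = rho_inf, R_v = R_v, delta_v = delta_v, R_p = R_p,
            H = H, calib = calib)
  bad <- names(vals)[vals <= 0]
  if (length(bad))
    stop_invalid("vortex-sound parameters must be strictly positive: %s",
                 paste(bad, collapse = ", "))
  if (!(R_v < R_p))
    stop_invalid("`R_v` must be smaller than the duct radius `R_p`")
  if (!(delta_v < 2 * R_v))
    stop_invalid("`delta_v` must be smaller than the ring diameter 2 R_v")
  structure(as.list(vals), class = "vortex_sound_params")
}

#' Constriction radius from tongue height
#'
#' Maps the rectangular teeth-gap geometry onto the axisymmetric duct of the
#' vortex-ring estimate: `R_min = (4 - h) / 2` mm, i.e. 0.5 mm with the
#' tongue fully raised (h = 3 mm) and 2 mm with the tongue lowered.
#'
#' @param h Tongue height(s), mm, in `[0, 4)`.
#' @return Constriction radius, mm.
#' @export
r_min_from_height <- function(h) {
  if (any(h < 0 | h >= 4))
    stop_invalid("tongue height must lie in [0, 4) mm for a positive radius")
  (4 - h) / 2
}

#' Vortex-ring acoustic pressure amplitude
#'
#' Amplitude estimate for a vortex ring convecting through the constriction:
#' \deqn{p' = calib \cdot \rho_\infty \frac{R_v \delta_v}{R_{min}^2} U_c^2
#'   \frac{R_p - R_{min}}{\sqrt{(R_p - R_{min})^2 + H^2}}}
#' Nonnegative, quadratic in `U_c`, and zero when `U_c = 0` or
#' `R_min = R_p` (no constriction).  Radii enter only through dimensionless
#' ratios, so mm may be used throughout; with `rho_inf` in kg/m^3 and `U_c`
#' in m/s the result is in Pa.
#'
#' @param u_c Convection speed(s), m/s.  Nonnegative.
#' @param r_min Constriction radius(es), mm, in `(0, R_p]`.
#' @param params A [vortex_sound_params()].
#' @return Pressure amplitude(s), Pa.
#' @export
vortex_pressure <- function(u_c, r_min, params = vortex_sound_params()) {
  stopifnot(inherits(params, "vortex_sound_params"))
  if (any(u_c < 0)) stop_invalid("`u_c` must be nonnegative (m/s)")
  if (any(r_min <= 0)) stop_invalid("`r_min` must be positive (mm)")
  if (any(r_min > params$R_p))
    stop_invalid("`r_min` exceeds the duct radius R_p = %g mm", params$R_p)
  gap <- params$R_p - r_min
  params$calib * params$rho_inf * (params$R_v * params$delta_v / r_min^2) *
    u_c^2 * gap / sqrt(gap^2 + params$H^2)
}

#' Sound pressure level
#'
#' `20 log10(p / 20 uPa)`.  Nonpositive pressures map to a configurable
#' sentinel floor instead of failing, so whole-trajectory level curves stay
#' finite and plottable.
#'
#' @param p Pressure amplitude(s) (interpreted as RMS), Pa.
#' @param floor_db Sentinel for `p <= 0`, dB.  Default -300.
#' @return Level(s), dB re 20 uPa.
#' @export
spl <- function(p, floor_db = -300) {
  out <- rep(floor_db, length(p))
  pos <- p > 0
  out[pos] <- pmax(20 * log10(p[pos] / P_REF), floor_db)
  out
}

#' Windowed-RMS convection speed from a hot-wire record
#'
#' Estimates the vortex convection speed U_c as the per-frame RMS of the
#' measured velocity, using the same 512-point, 30\%-overlap framing as the
#' spectrogram so the two share timestamps exactly.  By default each frame
#' mean is removed first (fluctuation RMS); `mean_removed = FALSE` gives the
#' raw RMS.
#'
#' @param sig A [sampled_signal()] of velocity, m/s.
#' @param frame_len Frame length, samples.  Default 512.
#' @param overlap Fractional overlap.  Default 0.30.
#' @param mean_removed Remove the frame mean before the RMS?  Default TRUE.
#' @return Data frame with `time` (units of `t_s`) and `u_c` (m/s).
#' @export
convection_speed <- function(sig, frame_len = 512, overlap = 0.30,
                             mean_removed = TRUE) {
  stopifnot(inherits(sig, "sampled_signal"))
  hop <- frame_hop(frame_len, overlap)
  starts <- frame_starts(length(sig$samples), frame_len, hop)
  idx <- outer(seq_len(frame_len) - 1L, starts, `+`)
  frames <- matrix(sig$samples[idx], nrow = frame_len)
  if (mean_removed) frames <- sweep(frames, 2L, colMeans(frames))
  data.frame(time = frame_center_times(sig, starts, frame_len),
             u_c = sqrt(colMeans(frames^2)))
}

#' Estimated level curve over the articulation
#'
#' Combines per-frame mean constriction velocity, convection speed and
#' tongue height into the vortex-ring pressure estimate, expressed as SPL
#' and paired with the mean velocity — one point per frame, tagged with the
#' movement phase so ascent and descent branches can be compared at equal
#' mean velocity.  Because the estimate is quadratic in U_c, the SPL gap
#' between two branches at the same mean velocity is
#' `40 log10(U_c ratio)` dB.
#'
#' @param u_bar Per-frame mean constriction velocity, m/s.
#' @param u_c Per-frame convection speed, m/s (same length).
#' @param h Per-frame tongue height, mm (same length).
#' @param params A [vortex_sound_params()].
#' @param phase Optional per-frame phase tags (see [tongue_phase()]).
#' @param time Optional per-frame times, units of `t_s`.
#' @param floor_db SPL sentinel for zero pressure.  Default -300.
#' @return Data frame with `u_bar`, `u_c`, `pressure` (Pa), `spl` (dB) and,
#'   when given, `phase` and `time`.
#' @export
estimated_level_curve <- function(u_bar, u_c, h,
                                  params = vortex_sound_params(),
                                  phase = NULL, time = NULL,
                                  floor_db = -300) {
  n <- length(u_bar)
  if (length(u_c) != n || length(h) != n)
    stop_invalid("`u_bar`, `u_c` and `h` must have equal length (%d, %d, %d)",
                 n, length(u_c), length(h))
  p <- vortex_pressure(u_c, r_min_from_height(h), params)
  out <- data.frame(u_bar = u_bar, u_c = u_c, pressure = p,
                    spl = spl(p, floor_db))
  if (!is.null(time)) out$time <- time
  if (!is.null(phase)) out$phase <- phase
  out
}

#' Write an estimated or measured level curve
#'
#' Two-column text (mean velocity, level) with an optional phase tag column;
#' same comment conventions as [write_flow_record()].
#'
#' @param curve Data frame with `u_bar`, `spl` and optionally `phase`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_level_curve <- function(curve, path) {
  stopifnot(all(c("u_bar", "spl") %in% names(curve)))
  tag <- if ("phase" %in% names(curve)) curve$phase else rep("", nrow(curve))
  writeLines(c("# u_bar_m_per_s\tspl_db\tphase",
               sprintf("%.17g\t%.17g\t%s", curve$u_bar, curve$spl, tag)),
             path)
  invisible(path)
}
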