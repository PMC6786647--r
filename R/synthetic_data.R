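#' Articulatory trajectory at given times
#'
#' Evaluates tongue height, constriction area, inlet flow rate and mean
#' constriction velocity along a schedule and flow profile at arbitrary
#' normalised times — the quasi-steady state underlying both simulation
#' tables and synthetic sensor records.
#'
#' @param t Times, units of `t_s`.
#' @param sched A [tongue_schedule()].
#' @param profile A [flow_profile()].
#' @param geom A [tract_geometry()].
#' @return Data frame with `t`, `h` (mm), `area` (mm^2), `Q` (cm^3/s),
#'   `u_bar` (m/s) and `phase`.
#' @export
articulation_trajectory <- function(t, sched = schedule_from_table(40),
                                    profile = flow_profile(),
                                    geom = tract_geometry()) {
  h <- tongue_height(t, sched)
  Q <- flow_rate(t, profile)
  area <- constriction_area(h, geom)
  data.frame(t = t, h = h, area = area, Q = Q, u_bar = Q / area,
             phase = tongue_phase(t, sched))
}

# first-order low-pass (exponential lag) of a uniformly sampled series
first_order_lag <- function(x, dt, tau) {
  if (tau <= 0) return(x)
  alpha <- 1 - exp(-dt / tau)
  as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                           init = x[1L]))
}

# linearly interpolated time at which `y` crosses `level` going up (first)
# or down (first), scanning a monotone-enough stretch
.cross_time <- function(t, y, level, direction = c("up", "down")) {
  direction <- match.arg(direction)
  i <- if (direction == "up") {
    which(y >= level)[1L]
  } else {
    which(y < level)[1L]
  }
  if (is.na(i) || i == 1L) return(NA_real_)
  t[i - 1L] + (level - y[i - 1L]) * (t[i] - t[i - 1L]) / (y[i] - y[i - 1L])
}

#' Calibrate the convection-speed lag model
#'
#' The synthetic convection speed is modelled as a first-order lag of the
#' mean constriction velocity, `U_c(t) = uc_gain * lag(U_bar(t); uc_lag)`.
#' This calibrates both parameters so the model reproduces the two measured
#' reference points of the 10 mm/s articulation: U_c = 3.02 m/s on the
#' ascent branch and 4.54 m/s on the descent branch, both where
#' U_bar = 26 m/s.  The lag constant is solved from the ascent/descent
#' ratio (the hysteresis), then the gain from the descent level.
#'
#' @param sched A [tongue_schedule()]; default the 10 mm/s schedule the
#'   reference points were measured on.
#' @param profile A [flow_profile()].
#' @param geom A [tract_geometry()].
#' @param u_bar_ref Reference mean velocity, m/s.  Default 26.
#' @param uc_ascent,uc_descent Reference convection speeds, m/s.  Defaults
#'   3.02 and 4.54.
#' @return List with `uc_gain` (dimensionless) and `uc_lag` (s).
#' @export
calibrate_uc <- function(sched = schedule_from_table(10),
                         profile = flow_profile(),
                         geom = tract_geometry(),
                         u_bar_ref = 26, uc_ascent = 3.02,
                         uc_descent = 4.54) {
  ts_sec <- sched$t_s / 1000
  dt <- 1 / 44100   # match the synthesis rate so the lag discretisation agrees
  span <- synth_time_extent(sched, fluct_onset = sched$t_int)
  t <- seq(span[1L] * ts_sec, span[2L] * ts_sec, by = dt) / ts_sec
  traj <- articulation_trajectory(t, sched, profile, geom)
  asc <- traj$phase == "ascent"
  dsc <- traj$phase == "descent"
  t_a <- .cross_time(traj$t[asc], traj$u_bar[asc], u_bar_ref, "up")
  t_d <- .cross_time(traj$t[dsc], traj$u_bar[dsc], u_bar_ref, "down")
  if (is.na(t_a) || is.na(t_d))
    stop_invalid("U_bar never crosses %g m/s on both branches; cannot %s",
                 u_bar_ref, "calibrate the convection-speed model")
  lag_at <- function(tau) {
    lagged <- first_order_lag(traj$u_bar, dt, tau)
    approx(traj$t, lagged, xout = c(t_a, t_d))$y
  }
  target <- uc_descent / uc_ascent
  f <- function(tau) {
    v <- lag_at(tau)
    v[2L] / v[1L] - target
  }
  tau <- uniroot(f, c(1e-4, 0.5), tol = 1e-8)$root
  v <- lag_at(tau)
  list(uc_gain = uc_descent / v[2L], uc_lag = tau)
}

# per-speed velocity-fluctuation onsets measured on the physical model,
# units of t_s
.fluct_onset_table <- c(`40` = -0.23, `20` = -0.27, `10` = -0.30)

# time extent of synthetic records, units of t_s
synth_time_extent <- function(sched, fluct_onset, pad = c(0.3, 0.4)) {
  end <- sched$t_int + sched$t1 + sched$t2 + descent_duration(sched)
  c(min(sched$t_int, fluct_onset) - pad[1L], end + pad[2L])
}

#' Configuration for synthetic sensor records
#'
#' Bundles the articulation schedule, flow profile, geometry and
#' vortex-sound parameters with the generator-specific settings: the
#' convection-speed lag model, the spectral resonances of the radiated
#' noise, the velocity-fluctuation onset, and the RNG seed that fixes all
#' randomness (identical configurations give bit-identical records).
#'
#' Defaults emulate the physical model: resonances at 4 and 10 kHz (its
#' sustained-[s] spectral peaks), fluctuation onsets of -0.23, -0.27 and
#' -0.30 t/t_s for 40, 20 and 10 mm/s, and a lag model calibrated to the
#' measured convection speeds (see [calibrate_uc()]).
#'
#' @param speed Tongue speed used to pick the schedule and fluctuation
#'   onset; one of 10, 20, 40.  Default 40.
#' @param sched,profile,geom,params Component configurations; defaults are
#'   the physical-model values.
#' @param uc_gain Ratio U_c / lagged U_bar.  Default: calibrated.
#' @param uc_lag Lag time constant, s.  Default: calibrated.
#' @param resonance_freqs Resonance centre frequencies, Hz.
#' @param resonance_q Per-resonance quality factors (bandwidth = f/Q).
#' @param noise_floor_db Broadband floor SPL, dB re 20 uPa.  Default 20.
#' @param fluct_onset Velocity-fluctuation onset, units of `t_s`.  Default:
#'   per-speed table value (-0.25 for unlisted speeds).
#' @param fluct_ramp_ms Fluctuation gate ramp, ms.  Default 5.
#' @param mean_scale Ratio of the hot-wire mean velocity to U_c.  Default 3.
#' @param rate Audio/velocity sampling rate, Hz.  Default 44100.
#' @param seed RNG seed.  Default 1.
#' @return An object of class `"synthesis_config"`.
#' @export
synthesis_config <- function(speed = 40,
                             sched = schedule_from_table(speed),
                             profile = flow_profile(),
                             geom = tract_geometry(),
                             params = vortex_sound_params(),
                             uc_gain = NULL, uc_lag = NULL,
                             resonance_freqs = c(4000, 10000),
                             resonance_q = c(40, 40),
                             noise_floor_db = 20,
                             fluct_onset = NULL,
                             fluct_ramp_ms = 5,
                             mean_scale = 3,
                             rate = 44100,
                             seed = 1) {
  if (is.null(uc_gain) || is.null(uc_lag)) {
    cal <- calibrate_uc(profile = profile, geom = geom)
    if (is.null(uc_gain)) uc_gain <- cal$uc_gain
    if (is.null(uc_lag)) uc_lag <- cal$uc_lag
  }
  if (uc_gain <= 0) stop_invalid("`uc_gain` must be positive")
  if (uc_lag < 0) stop_invalid("`uc_lag` must be nonnegative (s)")
  if (is.null(fluct_onset)) {
    fluct_onset <- .fluct_onset_table[as.character(speed)]
    if (is.na(fluct_onset)) fluct_onset <- -0.25
  }
  nyq <- rate / 2
  if (any(resonance_freqs <= 0 | resonance_freqs >= nyq))
    stop_invalid("resonance frequencies must lie in (0, %g) Hz", nyq)
  if (length(resonance_q) == 1L)
    resonance_q <- rep(resonance_q, length(resonance_freqs))
  if (length(resonance_q) != length(resonance_freqs) ||
      any(resonance_q <= 0))
    stop_invalid("`resonance_q` must be positive, one per resonance")
  structure(
    list(speed = speed, sched = sched, profile = profile, geom = geom,
         params = params, uc_gain = uc_gain, uc_lag = uc_lag,
         resonance_freqs = resonance_freqs, resonance_q = resonance_q,
         noise_floor_db = noise_floor_db,
         fluct_onset = unname(fluct_onset),
         fluct_ramp_ms = fluct_ramp_ms, mean_scale = mean_scale,
         rate = rate, seed = seed),
    class = "synthesis_config")
}

# per-sample times (units of t_s) of a synthetic record
synth_times <- function(cfg) {
  span <- synth_time_extent(cfg$sched, cfg$fluct_onset)
  ts_sec <- cfg$sched$t_s / 1000
  n <- floor((span[2L] - span[1L]) * ts_sec * cfg$rate) + 1L
  span[1L] + (seq_len(n) - 1L) / cfg$rate / ts_sec
}

#' Synthetic convection-speed trajectory
#'
#' The per-sample convection speed of the generator:
#' `U_c(t) = uc_gain * lag(U_bar(t); uc_lag)`.  With a positive lag the
#' trajectory is hysteretic — smaller on the ascent branch than on the
#' descent branch at equal `U_bar`, the delay-to-spin-up the hot-wire
#' measurements show; with `uc_lag = 0` it collapses onto
#' `uc_gain * U_bar` and the asymmetry vanishes.
#'
#' @param cfg A [synthesis_config()].
#' @return A [sampled_signal()] of U_c, m/s.
#' @export
synth_convection_speed <- function(cfg) {
  stopifnot(inherits(cfg, "synthesis_config"))
  t <- synth_times(cfg)
  traj <- articulation_trajectory(t, cfg$sched, cfg$profile, cfg$geom)
  u_c <- cfg$uc_gain * first_order_lag(traj$u_bar, 1 / cfg$rate, cfg$uc_lag)
  sampled_signal(u_c, rate = cfg$rate, t0 = t[1L], t_s = cfg$sched$t_s,
                 units = "m/s")
}

#' Band-shaped unit-variance noise
#'
#' Seeded Gaussian white noise passed through second-order all-pole
#' resonators (one per centre frequency, bandwidth `f/Q`), summed with each
#' branch normalised to unit RMS, then normalised to unit RMS overall.  The
#' spectral colouring of the synthetic microphone signal.
#'
#' @param n Number of samples.
#' @param rate Sampling rate, Hz.
#' @param freqs Resonance centre frequencies, Hz.
#' @param q Quality factors, one per resonance.
#' @param seed RNG seed.
#' @return Numeric vector of length `n` with unit RMS.
#' @export
shaped_noise <- function(n, rate, freqs = c(4000, 10000), q = c(40, 40),
                         seed = 1) {
  x <- with_seed(seed, rnorm(n))
  y <- numeric(n)
  for (k in seq_along(freqs)) {
    theta <- 2 * pi * freqs[k] / rate
    r <- exp(-pi * (freqs[k] / q[k]) / rate)
    branch <- as.numeric(stats::filter((1 - r) * x,
                                       c(2 * r * cos(theta), -r^2),
                                       method = "recursive"))
    y <- y + branch / sd(branch)
  }
  y / sd(y)
}

#' Synthetic microphone record
#'
#' Far-field pressure emulation: band-shaped noise (resonances at
#' `resonance_freqs`) amplitude-modulated so the per-frame RMS pressure
#' tracks the vortex-ring estimate `p'(U_c(t), R_min(h(t)))`, plus a white
#' noise floor at `noise_floor_db`.  Deterministic per seed.  Absolute
#' levels use `calib = 1` and are internally consistent, not a claim about
#' the experiment's absolute OASPL.
#'
#' @param cfg A [synthesis_config()].
#' @return A [sampled_signal()] in Pa at `cfg$rate`.
#' @export
synth_microphone <- function(cfg) {
  stopifnot(inherits(cfg, "synthesis_config"))
  t <- synth_times(cfg)
  h <- tongue_height(t, cfg$sched)
  u_c <- synth_convection_speed(cfg)$samples
  p_env <- vortex_pressure(u_c, r_min_from_height(h), cfg$params)
  carrier <- shaped_noise(length(t), cfg$rate, cfg$resonance_freqs,
                          cfg$resonance_q, seed = cfg$seed)
  floor_rms <- P_REF * 10^(cfg$noise_floor_db / 20)
  floor_noise <- with_seed(cfg$seed + 1L, rnorm(length(t), sd = floor_rms))
  sampled_signal(carrier * p_env + floor_noise, rate = cfg$rate,
                 t0 = t[1L], t_s = cfg$sched$t_s, units = "Pa")
}

#' Synthetic hot-wire velocity record
#'
#' Velocity at the teeth gap: a slowly varying mean (`mean_scale * U_c(t)`,
#' a crude proxy for the local jet speed) plus a zero-mean Gaussian
#' fluctuation whose RMS tracks `U_c(t)`, gated on at `fluct_onset` with a
#' raised-cosine ramp of `fluct_ramp_ms`.  Before the gate opens the
#' mean-removed frame RMS is essentially zero, reproducing the observation
#' that velocity fluctuation precedes the sound but not the whole record.
#'
#' @param cfg A [synthesis_config()].
#' @return A [sampled_signal()] in m/s at `cfg$rate`.
#' @export
synth_hotwire <- function(cfg) {
  stopifnot(inherits(cfg, "synthesis_config"))
  t <- synth_times(cfg)
  u_c <- synth_convection_speed(cfg)$samples
  ramp <- cfg$fluct_ramp_ms / cfg$sched$t_s  # units of t_s
  u <- (t - cfg$fluct_onset) / ramp
  gate <- ifelse(u <= 0, 0, ifelse(u >= 1, 1, 0.5 * (1 - cos(pi * u))))
  fluct <- with_seed(cfg$seed + 2L, rnorm(length(t))) * u_c * gate
  sampled_signal(cfg$mean_scale * u_c + fluct, rate = cfg$rate,
                 t0 = t[1L], t_s = cfg$sched$t_s, units = "m/s")
}

#' Synthetic mass-flow-meter record
#'
#' The discretised flow profile at the flow-meter rate (100 Hz by default)
#' over the synthetic time extent, with optional Gaussian jitter.
#'
#' @param cfg A [synthesis_config()].
#' @param jitter_sd Jitter standard deviation, cm^3/s.  Default 0.
#' @return Data frame with `time` (s) and `value` (cm^3/s).
#' @export
synth_flowmeter <- function(cfg, jitter_sd = 0) {
  stopifnot(inherits(cfg, "synthesis_config"))
  span <- synth_time_extent(cfg$sched, cfg$fluct_onset)
  prof <- cfg$profile
  prof$t_s <- cfg$sched$t_s
  rec <- discretize_flow(prof, span[1L], span[2L])
  if (jitter_sd > 0)
    rec$value <- rec$value +
      with_seed(cfg$seed + 3L, rnorm(nrow(rec), sd = jitter_sd))
  rec
}

#' Write a full synthetic recording bundle
#'
#' Generates and writes the three records of one run — microphone WAV,
#' hot-wire velocity text and flow-meter text — plus a JSON manifest of
#' every parameter and seed, mirroring the deposited experimental file
#' roles.
#'
#' @param cfg A [synthesis_config()].
#' @param out_dir Output directory (created if needed).
#' @param jitter_sd Flow-meter jitter, cm^3/s.  Default 0.
#' @return Named list of written paths, invisibly.
#' @export
synth_bundle <- function(cfg, out_dir, jitter_sd = 0) {
  stopifnot(inherits(cfg, "synthesis_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mic <- synth_microphone(cfg)
  hw <- synth_hotwire(cfg)
  fm <- synth_flowmeter(cfg, jitter_sd = jitter_sd)
  ts_sec <- cfg$sched$t_s / 1000
  paths <- list(
    microphone = file.path(out_dir, sprintf("mic_%gmmps.wav", cfg$speed)),
    hotwire = file.path(out_dir, sprintf("hotwire_%gmmps.txt", cfg$speed)),
    flow = file.path(out_dir, sprintf("flow_%gmmps.txt", cfg$speed)),
    manifest = file.path(out_dir, sprintf("manifest_%gmmps.json", cfg$speed)))
  write_wav(mic$samples, paths$microphone, rate = cfg$rate)
  write_flow_record(
    data.frame(time = mic$t0 * ts_sec +
                 (seq_along(hw$samples) - 1L) / cfg$rate,
               value = hw$samples),
    paths$hotwire, comment = "hot-wire velocity, m/s")
  write_flow_record(fm, paths$flow, comment = "inlet flow rate, cm^3/s")
  write_manifest(paths$manifest, command = "synth", config = cfg,
                 files = paths[c("microphone", "hotwire", "flow")])
  invisible(paths)
}
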