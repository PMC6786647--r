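#' Read a key/value model configuration
#'
#' Plain-text configuration, one `key: value` pair per line (`#` comments
#' allowed).  An empty or absent file reproduces the default physical-model
#' setup; keys override individual defaults.  Recognised keys:
#' `speed`, `h_max`, `t_s`, `t_int`, `t1`, `t2`, `descent_speed` (schedule);
#' `channel_span`, `area_offset`, `lip_half_height`, `teeth_axial_gap`
#' (geometry); `rho_inf`, `R_v`, `delta_v`, `R_p`, `H`, `calib`
#' (vortex-sound); `uc_gain`, `uc_lag`, `noise_floor_db`, `fluct_onset`,
#' `seed` (synthesis).
#'
#' @param path Configuration file path, or `NULL` for pure defaults.
#' @return Named list of numeric values (possibly empty).
#' @export
read_model_config <- function(path = NULL) {
  if (is.null(path)) return(list())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(list())
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(\\S+)\\s*$", lines))
  bad <- which(vapply(kv, length, integer(1)) != 3L)
  if (length(bad))
    stop_invalid("malformed config line %d: '%s'", bad[1L], lines[bad[1L]])
  vals <- lapply(kv, function(m) {
    v <- suppressWarnings(as.numeric(m[3L]))
    if (is.na(v)) stop_invalid("config key '%s' has non-numeric value '%s'",
                               m[2L], m[3L])
    v
  })
  stats::setNames(vals, vapply(kv, `[`, character(1), 2L))
}

# build schedule/geometry/params objects from a config list, applying
# defaults for anything unspecified
config_objects <- function(cfg = list(), speed = NULL) {
  pick <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  speed <- if (!is.null(speed)) speed else pick("speed", 40)
  sched <- if (any(c("t_int", "t1", "t2", "h_max", "t_s", "descent_speed")
                   %in% names(cfg))) {
    base <- schedule_from_table(speed)
    tongue_schedule(
      speed = speed,
      t_int = pick("t_int", base$t_int),
      t2 = pick("t2", base$t2),
      t1 = cfg[["t1"]],
      h_max = pick("h_max", base$h_max),
      t_s = pick("t_s", base$t_s),
      descent_speed = pick("descent_speed", speed))
  } else {
    schedule_from_table(speed)
  }
  geom <- tract_geometry(
    channel_span = pick("channel_span", 25),
    area_offset = pick("area_offset", 8),
    lip_half_height = pick("lip_half_height", 4),
    teeth_axial_gap = pick("teeth_axial_gap", 1),
    h_max = pick("h_max", 3))
  params <- vortex_sound_params(
    rho_inf = pick("rho_inf", 1.2), R_v = pick("R_v", 0.1),
    delta_v = pick("delta_v", 0.05), R_p = pick("R_p", 4),
    H = pick("H", 1), calib = pick("calib", 1))
  list(speed = speed, sched = sched, geom = geom, params = params,
       profile = flow_profile(t_s = pick("t_s", 175)))
}

#' Write a run manifest
#'
#' Every pipeline command records its full parameter set, seeds and output
#' files as JSON, so a deterministic run can be reproduced bit-exactly from
#' its manifest.
#'
#' @param path Manifest path.
#' @param command Command name.
#' @param config Parameter object or list (serialised as JSON).
#' @param files Named list of output paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config, files = list()) {
  strip <- function(x) {
    if (is.function(x)) return(NULL)
    if (is.list(x)) {
      x <- lapply(x, strip)
      x[!vapply(x, is.null, logical(1))]
    } else x
  }
  jsonlite::write_json(
    list(command = command,
         package = "sibilantflow",
         version = as.character(utils::packageVersion("sibilantflow")),
         config = strip(unclass(config)),
         files = lapply(files, as.character)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Simulate the articulatory trajectory
#'
#' Tabulates tongue height, constriction area, flow rate and mean
#' constriction velocity over one articulation at a uniform step, and
#' optionally writes the table and a manifest.
#'
#' @param speed Tongue speed, mm/s (10, 20 or 40 unless a full schedule is
#'   configured).  Default 40.
#' @param config Optional path to a key/value configuration file (see
#'   [read_model_config()]).
#' @param dt Time step, units of `t_s`.  Default 0.005.
#' @param pad Padding before ascent start and after descent end, units of
#'   `t_s`.
#' @param out_dir Optional output directory for `trajectory_<speed>.tsv`
#'   and a manifest.
#' @return The trajectory data frame (see [articulation_trajectory()]),
#'   invisibly when `out_dir` is given.
#' @export
run_simulate <- function(speed = 40, config = NULL, dt = 0.005,
                         pad = c(0.3, 0.4), out_dir = NULL) {
  obj <- config_objects(read_model_config(config), speed = speed)
  span <- synth_time_extent(obj$sched, obj$sched$t_int, pad = pad)
  t <- seq(span[1L], span[2L], by = dt)
  traj <- articulation_trajectory(t, obj$sched, obj$profile, obj$geom)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tab <- file.path(out_dir, sprintf("trajectory_%gmmps.tsv", obj$speed))
    utils::write.table(traj, tab, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    write_manifest(file.path(out_dir,
                             sprintf("manifest_simulate_%gmmps.json",
                                     obj$speed)),
                   command = "simulate",
                   config = list(speed = obj$speed, dt = dt, pad = pad,
                                 sched = obj$sched, geom = obj$geom),
                   files = list(trajectory = tab))
    return(invisible(traj))
  }
  traj
}

#' Analyse a microphone (and optional hot-wire) recording
#'
#' The measurement pipeline: spectrogram, band-limited OASPL, frication
#' onset/offset, extent of OASPL above a level and — when a velocity record
#' is supplied — the windowed-RMS convection speed on the same framing.
#' When a schedule is known, per-frame mean constriction velocity is added
#' and the measured OASPL is paired with it, tagged by movement phase.
#'
#' @param wav_path Microphone WAV path.
#' @param velocity_path Optional hot-wire record path (two-column text,
#'   same sampling rate as the WAV).
#' @param t0 Time of the first WAV sample, units of `t_s`.
#' @param f_lo,f_hi OASPL band, Hz.  Defaults 4000 and 15000.
#' @param f_probe,threshold_db Onset/offset probe frequency (Hz) and
#'   threshold (dB).  Defaults 9000 and 15.
#' @param level_db OASPL extent threshold, dB.  Default 60.
#' @param speed,config Schedule selection as in [run_simulate()]; set
#'   `speed = NULL` to skip trajectory pairing.
#' @param out_dir Optional output directory for tabular results and a
#'   manifest.
#' @return List with `spectrogram`, `oaspl`, `event` (onset/offset),
#'   `extent` (duration above `level_db`), and when available `u_c` and
#'   `level_curve`.
#' @export
run_analyze <- function(wav_path, velocity_path = NULL, t0 = 0,
                        f_lo = 4000, f_hi = 15000,
                        f_probe = 9000, threshold_db = 15, level_db = 60,
                        speed = 40, config = NULL, out_dir = NULL) {
  obj <- config_objects(read_model_config(config), speed = speed)
  mic <- read_wav_signal(wav_path, t0 = t0, t_s = obj$sched$t_s)
  spec <- spectrogram(mic)
  lev <- oaspl(spec, f_lo, f_hi)
  res <- list(
    spectrogram = spec,
    oaspl = lev,
    event = detect_onset_offset(spec, f_probe, threshold_db),
    extent = duration_above(lev, level_db))
  if (!is.null(velocity_path)) {
    vel <- read_record_signal(velocity_path, t_s = obj$sched$t_s)
    if (abs(vel$rate - mic$rate) > 0.5)
      stop_invalid("sample-rate mismatch: WAV %g Hz vs velocity %g Hz",
                   mic$rate, vel$rate)
    res$u_c <- convection_speed(vel)
  }
  if (!is.null(speed)) {
    traj <- articulation_trajectory(spec$frame_times, obj$sched,
                                    obj$profile, obj$geom)
    res$level_curve <- data.frame(
      time = spec$frame_times, u_bar = traj$u_bar, oaspl = lev$oaspl,
      phase = traj$phase)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(oaspl = file.path(out_dir, "oaspl.tsv"))
    utils::write.table(lev, files$oaspl, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    if (!is.null(res$u_c)) {
      files$u_c <- file.path(out_dir, "u_c.tsv")
      utils::write.table(res$u_c, files$u_c, sep = "\t", row.names = FALSE,
                         quote = FALSE)
    }
    if (!is.null(res$level_curve)) {
      files$level_curve <- file.path(out_dir, "level_curve.tsv")
      utils::write.table(res$level_curve, files$level_curve, sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    write_manifest(file.path(out_dir, "manifest_analyze.json"),
                   command = "analyze",
                   config = list(wav = wav_path, velocity = velocity_path,
                                 t0 = t0, f_lo = f_lo, f_hi = f_hi,
                                 f_probe = f_probe,
                                 threshold_db = threshold_db,
                                 level_db = level_db, speed = speed),
                   files = files)
  }
  res
}

#' Estimate the level curve from a hot-wire record
#'
#' The vortex-ring prediction: per-frame convection speed from the velocity
#' record, per-frame mean constriction velocity and tongue height from the
#' schedule, combined by [estimated_level_curve()] into estimated SPL
#' against mean velocity with ascent/descent tags.
#'
#' @param velocity_path Hot-wire record path (two-column text).
#' @param speed,config Schedule selection as in [run_simulate()].
#' @param mean_removed Use fluctuation RMS for U_c?  Default TRUE.
#' @param out_dir Optional output directory for the curve and a manifest.
#' @return The estimated level-curve data frame.
#' @export
run_estimate <- function(velocity_path, speed = 40, config = NULL,
                         mean_removed = TRUE, out_dir = NULL) {
  obj <- config_objects(read_model_config(config), speed = speed)
  vel <- read_record_signal(velocity_path, t_s = obj$sched$t_s)
  uc <- convection_speed(vel, mean_removed = mean_removed)
  traj <- articulation_trajectory(uc$time, obj$sched, obj$profile, obj$geom)
  curve <- estimated_level_curve(traj$u_bar, uc$u_c, traj$h, obj$params,
                                 phase = traj$phase, time = uc$time)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(out_dir, "estimated_curve.tsv")
    write_level_curve(curve, path)
    write_manifest(file.path(out_dir, "manifest_estimate.json"),
                   command = "estimate",
                   config = list(velocity = velocity_path, speed = obj$speed,
                                 mean_removed = mean_removed,
                                 params = obj$params),
                   files = list(curve = path))
  }
  curve
}
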