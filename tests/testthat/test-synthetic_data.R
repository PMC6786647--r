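# one calibrated configuration shared across tests (calibration is
# deterministic, so this is a fixture, not hidden state)
CFG40 <- synthesis_config(40)
CFG10 <- synthesis_config(10, uc_gain = CFG40$uc_gain,
                          uc_lag = CFG40$uc_lag)

test_that("first-order lag has the textbook step response", {
  dt <- 1e-3
  x <- c(rep(0, 10), rep(1, 2000))
  y <- sibilantflow:::first_order_lag(x, dt, tau = 0.05)
  # value after one time constant: 1 - 1/e
  k <- 10 + round(0.05 / dt)
  expect_equal(y[k], 1 - exp(-1), tolerance = 0.02)
  expect_equal(y[length(y)], 1, tolerance = 1e-8)
  expect_true(all(diff(y) >= 0))
  # tau = 0 is the identity
  expect_identical(sibilantflow:::first_order_lag(x, dt, 0), x)
})

test_that("lag calibration reproduces both measured convection speeds", {
  uc <- synth_convection_speed(CFG10)
  t <- uc$t0 + (seq_along(uc$samples) - 1) / uc$rate / (CFG10$sched$t_s / 1000)
  traj <- articulation_trajectory(t, CFG10$sched, CFG10$profile, CFG10$geom)
  asc <- traj$phase == "ascent"
  dsc <- traj$phase == "descent"
  expect_equal(uc_at_crossing(traj$u_bar[asc], uc$samples[asc], 26, "up"),
               3.02, tolerance = 0.01)
  expect_equal(uc_at_crossing(traj$u_bar[dsc], uc$samples[dsc], 26, "down"),
               4.54, tolerance = 0.01)
})

test_that("convection-speed hysteresis appears iff the lag is positive", {
  # with lag: descent U_c exceeds ascent U_c at equal mean velocity
  uc <- synth_convection_speed(CFG10)
  t <- uc$t0 + (seq_along(uc$samples) - 1) / uc$rate / (CFG10$sched$t_s / 1000)
  traj <- articulation_trajectory(t, CFG10$sched, CFG10$profile, CFG10$geom)
  for (level in c(15, 20, 26, 30)) {
    up <- uc_at_crossing(traj$u_bar[traj$phase == "ascent"],
                         uc$samples[traj$phase == "ascent"], level, "up")
    dn <- uc_at_crossing(traj$u_bar[traj$phase == "descent"],
                         uc$samples[traj$phase == "descent"], level, "down")
    expect_gt(dn, up)
  }
  # without lag the curve collapses onto uc_gain * u_bar exactly
  cfg0 <- synthesis_config(10, uc_gain = CFG10$uc_gain, uc_lag = 0)
  uc0 <- synth_convection_speed(cfg0)
  expect_equal(uc0$samples, CFG10$uc_gain * traj$u_bar, tolerance = 1e-12)
})

test_that("synthetic records are bit-identical for identical configurations", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  synth_bundle(CFG40, d1)
  synth_bundle(CFG40, d2)
  for (f in c("mic_40mmps.wav", "hotwire_40mmps.txt", "flow_40mmps.txt")) {
    expect_identical(readBin(file.path(d1, f), raw(), 1e7),
                     readBin(file.path(d2, f), raw(), 1e7))
  }
  # a different seed changes the audio
  d3 <- withr::local_tempdir()
  synth_bundle(synthesis_config(40, uc_gain = CFG40$uc_gain,
                                uc_lag = CFG40$uc_lag, seed = 2), d3)
  expect_false(identical(readBin(file.path(d1, "mic_40mmps.wav"), raw(), 1e7),
                         readBin(file.path(d3, "mic_40mmps.wav"), raw(), 1e7)))
})

test_that("microphone per-frame RMS tracks the vortex-pressure envelope", {
  mic <- synth_microphone(CFG40)
  uc <- synth_convection_speed(CFG40)
  rms <- convection_speed(mic, mean_removed = FALSE)   # frame RMS pressure
  ts_sec <- CFG40$sched$t_s / 1000
  t <- mic$t0 + (seq_along(mic$samples) - 1) / mic$rate / ts_sec
  p_env <- vortex_pressure(uc$samples,
                           r_min_from_height(tongue_height(t, CFG40$sched)),
                           CFG40$params)
  env_frame <- approx(t, p_env, xout = rms$time)$y
  sounding <- env_frame > 0.05 * max(env_frame)
  expect_gt(sum(sounding), 10)
  # measured frame levels follow the quadratic-in-U_c envelope law
  # (40 log10 U_c plus the slowly varying R_min geometry factor)
  measured_db <- 20 * log10(rms$u_c[sounding] / 2e-5)
  predicted_db <- spl(env_frame[sounding])
  expect_lt(max(abs(measured_db - predicted_db)), 3)    # per-frame noise
  expect_lt(abs(mean(measured_db - predicted_db)), 0.5) # no systematic bias
})

test_that("near-zero convection speed leaves only the noise floor", {
  cfg <- synthesis_config(40, uc_gain = 1e-9, uc_lag = CFG40$uc_lag)
  mic <- synth_microphone(cfg)
  frame_spl <- 20 * log10(convection_speed(mic, mean_removed = FALSE)$u_c /
                            2e-5)
  expect_equal(mean(frame_spl), cfg$noise_floor_db, tolerance = 0.05)
})

test_that("hot-wire fluctuation is gated on at the configured onset", {
  hw <- synth_hotwire(CFG40)
  uc <- convection_speed(hw)        # mean-removed frame RMS
  peak <- max(uc$u_c)
  hop_ts <- 358 / CFG40$rate / (CFG40$sched$t_s / 1000)
  before <- uc$time < CFG40$fluct_onset - hop_ts
  expect_true(all(uc$u_c[before] < 0.05 * peak))
  # fluctuation onset recovered within one frame of the configured time
  t_detect <- uc$time[which(uc$u_c > 0.05 * peak)[1]]
  expect_lt(abs(t_detect - CFG40$fluct_onset), hop_ts + 0.005 / 0.175)
  # the default onsets follow the per-speed table
  expect_equal(synthesis_config(20, uc_gain = 1, uc_lag = 0)$fluct_onset,
               -0.27)
  expect_equal(CFG40$fluct_onset, -0.23)
  expect_equal(CFG10$fluct_onset, -0.30)
})

test_that("flow-meter records discretise the profile and round-trip", {
  fm <- synth_flowmeter(CFG40)
  span <- sibilantflow:::synth_time_extent(CFG40$sched, CFG40$fluct_onset)
  prof <- CFG40$profile
  ref <- discretize_flow(prof, span[1], span[2])
  expect_identical(fm, ref)                       # sigma = 0: no jitter
  # anchors reproduced at the nearest samples, to within the half-sample
  # discretisation error of the 100 Hz grid
  ts_sec <- CFG40$sched$t_s / 1000
  for (k in seq_len(nrow(prof$anchors))) {
    t_anchor <- prof$anchors$t[k] * ts_sec
    i <- which.min(abs(fm$time - t_anchor))
    slope_bound <- max(abs(diff(fm$value[max(1, i - 1):min(nrow(fm), i + 1)])))
    expect_lte(abs(fm$value[i] - prof$anchors$Q[k]), slope_bound / 2 + 0.5)
  }
  # jitter is seeded and deterministic
  j1 <- synth_flowmeter(CFG40, jitter_sd = 2)
  j2 <- synth_flowmeter(CFG40, jitter_sd = 2)
  expect_identical(j1, j2)
  expect_false(identical(j1$value, fm$value))
  # text round trip
  path <- withr::local_tempfile(fileext = ".txt")
  write_flow_record(fm, path)
  expect_identical(read_flow_record(path)$value, fm$value)
})

test_that("WAV files round-trip the synthetic audio", {
  mic <- synth_microphone(CFG40)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(mic$samples, path)
  back <- read_wav(path)
  expect_equal(back$rate, 44100)
  expect_equal(back$samples, mic$samples, tolerance = 1e-6)  # float32
  write_wav(mic$samples / max(abs(mic$samples)), path, format = "pcm16")
  b16 <- read_wav(path)
  # 16-bit quantisation: absolute error bounded by half a step
  expect_lt(max(abs(b16$samples - mic$samples / max(abs(mic$samples)))),
            1 / 32767)
})
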