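test_that("a calibration sine reports its true SPL at its bin", {
  tone <- bin_tone(9000, amp = 0.2)
  sp <- spectrogram(tone$sig)
  bin <- which.min(abs(sp$freqs - tone$freq))
  expect_equal(sp$freqs[bin], tone$freq)
  expect_equal(max(abs(sp$levels[bin, ] - tone_spl(tone$amp))), 0,
               tolerance = 0.01)
})

test_that("spectrogram structure follows the framing recipe", {
  sig <- sampled_signal(rep(0, 5000), FS, t0 = -0.2)
  sp <- spectrogram(sig)
  expect_equal(sp$hop, 358)                       # round(512 * 0.7)
  expect_equal(sp$freqs, (0:256) * FS / 512)
  expect_true(all(sp$levels == sp$floor_db))      # silence sits at the floor
  # frame centres advance by one hop, starting half a frame in
  dt <- diff(sp$frame_times) * 0.175
  expect_equal(dt, rep(358 / FS, length(dt)))
  expect_equal(sp$frame_times[1], -0.2 + (511 / 2) / FS / 0.175)
  expect_error(spectrogram(sampled_signal(rnorm(100), FS)), "too short")
})

test_that("white noise gives a statistically flat mean spectrum", {
  sig <- with_seed_local(7, sampled_signal(rnorm(FS), FS))
  sp <- spectrogram(sig)
  mean_level <- 10 * log10(rowMeans(10^(sp$levels / 10)))
  inner <- mean_level[2:256]          # DC and Nyquist scale differently
  expect_lt(diff(range(inner)), 5)    # ~120-frame average, dB spread
  expect_lt(max(abs(inner - median(inner))), 2.5)
})

test_that("band OASPL obeys Parseval and tone power summation", {
  # single in-band tone: band OASPL equals the tone SPL
  tone <- bin_tone(9000, amp = 0.2)
  sp <- spectrogram(tone$sig)
  lev <- oaspl(sp)
  expect_equal(max(abs(lev$oaspl - tone_spl(tone$amp))), 0, tolerance = 0.5)
  # out-of-band tone: band level at least 60 dB below the tone
  t2 <- bin_tone(2000, amp = 0.2)
  lev2 <- oaspl(spectrogram(t2$sig))
  expect_lt(max(lev2$oaspl), tone_spl(0.2) - 60)
  # two equal in-band tones: +3.01 dB over one
  both <- sampled_signal(tone$sig$samples +
                           bin_tone(6000, amp = 0.2)$sig$samples, FS)
  lev3 <- oaspl(spectrogram(both))
  expect_equal(mean(lev3$oaspl) - tone_spl(0.2), 10 * log10(2),
               tolerance = 0.05)
  # full-band OASPL of every multitone frame equals its time-domain SPL
  mt <- multitone()
  spm <- spectrogram(mt)
  full <- oaspl(spm, 0, FS / 2)
  starts <- seq(1, length(mt$samples) - 511, by = 358)
  td <- vapply(starts, function(s)
    10 * log10(mean(mt$samples[s:(s + 511)]^2) / (2e-5)^2), numeric(1))
  expect_lt(max(abs(full$oaspl - td)), 0.5)
  expect_error(oaspl(spm, 8000, 4000), "f_lo")
  expect_error(oaspl(spm, 4000, 30000), "Nyquist")
})

test_that("OASPL is monotone under added in-band power", {
  tone <- bin_tone(7000, amp = 0.05)
  base <- oaspl(spectrogram(tone$sig))
  more <- sampled_signal(tone$sig$samples +
                           bin_tone(10000, amp = 0.05)$sig$samples, FS)
  lev <- oaspl(spectrogram(more))
  expect_true(all(lev$oaspl >= base$oaspl - 1e-9))
})

test_that("onset/offset detection recovers an injected burst within one hop", {
  sig <- burst_signal(t_on = 0.1, t_off = 0.9)
  sp <- spectrogram(sig)
  ev <- detect_onset_offset(sp)
  hop_ts <- 358 / FS / 0.175        # one frame hop in units of t_s
  expect_true(ev$event)
  expect_equal(ev$t_on, 0.1, tolerance = hop_ts / 0.1)
  expect_equal(ev$t_off, 0.9, tolerance = hop_ts / 0.9)
  expect_equal(ev$bin_freq, round(9000 / DF) * DF)
  # silence: an explicit no-event result, not an exception
  silent <- sampled_signal(rep(0, 10000), FS)
  none <- detect_onset_offset(spectrogram(silent))
  expect_false(none$event)
  expect_true(is.na(none$t_on) && is.na(none$t_off))
})

test_that("single-frame spikes are rejected by the minimum run length", {
  sig <- burst_signal(t_on = 0.1, t_off = 0.9)
  sp <- spectrogram(sig)
  bin <- which.min(abs(sp$freqs - 9000))
  # forge a lone spike well before the burst
  sp$levels[bin, 2] <- 80
  ev <- detect_onset_offset(sp)
  expect_gt(ev$t_on, 0)             # spike at frame 2 ignored
  ev1 <- detect_onset_offset(sp, min_run = 1)
  expect_lt(ev1$t_on, 0)            # accepted when runs of 1 are allowed
})

test_that("event detection is invariant to uniform time shifts", {
  a <- burst_signal(t_on = 0.1, t_off = 0.9, t_lo = -0.5)
  b <- a
  b$t0 <- a$t0 + 0.37
  ea <- detect_onset_offset(spectrogram(a))
  eb <- detect_onset_offset(spectrogram(b))
  expect_equal(eb$t_on - ea$t_on, 0.37)
  expect_equal(eb$t_off - ea$t_off, 0.37)
  da <- duration_above(oaspl(spectrogram(a)), 40)
  db <- duration_above(oaspl(spectrogram(b)), 40)
  expect_equal(db$t_start - da$t_start, 0.37)
  expect_equal(db$t_end - da$t_end, 0.37)
})

test_that("duration above a level finds the longest contiguous run", {
  lev <- data.frame(time = seq(0, 1, 0.1), oaspl = rep(70, 11))
  full <- duration_above(lev, 60)
  expect_true(full$event)
  expect_equal(c(full$t_start, full$t_end), c(0, 1))
  expect_false(duration_above(data.frame(time = 0:5, oaspl = rep(50, 6)),
                              60)$event)
  # synthetic hump with known crossings, sampled on the spectrogram frames
  sig <- burst_signal(t_on = 0.12, t_off = 0.92)
  lv <- oaspl(spectrogram(sig))
  hop_ts <- 358 / FS / 0.175
  ext <- duration_above(lv, tone_spl(0.2) - 20)
  expect_equal(ext$t_start, 0.12, tolerance = hop_ts / 0.12)
  expect_equal(ext$t_end, 0.92, tolerance = hop_ts / 0.92)
  # two runs: the longer one wins
  two <- data.frame(time = 1:10,
                    oaspl = c(70, 70, 10, 70, 70, 70, 70, 10, 10, 10))
  ext2 <- duration_above(two, 60)
  expect_equal(c(ext2$t_start, ext2$t_end), c(4, 7))
})

test_that("spectrum slices and peak finding recover known structure", {
  tone <- bin_tone(9000, amp = 0.2)
  sp <- spectrogram(tone$sig)
  sl <- spectrum_slice(sp, range(sp$frame_times))
  pk <- find_spectral_peaks(sl, min_prominence = 20)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$freq, tone$freq)
  # white noise with a high prominence bar: no peaks
  noise <- with_seed_local(11, sampled_signal(rnorm(FS / 2), FS))
  sln <- spectrum_slice(spectrogram(noise), c(0, 0.5))
  expect_equal(nrow(find_spectral_peaks(sln, min_prominence = 15)), 0)
  expect_error(spectrum_slice(sp, c(5, 6)), "no spectrogram frames")
})
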