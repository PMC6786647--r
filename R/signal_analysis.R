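#' Uniformly sampled sensor signal
#'
#' Container for microphone (Pa) or hot-wire velocity (m/s) records.  The
#' time of the first sample is stored in normalised units of `t_s` so all
#' analytics report event times on the articulation clock.
#'
#' @param samples Numeric vector; all values must be finite.
#' @param rate Sampling rate, Hz.  Default 44100.
#' @param t0 Time of the first sample, units of `t_s`.  Default 0.
#' @param t_s Normalisation duration, ms.  Default 175.
#' @param units Unit label, e.g. `"Pa"` or `"m/s"`.
#' @return An object of class `"sampled_signal"`.
#' @export
sampled_signal <- function(samples, rate = 44100, t0 = 0, t_s = 175,
                           units = "Pa") {
  if (!is.numeric(samples) || !length(samples))
    stop_invalid("`samples` must be a nonempty numeric vector")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop_invalid("`samples` must be finite")
  if (rate <= 0) stop_invalid("`rate` must be positive (Hz)")
  structure(list(samples = as.numeric(samples), rate = rate, t0 = t0,
                 t_s = t_s, units = units),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("Sampled signal: %d samples @ %g Hz (%s), t0 = %.3f t/t_s\n",
              length(x$samples), x$rate, x$units, x$t0))
  invisible(x)
}

#' Read a WAV file as a sampled signal
#'
#' @param path WAV file path.
#' @param t0 Time of the first sample, units of `t_s`.
#' @param t_s Normalisation duration, ms.
#' @param units Unit label for the samples.
#' @return A [sampled_signal()].
#' @export
read_wav_signal <- function(path, t0 = 0, t_s = 175, units = "Pa") {
  w <- read_wav(path)
  sampled_signal(w$samples, rate = w$rate, t0 = t0, t_s = t_s, units = units)
}

#' Read a two-column text record as a sampled signal
#'
#' The record must be uniformly sampled; the rate is inferred from the time
#' column.
#'
#' @param path Record path (see [read_flow_record()] for the format).
#' @param t_s Normalisation duration, ms.
#' @param units Unit label.
#' @return A [sampled_signal()].
#' @export
read_record_signal <- function(path, t_s = 175, units = "m/s") {
  rec <- read_flow_record(path)
  if (nrow(rec) < 2L) stop_invalid("record '%s' has fewer than 2 samples", path)
  dt <- diff(rec$time)
  if (max(abs(dt - dt[1L])) > 1e-6 * dt[1L] + 1e-12)
    stop_invalid("record '%s' is not uniformly sampled", path)
  sampled_signal(rec$value, rate = 1 / dt[1L],
                 t0 = rec$time[1L] / (t_s / 1000), t_s = t_s, units = units)
}

# symmetric Hann window
hann_window <- function(n) {
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
}

# first sample index of each analysis frame
frame_starts <- function(n, frame_len, hop) {
  if (n < frame_len)
    stop_invalid("signal too short: %d samples < frame length %d", n,
                 frame_len)
  seq.int(1L, n - frame_len + 1L, by = hop)
}

# frame hop in samples for a fractional overlap
frame_hop <- function(frame_len, overlap) {
  hop <- as.integer(round(frame_len * (1 - overlap)))
  if (hop < 1L) stop_invalid("overlap %g leaves no hop", overlap)
  hop
}

# frame centre times, units of t_s
frame_center_times <- function(sig, starts, frame_len) {
  sec <- (starts - 1L + (frame_len - 1) / 2) / sig$rate
  sig$t0 + sec / (sig$t_s / 1000)
}

#' Spectrogram with per-bin sound pressure levels
#'
#' Short-time Fourier transform of a pressure signal: 512-point frames with
#' 30\% overlap, each multiplied by a Hann window (the hop is
#' `round(frame_len * (1 - overlap))` = 358 samples at the defaults, about
#' 8.1 ms at 44.1 kHz).  Per-bin one-sided amplitudes are scaled by
#' `2 / sum(window)` so a calibration sinusoid reports its true SPL
#' (`20 log10(RMS / 20 uPa)`) at its bin; band power sums divide by the
#' window's equivalent noise bandwidth so Parseval holds (see [oaspl()]).
#'
#' @param sig A [sampled_signal()] in Pa, at least `frame_len` samples.
#' @param frame_len Frame length, samples.  Default 512.
#' @param overlap Fractional frame overlap.  Default 0.30.
#' @param floor_db Sentinel SPL assigned to empty bins, dB.  Default -300.
#' @return An object of class `"frication_spectrogram"` with `frame_times`
#'   (units of `t_s`), `freqs` (Hz) and `levels` (matrix, bins x frames, dB
#'   re 20 uPa).
#' @export
spectrogram <- function(sig, frame_len = 512, overlap = 0.30,
                        floor_db = -300) {
  stopifnot(inherits(sig, "sampled_signal"))
  hop <- frame_hop(frame_len, overlap)
  starts <- frame_starts(length(sig$samples), frame_len, hop)
  w <- hann_window(frame_len)
  idx <- outer(seq_len(frame_len) - 1L, starts, `+`)
  frames <- matrix(sig$samples[idx], nrow = frame_len)
  X <- mvfft(frames * w)
  nbin <- frame_len %/% 2L + 1L
  amp <- Mod(X[seq_len(nbin), , drop = FALSE]) / sum(w)
  rms <- 2 * amp / sqrt(2)                 # one-sided doubling, sine RMS
  rms[c(1L, nbin), ] <- amp[c(1L, nbin), ] # DC and Nyquist: neither applies
  levels <- 20 * log10(rms / P_REF)
  levels[!is.finite(levels) | levels < floor_db] <- floor_db
  structure(
    list(frame_times = frame_center_times(sig, starts, frame_len),
         freqs = (seq_len(nbin) - 1L) * sig$rate / frame_len,
         levels = levels, frame_len = frame_len, overlap = overlap,
         hop = hop, window = "hann",
         enbw = frame_len * sum(w^2) / sum(w)^2,
         rate = sig$rate, t_s = sig$t_s, floor_db = floor_db),
    class = "frication_spectrogram")
}

#' @export
print.frication_spectrogram <- function(x, ...) {
  cat(sprintf(
    "Spectrogram: %d frames x %d bins, %d-pt %s window, %.0f%% overlap\n",
    ncol(x$levels), nrow(x$levels), x$frame_len, x$window, 100 * x$overlap))
  cat(sprintf("  t/t_s in [%.3f, %.3f], df = %.1f Hz, hop = %.2f ms\n",
              min(x$frame_times), max(x$frame_times), x$freqs[2L],
              1000 * x$hop / x$rate))
  invisible(x)
}

# frame hop expressed in units of t_s
hop_norm <- function(spec) spec$hop / spec$rate / (spec$t_s / 1000)

#' Band-limited overall sound pressure level per frame
#'
#' Power-sums the spectrogram bins whose frequency lies in `[f_lo, f_hi]`
#' (default 4-15 kHz, the band above the first characteristic spectral peak
#' of [s]) and converts to dB re 20 uPa.  The sum is divided by the
#' window's equivalent noise bandwidth, so the full-band OASPL of a frame
#' equals its time-domain SPL (Parseval).
#'
#' @param spec A [spectrogram()].
#' @param f_lo,f_hi Band edges, Hz; `f_lo < f_hi <=` Nyquist.
#' @return Data frame with `time` (units of `t_s`) and `oaspl` (dB).
#' @export
oaspl <- function(spec, f_lo = 4000, f_hi = 15000) {
  stopifnot(inherits(spec, "frication_spectrogram"))
  if (!(f_lo < f_hi)) stop_invalid("`f_lo` must be below `f_hi`")
  if (f_hi > max(spec$freqs) + spec$freqs[2L] / 2)
    stop_invalid("`f_hi` = %g Hz exceeds the Nyquist frequency %g Hz", f_hi,
                 max(spec$freqs))
  sel <- spec$freqs >= f_lo & spec$freqs <= f_hi
  if (!any(sel)) stop_invalid("no spectrogram bins in [%g, %g] Hz", f_lo, f_hi)
  power <- colSums(10^(spec$levels[sel, , drop = FALSE] / 10)) / spec$enbw
  level <- 10 * log10(power)
  level[!is.finite(level) | level < spec$floor_db] <- spec$floor_db
  data.frame(time = spec$frame_times, oaspl = level)
}

#' Frication onset and offset from a spectrogram threshold
#'
#' The event detector used for the articulation clock: the onset is the
#' first frame whose level at the bin nearest `f_probe` exceeds
#' `threshold_db`, the offset the last such frame.  Runs shorter than
#' `min_run` frames are ignored, which rejects single-frame spikes.
#'
#' @param spec A [spectrogram()].
#' @param f_probe Probe frequency, Hz.  Default 9000.
#' @param threshold_db Per-bin SPL threshold, dB.  Default 15.
#' @param min_run Minimum run length in frames.  Default 3.
#' @return A list with `event` (logical), `t_on`, `t_off` (units of `t_s`;
#'   `NA` when no event) and `bin_freq` (the probed bin, Hz).  No exception
#'   is raised for silence.
#' @export
detect_onset_offset <- function(spec, f_probe = 9000, threshold_db = 15,
                                min_run = 3) {
  stopifnot(inherits(spec, "frication_spectrogram"))
  if (f_probe < 0 || f_probe > max(spec$freqs))
    stop_invalid("`f_probe` outside the analysed band")
  bin <- which.min(abs(spec$freqs - f_probe))
  above <- spec$levels[bin, ] > threshold_db
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  keep <- runs$values & runs$lengths >= min_run
  if (!any(keep))
    return(list(event = FALSE, t_on = NA_real_, t_off = NA_real_,
                bin_freq = spec$freqs[bin]))
  starts <- ends - runs$lengths + 1L
  list(event = TRUE,
       t_on = spec$frame_times[min(starts[keep])],
       t_off = spec$frame_times[max(ends[keep])],
       bin_freq = spec$freqs[bin])
}

#' Extent of the longest run above a level
#'
#' Finds the longest contiguous run of a level series above `level` and
#' returns its first and last times — e.g. the extent of OASPL above 60 dB.
#'
#' @param level_series Data frame with columns `time` and a level column
#'   (the second column is used).
#' @param level Threshold, dB.  Default 60.
#' @return A list with `event` (logical) and `t_start`, `t_end` (same units
#'   as `time`; `NA` when the series never exceeds `level`).
#' @export
duration_above <- function(level_series, level = 60) {
  stopifnot(is.data.frame(level_series), nrow(level_series) > 0L,
            ncol(level_series) >= 2L)
  above <- level_series[[2L]] > level
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  keep <- which(runs$values)
  if (!length(keep))
    return(list(event = FALSE, t_start = NA_real_, t_end = NA_real_))
  best <- keep[which.max(runs$lengths[keep])]
  list(event = TRUE,
       t_start = level_series$time[ends[best] - runs$lengths[best] + 1L],
       t_end = level_series$time[ends[best]])
}

#' Time-averaged spectrum over a window
#'
#' Averages per-bin power over all frames whose centre falls in `t_window`
#' and returns the mean spectrum in dB.
#'
#' @param spec A [spectrogram()].
#' @param t_window Length-2 numeric, units of `t_s`.
#' @return Data frame with `freq` (Hz) and `spl` (dB re 20 uPa).
#' @export
spectrum_slice <- function(spec, t_window) {
  stopifnot(inherits(spec, "frication_spectrogram"),
            length(t_window) == 2L)
  sel <- spec$frame_times >= min(t_window) & spec$frame_times <= max(t_window)
  if (!any(sel))
    stop_invalid("no spectrogram frames in t/t_s window [%g, %g]",
                 min(t_window), max(t_window))
  power <- rowMeans(10^(spec$levels[, sel, drop = FALSE] / 10))
  spl <- 10 * log10(power)
  spl[!is.finite(spl) | spl < spec$floor_db] <- spec$floor_db
  data.frame(freq = spec$freqs, spl = spl)
}

#' Spectral peaks by prominence
#'
#' Local maxima of a spectrum ranked by topographic prominence (height above
#' the higher of the two key saddles towards higher terrain).
#'
#' @param spectrum Data frame with columns `freq` and `spl` (from
#'   [spectrum_slice()]).
#' @param min_prominence Minimum prominence, dB.  Default 3.
#' @return Data frame with `freq`, `spl` and `prominence`, sorted by
#'   descending prominence.  Zero rows when nothing qualifies.
#' @export
find_spectral_peaks <- function(spectrum, min_prominence = 3) {
  stopifnot(is.data.frame(spectrum),
            all(c("freq", "spl") %in% names(spectrum)))
  y <- spectrum$spl
  n <- length(y)
  if (n < 3L)
    return(data.frame(freq = numeric(), spl = numeric(),
                      prominence = numeric()))
  is_peak <- which(y[2:(n - 1L)] > y[1:(n - 2L)] &
                     y[2:(n - 1L)] >= y[3:n]) + 1L
  prom <- vapply(is_peak, function(i) {
    h <- y[i]
    left <- y[seq_len(i - 1L)]
    higher_l <- which(left > h)
    key_l <- min(left[seq.int(if (length(higher_l)) max(higher_l) else 1L,
                              i - 1L)])
    right <- y[seq.int(i + 1L, n)]
    higher_r <- which(right > h)
    key_r <- min(right[seq_len(if (length(higher_r)) min(higher_r) else
      length(right))])
    h - max(key_l, key_r)
  }, numeric(1))
  out <- data.frame(freq = spectrum$freq[is_peak], spl = y[is_peak],
                    prominence = prom)
  out <- out[out$prominence >= min_prominence, , drop = FALSE]
  out[order(-out$prominence), , drop = FALSE]
}
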