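# shared fixtures: deterministic test signals built in code

FS <- 44100
NFFT <- 512
DF <- FS / NFFT          # 86.13 Hz bin spacing
HOP <- round(NFFT * 0.7) # 358 samples

# sine at the FFT bin nearest `freq`, so its SPL is exactly representable
bin_tone <- function(freq, amp, dur = 0.5, rate = FS) {
  f <- round(freq / (rate / NFFT)) * rate / NFFT
  n <- round(dur * rate)
  list(freq = f, amp = amp,
       sig = sampled_signal(amp * sin(2 * pi * f * (0:(n - 1)) / rate),
                            rate = rate))
}

tone_spl <- function(amp) 20 * log10(amp / sqrt(2) / 2e-5)

# deterministic multitone: equal-amplitude bin-centred sines, random phases
multitone <- function(n_tones = 40, amp = 0.01, dur = 0.5, seed = 42) {
  with_seed_local(seed, {
    k <- sample(20:230, n_tones)
    ph <- runif(n_tones, 0, 2 * pi)
    n <- round(dur * FS)
    x <- colSums(amp * sin(outer(2 * pi * k * DF / FS, 0:(n - 1)) + ph))
    sampled_signal(x, FS)
  })
}

# seeded evaluation without clobbering the suite RNG
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# band-shaped noise burst with a rectangular envelope between t_on and
# t_off (units of t_s); silence elsewhere apart from a tiny floor
burst_signal <- function(t_on, t_off, t_lo = -0.5, t_hi = 1.5, amp = 0.2,
                         seed = 9, t_s = 175) {
  ts_sec <- t_s / 1000
  n <- round((t_hi - t_lo) * ts_sec * FS)
  t <- t_lo + (0:(n - 1)) / FS / ts_sec
  x <- amp * shaped_noise(n, FS, seed = seed) * (t >= t_on & t <= t_off)
  x <- x + with_seed_local(seed + 1, rnorm(n, sd = 1e-6))
  sampled_signal(x, rate = FS, t0 = t_lo, t_s = t_s)
}

# linear interpolation of the u_c value where u_bar crosses `level`
uc_at_crossing <- function(u_bar, u_c, level, direction = c("up", "down")) {
  direction <- match.arg(direction)
  i <- if (direction == "up") which(u_bar >= level)[1L]
       else which(u_bar < level)[1L]
  u_c[i - 1L] + (level - u_bar[i - 1L]) * (u_c[i] - u_c[i - 1L]) /
    (u_bar[i] - u_bar[i - 1L])
}
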