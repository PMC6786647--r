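# sibilantflow

Tongue kinematics, constriction flow and vortex-sound analytics for the
fricative [s].

## What this is for

When [s] is spoken inside a word, the tongue tip rises toward the palate,
holds, and falls, while the lungs drive a time-varying airflow through the
narrowing channel. The turbulent jet that forms downstream of the
constriction radiates broadband noise (roughly 4–15 kHz), and the sound
does not line up neatly with the articulation: flow fluctuation at the
teeth precedes the sound, and the sound outlasts the tongue's stay at the
[s] position. `sibilantflow` is for researchers in speech production and
aeroacoustics who want to study this coupling quantitatively — with a
physical model's measurements, or entirely in silico.

The package implements:

* **Articulation kinematics** — trapezoidal tongue-height schedules
  h(t) for tongue speeds 10/20/40 mm/s (ascent duration t₁ = h_max/(v·t_s),
  t_s = 175 ms), the affine constriction area
  A_c(h) = 8 + 25·(3 − h) mm², and the quasi-steady mean jet velocity
  **U̅ = Q/A_c** (Q in cm³/s, A_c in mm², U̅ in m/s).
* **Flow profile** — the measured inlet flow Q(t) through its anchors
  (280 → 313 → 184 cm³/s at t/t_s = 0, 0.314, 1), shape-preserving
  interpolation, 100 Hz discretisation, text record I/O.
* **Vortex-ring amplitude estimate** — the radiated pressure
  p′ ∝ ρ∞ (R_v δ_v / R_min²) U_c² (R_p − R_min)/√((R_p − R_min)² + H²)
  with R_min = (4 − h)/2 mm, R_v = 0.1 mm, δ_v = 0.05 mm, R_p = 4 mm,
  H = 1 mm; SPL conversion re 20 µPa; the convection speed U_c as
  windowed RMS of hot-wire velocity.
* **Signal statistics** — 512-point Hann spectrogram with 30% overlap,
  band-limited OASPL (4–15 kHz), the 9 kHz/15 dB onset–offset detector,
  duration-above-level, spectrum slices and prominence-ranked peaks.
* **Synthetic data** — seeded microphone/hot-wire/flow-meter generators
  whose defaults are the study conditions, so the full pipeline is
  testable end to end without recordings.
* **Orchestration** — `run_simulate()`, `run_analyze()`, `run_estimate()`
  with JSON manifests, plus a thin command-line wrapper in
  `inst/cli/sibilantflow.R`.

## Worked example

Simulate the 20 mm/s articulation, synthesise its sensor records, and run
the analysis pipeline on them:

```r
library(sibilantflow)

schedule_from_table(20)
#> Tongue schedule: 20 mm/s, h_max = 3 mm, t_s = 175 ms
#>   ascent  [-0.760, 0.097] t/t_s
#>   plateau [0.097, 0.611] t/t_s
#>   descent [0.611, 1.468] t/t_s

traj <- run_simulate(20)
max(traj$u_bar)          # 39.1 m/s, at t/t_s = 0.315

cfg   <- synthesis_config(20, seed = 1)
paths <- synth_bundle(cfg, "demo")
res   <- run_analyze(paths$microphone, paths$hotwire, t0 = -1.06, speed = 20)

res$event                # sound event spans t/t_s [-0.24, 1.06]
max(res$oaspl$oaspl)     # peak OASPL 92.1 dB (calib = 1 scale)

pk <- find_spectral_peaks(spectrum_slice(res$spectrogram, c(0, 0.8)), 8)
sort(pk$freq[1:2])       # 3962, 9991 Hz — the injected 4 / 10 kHz peaks

curve <- run_estimate(paths$hotwire, speed = 20)
```

Reading these numbers: the mean constriction velocity peaks at
313/8 ≈ 39 m/s when the flow maximum coincides with the fully raised
tongue. The sound event starts before t/t_s = 0 and survives into the
descent, and the estimated level curve is louder on the descent branch
than on the ascent branch at equal U̅ (83.3 vs 71.4 dB at 20 m/s in this
run) — the convection-speed hysteresis the model encodes. Absolute
synthetic levels use a unit calibration constant; only level differences
and curve shapes are meaningful.

The same operations are available from a shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "sibilantflow.R", package = "sibilantflow"))')" \
    synth --speed 20 --seed 1 --out demo
```

## Layout

```
R/                 kinematics, flow_profile, vortex_sound,
                   signal_analysis, synthetic_data, pipeline, wav I/O
tests/testthat/    unit, property and acceptance suites
vignettes/         methods vignette (model, assumptions, design choices)
scripts/           acceptance.R
inst/cli/          command-line front end
```
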