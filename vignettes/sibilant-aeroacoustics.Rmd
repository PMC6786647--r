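---
title: "Modelling tongue movement and sound generation in the sibilant [s]"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tongue movement and sound generation in the sibilant [s]}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibilantflow)
```

## The problem

The sibilant [s] is produced by forcing air through a narrow channel
between the tongue tip and the palate. The jet that forms downstream hits
the teeth and lips and radiates broadband noise, mostly between 4 and
15 kHz. When [s] is spoken inside a word, neither the airflow nor the
constriction is steady: the tongue rises into the [s] position, holds, and
falls again, while the lung pressure drives a time-varying volume flow.
A recurring experimental observation is a *time shift* between articulation
and sound: the flow at the teeth starts fluctuating before the tongue
reaches the [s] position, and the noise persists through the tongue's
descent.

`sibilantflow` implements the computational side of a physical-model study
of this process: a quasi-steady model of the articulation
(tongue-height schedule, constriction area, mean jet velocity), a
vortex-ring estimate of the radiated pressure amplitude, and the signal
statistics used to analyse microphone and hot-wire recordings
(STFT spectrogram, band-limited OASPL, a spectrogram-threshold event
detector, windowed-RMS convection speed). A seeded synthetic-data module
generates microphone, hot-wire and flow-meter records with the statistical
structure the analysis assumes, so the whole pipeline is testable without
laboratory data.

## The articulation model

Tongue height follows a trapezoid in normalised time $t/t_s$, where
$t_s = 175$ ms is the mean duration of [s]: a linear ascent of duration
$t_1$ starting at $t_{int} < 0$, a plateau of duration $t_2$ at
$h_{max} = 3$ mm, and a linear descent. Because the ascent is linear,
$t_1$ is fixed by the tongue speed: $t_1 = h_{max} / (v \, t_s)$. Three
calibrated schedules are built in:

```{r}
for (v in c(40, 20, 10)) print(schedule_from_table(v))
```

The plateau intervals these schedules imply — $[0.05, 0.76]$,
$[0.10, 0.61]$ and $[0.26, 0.46]$ after rounding — are checked in the test
suite. Only ascent speeds are tabulated; the descent is taken at the same
magnitude (the trapezoid is drawn symmetric), and `descent_speed` is a
separate field for anyone who wants to break that symmetry.

The constriction area is affine in tongue height,
$A_c(h) = 8 + 25\,(3 - h)$ mm², and the quasi-steady bulk jet speed is
$\bar U = Q / A_c$. With $Q$ in cm³/s and $A_c$ in mm² this ratio is
already in m/s, so the package performs no hidden unit conversion; heights
outside $[0, h_{max}]$ raise an error rather than being clamped, so
schedule bugs surface at the boundary where they happen.

The inlet flow rate is defined by three measured anchors —
280 cm³/s at $t/t_s = 0$, a 313 cm³/s maximum at $t/t_s = 0.314$,
184 cm³/s at $t/t_s = 1$ — joined by a shape-preserving piecewise-cubic
Hermite interpolant (exact at the anchors, bounded between neighbouring
anchors, zero slope at the interior maximum). A piecewise-linear option
exists for bit-exact tests. Before the first anchor the profile holds the
first value (the preceding vowel still carries flow); after the last it
decays linearly to zero over $0.3\,t_s$. Both tails are model choices —
only the three anchors are measured — and both are configurable.

Composing the two models gives the trajectory of the driving jet:

```{r}
traj <- run_simulate(40)
traj[which.max(traj$u_bar), ]
```

$\bar U$ peaks at $313/8 \approx 39$ m/s with the tongue fully raised, and
is about 35 m/s at the frication onset.

## The vortex-ring amplitude estimate

The radiated pressure amplitude is estimated from an idealised vortex ring
(radius $R_v = 0.1$ mm, core diameter $\delta_v = 0.05$ mm) convecting at
speed $U_c$ through an axisymmetric constriction of radius
$R_{min} = (4 - h)/2$ mm inside a duct of radius $R_p = 4$ mm with axial
constriction length $H = 1$ mm:

$$
p' = C\,\rho_\infty\,\frac{R_v\,\delta_v}{R_{min}^2}\,U_c^2\,
\frac{R_p - R_{min}}{\sqrt{(R_p - R_{min})^2 + H^2}}
$$

The estimate is stated as a proportionality, so the package carries a
dimensionless constant $C$ (`calib`, default 1). $C$ rescales pressure
linearly and shifts every SPL curve by a constant: curve *shapes* are
calibration-invariant, which is what the estimate is used for. The air
density $\rho_\infty = 1.2$ kg/m³ is a package default, not a measured
value. The quadratic $U_c$ dependence means the level difference between
two operating points at the same geometry is $40 \log_{10}$ of the $U_c$
ratio — doubling $U_c$ adds 12.04 dB:

```{r}
p <- vortex_pressure(4.54, r_min_from_height(3))
c(pressure_Pa = p, spl_db = spl(p))
spl(vortex_pressure(9.08, 0.5)) - spl(vortex_pressure(4.54, 0.5))
```

$U_c$ is estimated from hot-wire records as a windowed RMS on exactly the
spectrogram framing (512 samples, 30% overlap), so level and velocity
series share timestamps. The RMS is taken on the mean-removed frame by
default: the reference values of $U_c$ (3–4.5 m/s) are far below the jet's
bulk speed, which identifies them as fluctuation amplitudes; a
`mean_removed = FALSE` flag gives the raw RMS for anyone who reads the
definition the other way.

## Signal statistics

The spectrogram uses 512-point frames, 30% overlap (hop
$\mathrm{round}(512 \times 0.7) = 358$ samples, about 8.1 ms at 44.1 kHz)
and a Hann window. Two scaling conventions are combined deliberately:

* per-bin levels scale the one-sided amplitude spectrum by
  $2/\sum w$, so a calibration sinusoid placed at a bin centre reports its
  true SPL at that bin;
* band sums (OASPL) divide the summed per-bin powers by the window's
  equivalent noise bandwidth $N \sum w^2 / (\sum w)^2$, so the full-band
  OASPL of a frame equals its time-domain SPL (Parseval).

Neither convention is dictated by the measurement recipe; this pair is the
unique choice under which both the tone calibration and the band-power
checks hold simultaneously. A sinusoid halfway between bins still scallops
by up to 1.4 dB at its nearest bin — a property of the Hann window, which
is why the calibration checks use bin-centred tones. Zero or negative
power maps to a −300 dB sentinel rather than −Inf so whole-trajectory
curves stay finite.

OASPL is computed over 4–15 kHz, the band above the first characteristic
spectral peak. The onset/offset statistic is a threshold on the bin
nearest 9 kHz (15 dB by default): onset is the first frame above
threshold, offset the last, with runs shorter than 3 frames rejected as
spikes. The dB reference of the original rendered spectrograms is not
fully specified, so both the probe frequency and the threshold are
arguments, not constants. Silence yields an explicit no-event result
rather than an error.

## What the synthetic data emulates

`synthesis_config()` bundles everything the generator needs. Its defaults
*are* the study conditions: the tabulated schedules, the measured flow
anchors, the 4 and 10 kHz spectral peaks of the physical model's sustained
[s], and per-speed velocity-fluctuation onsets of −0.23, −0.27 and −0.30
$t/t_s$ for 40, 20 and 10 mm/s.

The one mechanism the measurements constrain but do not specify is the map
from $\bar U$ to $U_c$. Two measured points exist — on the 10 mm/s
articulation, $U_c = 3.02$ m/s during ascent and $4.54$ m/s during descent,
both at $\bar U = 26$ m/s — and they encode a hysteresis: the convection
speed lags the jet. The generator realises this with the simplest
mechanism that produces it, a first-order lag,
$U_c(t) = g \cdot \mathrm{lag}(\bar U(t); \tau)$. Both parameters are
calibrated, not asserted: $\tau$ is solved (by `uniroot`) so the
ascent/descent ratio at $\bar U = 26$ matches $4.54/3.02$, then $g$ matches
the descent level. The calibration lands at $\tau \approx 10$ ms and
$g \approx 0.14$, runs on the same 44.1 kHz discretisation as the
synthesis, and is deterministic. With $\tau = 0$ the hysteresis vanishes —
the null case the tests exercise. The lag model is a stand-in for unknown
jet physics; its parameters are exposed, and nothing downstream depends on
its functional form.

The microphone signal is seeded Gaussian noise shaped by two-pole
resonators at the configured peaks, amplitude-modulated so the per-frame
RMS pressure equals the vortex-ring estimate
$p'(U_c(t), R_{min}(h(t)))$, plus a white floor (20 dB SPL). Resonator
bandwidths are $f/Q$ with $Q = 40$ (100 and 250 Hz), chosen so the peaks
are localised at the 86 Hz bin spacing of the 512-point analysis while
remaining plausible sibilant spectral humps. The hot-wire signal is a
slowly varying mean (a crude $3 \times U_c$ proxy for the local jet speed)
plus a zero-mean fluctuation with RMS $U_c(t)$, gated on at the
fluctuation onset with a 5 ms raised-cosine ramp. The flow-meter record is
the profile discretised at 100 Hz. All randomness derives from the
configuration seed; identical configurations give bit-identical files.

What the generator does **not** emulate: physically faithful turbulence
spectra, tract resonances and their motion during articulation, room and
baffle acoustics, the vowels around [s], or the experiment's absolute
OASPL (55–65 dB at 30 cm) — synthetic absolute levels use `calib` = 1 and
are only internally consistent. Passing end-to-end tests therefore shows
that the analysis recovers what the generator injects (event times,
spectral peaks, envelope scaling, hysteresis sign), not that it would
reproduce every property of laboratory recordings.

## Numerical choices and degenerate inputs

* Schedule times are dimensionless ($t/t_s$) everywhere; seconds appear
  only at signal boundaries. Geometry is mm/mm², flow cm³/s, velocity m/s.
* `tongue_schedule()` rejects a supplied $t_1$ inconsistent with
  speed × duration by more than 0.5%; the printed three-decimal table
  values pass this gate.
* Flow interpolation falls back to linear with fewer than three anchors;
  a single anchor is a constant profile.
* The event detectors return explicit no-event results for silence;
  `spl()` maps nonpositive pressure to the configurable floor sentinel.
* Records are written at full double precision (`%.17g`) so text
  round-trips are lossless; WAV output is 32-bit float by default, 16-bit
  PCM on request.
* Problem sizes in the tests: synthetic records span one articulation
  (0.5–0.9 s at 44.1 kHz, 22k–39k samples), spectrograms are 48–105
  frames. The whole suite runs in a few seconds.

## Known limitations

The model is amplitude-only: no tract resonances, no far-field propagation
(the 30 cm microphone distance is not modelled), no frequency content in
the vortex-ring estimate beyond the injected resonances. The quasi-steady
assumption ties $\bar U$ instantaneously to $Q$ and $h$; the only
unsteadiness is the calibrated first-order lag. The pre-onset and
post-offset flow shapes are graphical extrapolations, configurable but not
measured. The event threshold's absolute meaning depends on a rendered-dB
convention the analysis cannot recover from published figures alone.
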