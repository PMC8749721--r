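---
title: "Signal models and design choices in biopad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal models and design choices in biopad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biopad)
```

biopad implements, in software, the complete signal chain of a
forehead-mounted multimodal biosignal pad: the framed binary wire protocol,
the analog-front-end (AFE) unit conversions, the digital filtering stack,
and per-modality analysis pipelines for EEG, electrodermal activity (EDA),
skin temperature (SKT) and photoplethysmography (PPG). Because no hardware
or recordings ship with the package, a seeded synthetic-session generator
stands in for the device; every pipeline is exercised end to end against
the generator's ground truth.

## The wire protocol

The device transmits one 168-byte frame every 50 ms (20 frames per
second): a `0x7F` header, a literal `0xE6` protocol constant, 120 bytes of
EEG (20 ticks x 2 channels x 24-bit two's-complement big-endian ADC
codes, covering 50 ms at 400 Hz), 45 bytes of peripherals (5 ticks at
100 Hz x 9 bytes: EDA u16, SKT u16, PPG red u8, PPG IR u8, and three
signed 8-bit acceleration axes) and one CRC byte.

Two choices here are the package's own. First, the 9-byte peripheral tick:
seven peripheral channels must fit 45 bytes, so the two PPG channels are
carried at 8-bit depth — pulse-rate estimation downstream is spectral and
amplitude-invariant, so waveform shape at 8 bits is sufficient, while EDA
and SKT keep 16 bits for their sub-0.01-unit resolution. Second, the CRC:
the variant is CRC-8 with polynomial `0x31`, reflected, zero initial value
(the Dallas/Maxim sensor-bus convention; check value `0xA1` over
`"123456789"`). `0xE6` is treated as a protocol magic constant rather than
a computed payload length, since no length convention reproduces it.

Stream decoding scans for the two-byte sync pattern, validates each
candidate frame's CRC, and skips (while counting) anything malformed, so
a corrupted region costs only the frames it touches. The diagnostics
satisfy an exact byte-conservation identity that the tests check.

## Unit conversions

The AFE models are closed-form component equations:

* instrumentation-amplifier gain `G = 1 + 19.8 kOhm / Rg` (100 at the
  device's 200 ohm) and `CMRR = 80 dB + 20 log10 G` (120 dB);
* a cascade frequency-response model — first-order high-pass at 0.5 Hz
  (the integral-feedback DC-correction loop, which nulls electrode
  polarization voltage), gain 100, second-order Butterworth low-pass at
  35 Hz, gain 2 — giving a ~200x passband plateau;
* 24-bit bipolar sigma-delta conversion `V = 2 VREF / (2^23 - 1) * L / PGA`
  with `VREF = 2.5 V`;
* the EDA stage's Sallen-Key corner `1 / (2 pi R C)` (5.3 Hz at
  300 kOhm / 0.1 uF) and the divider algebra
  `rho = 16.5 / (8 U - 3.3)` uS;
* the affine SKT sensor law `T = m V + b` with `|m| = 0.1943` degC/mV,
  `b = 213.340` degC.

Two printed constants are dimensionally problematic, and both get a
dual-mode treatment with a physically consistent default. The EDA formula
carries a trailing 10^3 that would put skin conductance in the
thousands-of-uS range; the default `consistent` mode drops it (yielding
1-25 uS over the stage's 0.4-2.4 V output span), and `as_printed`
retains it. The SKT slope applied with a positive sign maps the sensor's
~900 mV output to ~400 degC; the default uses the negative slope
(30-40 degC over the forehead range), with an as-printed option. Both are
selectable per run (`codec_scales()`, CLI flags `--eda-mode`,
`--skt-slope`).

## The filtering stack

Mains rejection uses an IIR comb realizing

    y(n) = (1 + rh0)/2 * [x(n) - x(n - N)] + rh0 * y(n - N)

with `N = 8` and `rh0 = 0.96852105385218623` at 400 Hz: zeros at every
multiple of 50 Hz including DC, each flanked by a pole that holds the
inter-notch response at exactly unity. The analytic notch is infinitely
deep at exactly 50 Hz; where a single attenuation figure is needed (the
`notch_attenuation_db()` helper), the response is read off an
8192-point inclusive grid over `[0, fs/2]`, the convention of plotted
filter responses, giving 32.4 dB at the bin nearest 50 Hz.

The EEG display low-pass is a second-order direct-form-II Butterworth at
30 Hz (designed via `signal::butter()`; the tests verify it against the
closed-form prewarped bilinear magnitude). Application runs the DF2
recursion `w(n) = x(n) - sum a_i w(n-i)`, `y(n) = sum b_j w(n-j)` with
zero initial state — the behaviour of a streaming chain, including its
start-up transient and group delay. For offline analysis a zero-phase
(forward-backward) option squares the magnitude response and cancels
phase; the blink detector and the EDA anti-alias stage use it to keep
event timing. Internally the recursion is evaluated by `stats::filter()`
(a recursive pass followed by a one-sided convolution); the test suite
holds it to 1e-10 agreement with a literal sample-by-sample evaluation of
the two difference equations.

Peripheral channels get order-2 Butterworth low-passes at corners chosen
from each signal's bandwidth, since no values are printed for them: EDA
5 Hz (mirroring the analog Sallen-Key stage), PPG 8 Hz (cardiac content
through the third harmonic at 160 BPM), SKT 1 Hz (quasi-static). All are
overridable.

## EEG analysis

Spectra use Welch's method — 2-s Hann-windowed, mean-removed segments at
50% overlap — scaled so the spectral integral matches the signal variance
(checked by a Parseval test). No estimator is dictated by the hardware;
these are conventional EEG choices. Band power integrates the density by
trapezoid over `(lo, hi]`; alpha dominance is the ratio of relative
8-13 Hz power between eyes-closed and eyes-open epochs of at least 15 s.
The blink detector (zero-phase low-pass below 5 Hz, threshold at 6 scaled
MADs from the median, 0.5-s refractory) is fixture-validation plumbing,
not a published algorithm, and is documented as such.

## EDA analysis

The band-split SNR statistic takes periodogram power in `(0, 5]` Hz as
signal and `(5, fs/2]` as noise, in dB, DC excluded; recordings are
segmented into 10-s windows at 50% overlap (a 150-s recording gives 29
segments) and summarized by mean and standard deviation.

SCR extraction follows the fixed order: anti-alias low-pass (order-8
zero-phase Butterworth at 8 Hz), decimation to 20 Hz, first difference
scaled to uS/s, convolution with a 20-point Bartlett window normalized to
unit sum — so the phasic signal is a smoothed derivative with 1-s support.
The tonic offset is subtracted before filtering and restored afterwards:
the filter starts from zero state, and a 5-uS step at t = 0 would
otherwise ring through the whole chain. Event detection thresholds the
phasic signal at 4 scaled MADs above the baseline median for at least
0.25 s, and matches each onset to the latest stimulus within a 10-s
lookback; the threshold constants are package choices (none are printed
anywhere authoritative).

## SKT analysis

Smoothing is the three-point weighted moving average
`y(n) = 0.8 x(n) + 0.1 x(n-1) + 0.1 x(n-2)` with the first two samples
passed through. The stimulus response is quantified by 5-s edge means:
the delta is the mean over the last 5 s of the stimulus window minus the
mean over its first 5 s (robust to sensor noise, at the cost of reading
~92% of a linear ramp's full drop), plus a least-squares recovery slope.

## PPG analysis

Motion artifact is cancelled by exponentially weighted recursive least
squares with the three acceleration axes as references. The default
topology is a cascade of three single-reference stages (x, then y, then
z) of order 10, forgetting factor 0.999, inverse-correlation
initialization `P = I / 0.01`; a joint multi-reference variant is
available. All constants are package choices — the underlying method's
parameters are not printed — and are config-exposed. Two numerical
safeguards matter in long runs: the inverse-correlation matrix is
re-symmetrized every update and the gain denominator is floored at machine
epsilon, without which round-off can drive the recursion unstable over
tens of thousands of samples. The misadjustment floor of RLS is
proportional to `(1 - lambda) * order * var(d)`, so cancellation depth is
greatest when the artifact dominates the input — precisely the motion
regime the stage exists for.

Pulse rate is estimated per 8-s window in 2-s steps: detrend, Hann
window, zero-padded FFT to at most 0.02-Hz bin spacing, peak search in
0.7-3.5 Hz. Verification: the first window takes the global in-band
maximum; subsequent windows take the local maximum nearest the previous
estimate within a +/-12 BPM collar, falling back to the global maximum if
the collar is empty; finally, if the spectrum holds at least 40% as much
power near half the chosen frequency, the estimate is halved. The
sub-harmonic check both prevents second-harmonic jumps and recovers from
them — a tracker that only vetoes jumps at selection time can lock onto
twice the true rate indefinitely after a strong artifact burst.

Agreement statistics are the average absolute error
`AAE = (1/W) sum |PR_est - PR_true|`, the Bland-Altman bias with
`bias +/- 1.96 sd` limits of agreement, and the Pearson correlation.

## The synthetic-session generator

The generator emulates the stimulus paradigms the device was validated
under, with all randomness derived from one seed:

* **EEG** (400 Hz, 2 channels): pink background noise (10 uV RMS), a
  10-Hz alpha oscillation with slow frequency wander whose amplitude
  follows an eyes-open/closed schedule (20 uV closed, 2 uV open — the
  ~10x amplitude contrast typical of posterior-dominant rhythm),
  asymmetric biphasic blink transients (~100 uV, 300 ms, 10 per minute)
  and a 10-uV 50-Hz mains line.
* **EDA** (100 Hz): 5-uS tonic level with slow drift, bi-exponential
  SCRs (`exp(-t/3) - exp(-t/0.75)`, unit-peak normalized, 0.5 uS)
  starting 2 s after each stimulus, 0.02-uS noise. The 0.75-s rise and
  3-s decay are typical electrodermal time constants.
* **SKT** (100 Hz): 34 degC baseline, a linear 0.2-degC decline across
  the 60-s stimulation window of the 20/60/90-s paradigm, exponential
  recovery, 0.01-degC sensor noise.
* **PPG + accelerometer** (100 Hz): harmonics (1.0, 0.4, 0.15) of the
  phase integrated from a piecewise-linear pulse-rate profile, baseline
  wander, and a motion artifact built by FIR-filtering the acceleration
  channels into the optical signal. Motion bursts are swept sinusoids
  (0.8-2.8 Hz cadence drift, the rhythmic character of head/body motion)
  with a stochastic component; broadband-noise bursts were tried first
  and discarded because they leave the spectral tracker essentially
  undisturbed and so fail to pose the problem artifact cancellation
  solves. The six-minute preset session (30-s lead-in, four 60-s scenes
  separated by 30-s rests) sweeps the rate over 60-100 BPM with a burst
  inside each scene.

What the generator does **not** emulate: heart-rate variability beyond
the programmed profile, pulse-morphology changes, electrode pops and
drift, EDA habituation, thermoregulatory dynamics, or any coupling
between modalities beyond the shared clock. Passing parameter-recovery
tests therefore demonstrates that the pipelines are correct transformations
with the stated statistical behaviour on signals of this class — not that
they would achieve the same figures on human recordings, which ship with
neither the package nor its sources.

Quantization scales map nominal physiological ranges onto most of each
wire field's code span: EEG through the 200x analog gain onto the 24-bit
ADC (LSB ~0.003 uV), EDA and SKT through their voltage laws onto 16 bits
over 0-3.3 V (LSB ~0.0006 uS near 5 uS, ~0.01 degC), PPG +/-8
dimensionless units onto 8 bits, acceleration +/-2 g onto the signed
byte. The round-trip tests bound every channel's reconstruction error by
one code step.

## Problem sizes and numerical conventions

The test suite and acceptance script run at desk scale: 1-240-s synthetic
sessions, a 6-minute pulse-rate session, 1000-frame codec round-trips,
10^4-sample filter-equivalence checks. A full run takes well under a
minute on one core. Degenerate inputs are rejected with classed
conditions (`biopad_config_error`, `biopad_data_error`,
`biopad_integrity_error`) that the CLI maps to exit codes 2 and 3;
zero-length streams decode to empty records; constant signals yield zero
phasic output and are rejected where a correlation would be undefined.
Interchange formats are plain text (CSV, YAML) plus the raw `.bin` packet
stream.

## Known limitations

* The frame layout beyond the header/magic/length identities is this
  package's normative definition; hardware built to a different internal
  layout would interoperate only at the framing level.
* The comb filter does not track mains-frequency drift, and no 60-Hz
  variant is preconfigured (redesign with `design_comb(fs = ...)`).
* SCR events are detected on the smoothed derivative; overlapping
  responses closer than about a second merge into one event.
* RLS cancellation assumes a short, slowly varying linear coupling from
  acceleration to the optical signal; saturation or optical decoupling
  (sensor lift-off) violates that model.
* The spectral tracker bounds rate changes to 6 BPM/s via its collar;
  genuinely faster transitions are followed only after re-acquisition.
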