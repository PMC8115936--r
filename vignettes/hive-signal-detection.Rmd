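---
title: "Detecting honeybee social signals in electrostatic-field recordings"
author: "hiveESF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting honeybee social signals in electrostatic-field recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiveESF)
```

## The measurement and the model

A honeybee's wax-covered body charges triboelectrically, so every
stereotyped body movement inside the hive modulates the local
electrostatic field. Six capacitive sensors facing the dance floor record
this field at 5000 samples/s with 24-bit resolution; two ring sensors in
the entrance tube record passing bees at 100 samples/s; temperature,
humidity and hive-mass telemetry arrives every 120 s. hiveESF implements
the analysis half of such a rig: containers and converters for the three
streams, a ground-truth simulator, and a rule-based detector for the
three signal classes a trained observer can identify in these recordings:

* **Waggle runs (WRS).** The dancing bee waggles her abdomen at 5–25 Hz
  while vibrating her wings at 190–230 Hz; the wing component is only
  partially synchronized with the abdominal cycles. The number of waggle
  cycles in a run scales with the distance to the advertised food source
  at roughly 75 m per cycle, so counting cycles decodes distance.
* **Short pulses (SRS).** Sub-second pulses with fundamentals above
  350 Hz plus harmonics, produced in several behavioral contexts around
  dancing; the package labels them as one class and does not attempt to
  separate the contexts.
* **Fanning (FRS).** Wing-fanning ventilation produces highly regular
  waves at 90–120 Hz lasting longer than 15 s.

## Detection pipeline

Each channel is analyzed at two short-time Fourier resolutions: 1.0 s
windows (0.25 s hop) for the low band, where 5 Hz structure must be
resolved, and 0.2 s windows (0.05 s hop) for the high bands, where
sub-second pulses must not be smeared away. Band edges are half-open
`[lo, hi)` so adjacent bands partition the spectrum without double
counting. Detection operates on per-band mean power traces.

**Segmentation.** A candidate interval opens where a trace exceeds
`k = 4` times its rolling-median baseline and closes when it falls below
half that threshold (hysteresis, to avoid splitting events on power dips).
Two robustness measures matter in practice:

* *Two-pass baseline.* A first pass masks frames above `k` times the
  global lower-quartile level before the rolling median is computed.
  Without this, a band in which events are frequent or long — fanning can
  occupy half of a busy recording — drags its own baseline up and
  suppresses detection. The median window is therefore also per band:
  30 s for the slow low band, 5 s for the pulse bands, and 60 s for the
  fanning band, which must span much more than one > 15 s event.
* *Threshold floor.* Thresholds never fall below `1e-4` of the trace
  peak, so that in near-noiseless material (unit tests, clean sweeps) the
  near-zero baseline does not declare the entire trace active.

**Edge refinement.** Interval edges are refined to the crossing of half
the interior power level, linearly interpolated between frames. For an
event of roughly constant power seen through a symmetric analysis window,
the band power at a frame centered exactly on the event edge is half the
interior level, so this crossing is an unbiased estimate of the true edge
— it removes the half-window smearing that raw threshold crossings carry.

**Classification.** Rules apply in priority order, and every accepted
event consumes overlapping candidates in the other bands of its channel:

1. **FRS**: fanning-band interval longer than 15 s whose waveform has a
   spectral regularity index of at least 0.6;
2. **SRS**: pulse-band interval shorter than 1 s;
3. **WRS**: low-band interval of plausible run duration (0.4–10 s, wide
   enough for 3–30 cycles at 5–25 Hz) that is concurrently active in the
   wing band for at least 30 % of its span, and whose low-band power is
   at least 5 % of the strongest competing band's power over the span.
   The dominance condition rejects "ghost" candidates created by the
   broadband onset of a strong event in another band.

Durations are measured on the STFT frame grid, so the 15 s and 1 s bounds
are compared with a half-hop guard band (0.025 s at the high-band
resolution); accepted spans within the guard are snapped to the bound.
This makes boundary decisions stable under frame quantization while
keeping the emitted events consistent with the class definitions — the
detector never reports an SRS longer than 1 s or an FRS shorter than
15 s.

**Regularity index.** "Highly regular" fanning is quantified as the share
of in-band periodogram power lying within ±2 Hz of the dominant peak
(never less than the Hann main lobe). The ±2 Hz line width is a physical
tolerance — it forgives slow drift and mild cycle-period jitter while
in-band noise, which spreads over the full 30 Hz band, scores near zero.
A jitter-free wave scores 1; the default acceptance minimum is 0.6.

**Waggle counting and distance.** The accepted span is band-passed in
5–25 Hz with an exactly zero-phase spectral-mask filter and cycles are
counted from zero crossings. One cycle contributes one positive-going and
one negative-going crossing, so the count is the rounded mean of the two
crossing counts; this stays correct when a crossing falls exactly on a
span boundary (a single-cycle run counts as 1, not 0). Counts on spans
whose band-passed RMS is below 5 % of the raw RMS are flagged
low-confidence. Distance is `count × 75 m`; bouts (runs on one channel
separated by less than 5 s) report the median member count, a more
stable distance estimate than any single run.

**Cross-channel fusion.** Six sensors face one dance floor, so a real
dance can register on several channels; `fuseChannels()` merges same-label
events overlapping by at least half of the shorter one (transitively),
keeping the strongest channel's features. Fusion is off by default in
`detectSignals()` because the simulator — and any evaluation against
per-channel ground truth — treats channels as independent; field
deployments with correlated channels should enable it.

## The simulator as study condition

The simulator is first-class, tested code; its defaults define the
synthetic study conditions under which the package evaluates itself.

* **Waggle runs**: the abdomen component is a phase-continuous sinusoid
  whose instantaneous frequency ramps up over the first 10 % of the run,
  holds a plateau for 80 % and decays over the last 10 % (default
  excursion 20 %), reproducing the characteristic rise–plateau–fall of
  real runs; run duration is derived so the integrated phase covers
  exactly `nWaggles` cycles. Wing bursts are Hann-gated copies of a
  continuous 190–230 Hz oscillator on an evenly spread 70 % of cycles —
  "partial synchronization" realized as a gating fraction.
* **Pulses**: Hann-windowed fundamentals > 350 Hz with 1/k harmonics.
* **Fanning**: a near-sinusoid with per-cycle period jitter and a 50 ms
  edge taper (wings spin up and down; an instantaneous onset would be a
  nonphysical broadband click).
* **Noise**: white + 1/f pink (power slope −1) + 50 Hz mains (the
  deployment-region grid frequency, configurable) + band-limited
  (< 30 Hz) random-walk "crowd" clutter standing in for many bees moving
  in front of a sensor.
* **SNR**: band-local — each event component is scaled so its RMS over
  the event span is `10^(SNR/20)` times the RMS of the channel noise
  band-passed to that component's band over the same span. For waggle
  runs the abdomen and wing components are scaled against their own
  bands separately.

What the simulator does *not* emulate — multiple simultaneous dancers on
one sensor, sensor drift, comb vibrations, electrode artifacts — bounds
what green tests mean: they demonstrate correct rule behavior and
detection at defined SNR on the modeled signal families, not field
performance on real colonies, where conservative thresholds historically
miss a substantial share of visually identifiable runs.

## Numerical choices

* **Band-pass filtering** uses a zero-phase FFT mask with raised-cosine
  transitions rather than a recursive design: at 5–25 Hz on a 5 kHz
  stream the normalized corner frequencies are ~0.002, where
  transfer-function IIR filtering is numerically divergent in double
  precision. The mask is exactly zero-phase (cycle positions used for
  waggle counting are not shifted) and exactly idempotent in-band.
* **Long FFTs** (noise synthesis, filtering) are zero-padded to
  2-3-5-smooth lengths; R's mixed-radix FFT degrades to quadratic cost on
  lengths with large prime factors.
* **Spectrogram scaling** is a one-sided density such that
  `sum(power) * df * sum(w^2)` per frame equals the frame's windowed
  energy exactly (Parseval), which the tests verify to 1 %.
* **Ties and degenerate inputs**: empty recordings produce empty (not
  erroneous) spectrograms and event tables; an all-zero trace yields no
  candidates; evaluation with no detections reports precision 0 with an
  explicit `precision_undefined` flag.

## Evaluation scale

The package's own acceptance checks run on a seeded benchmark scenario of
150 events (50 per class, parameters drawn from their natural ranges)
spread over the six channels of a ~5 min recording at 10 dB band-local
SNR, where the detector reaches precision and recall of at least 0.9 per
class; waggle-count recovery is checked over 3–30 cycles with five
repeats each. These sizes keep the full suite under a minute on one CPU
while exercising every rule path; they are stated here so that larger
replications can scale them up deliberately.

Two figures often quoted for band/duration rules are recovered
*operationally* rather than asserted: sweeping clean constant-envelope
tone bursts through the detector locates the fanning acceptance boundary
at 15 s and the short-pulse boundary at 1 s (`sweepDurationBoundary()`),
confirming that the implemented rules, measurement smear and guard bands
compose to the intended constants.

## Known limitations

* The classifier is rule-based by design; no learned model is included.
* Dance direction (waggle-run angle) is not decoded — only distance.
* SRS subtypes (begging, stop, whooping) are not separated.
* Entrance counting does not distinguish arriving from departing bees.
* Duration measurement of strongly amplitude-tapered pulses (e.g. the
  simulator's Hann-windowed SRS) reads the half-level support, which is
  shorter than the full taper support; classification is tolerant of
  this, but reported SRS spans are conservative.
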