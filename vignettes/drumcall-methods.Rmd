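---
title: "Feature-based detection of sciaenid fish calls: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-based detection of sciaenid fish calls: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Passive acoustic monitoring of estuaries in the Southeast United States
produces tens of thousands of short hydrophone recordings per season. The
dominant biological sound sources are snapping shrimp and the courtship
calls of sciaenid fishes — black drum (*Pogonias cromis*), silver perch
(*Bairdiella chrysoura*), spotted seatrout (*Cynoscion nebulosus*), and red
drum (*Sciaenops ocellatus*). Counting calls by ear does not scale (and is
impossible during chorusing), so `drumcall` implements a feature-based
(template-matching) signal detector: representative calls are stored as
time-by-frequency surfaces of sound pressure level, and each recording is
scanned for windows that correlate strongly with a template.

## From waveform to calibrated spectrogram

A recording is a vector of dimensionless ADC amplitudes `y` sampled at
`fs` (80 kHz in the reference deployment). The recorder chain —
hydrophone sensitivity `h` (dBV/uPa), gain `g` (dB), ADC full-scale
voltage `Vadc` — defines a constant correction factor

    S = h + g + 20 log10(1 / Vadc)

and any uncalibrated dB level `b` becomes sound pressure level
`a = b - S` in dB re 1 uPa. With the default chain (`h = -186`, `g = 20`,
`Vadc = 1`), `S = -166` dB. For broadband levels the package uses the
standard RMS definition `b = 10 log10(mean(y^2))`; a doubled-dB variant
(`20 log10(mean(y^2))`) seen in some calibration write-ups is available as
`mode = "printed"`. Because the matching score below is invariant to any
constant dB offset, this choice cannot change detection results, only
absolute reported levels.

The signal is then reorganized into a matrix of data frames: frame window
`w` samples long, successive frames starting `p` samples apart (the
repetition parameter), so adjacent frames share `w - p` samples. The two
resolutions follow directly:

* time step between frames: `dtau = p / fs` (with `p = 1`, the sample
  period itself);
* frequency resolution: `df = fs / w`.

Each frame is transformed with a `w`-point DFT under a rectangular taper
(the framing construction implies no taper), converted to a single-sided
amplitude spectrum in dB, floored at -200 dB so digital silence stays
finite, and calibrated by subtracting `S`. The result is an
`SPLSpectrogram`: frames x bins, bin centers at `n * df`.

The `(w, p)` trade-off is species-specific. At `fs = 80` kHz and
`w = 4096`, `df = 19.53` Hz, and the narrow 80-400 Hz black drum band
spans only 16 bins — finer `df` (larger `w`) suits long narrowband
callers, while short pulsed calls need fine `dtau` (small `p`, smaller
`w`). The shipped defaults are `w = 8192, p = 2048` for black drum,
`w = 2048, p = 256` for silver perch and red drum, and
`w = 4096, p = 512` for spotted seatrout; all are configuration, not
ground truth, and can be overridden per library.

## Templates and the matching score

A `CallFeature` is a sub-matrix of a calibrated spectrogram covering one
representative call (rows: call duration; columns: the frequency bins of
the species band; values: SPL — the "3D surface" of the call). A
candidate window `B` of the same shape is scored against template `A`
with the normalized centered correlation

    s = sum((A - mean(A)) * (B - mean(B))) /
        sqrt(sum((A - mean(A))^2) * sum((B - mean(B))^2))

which is the product-moment correlation of the flattened matrices:
bounded in [-1, 1], invariant under affine rescaling of either surface.
Silence (zero variance) is defined to score 0 so it can never match.

Scanning slides the template along time only — frequency rows stay fixed
at the species band; variation in a species' upper frequency is handled
by multiple templates and by the *partition plane*, a frequency cut-off
that removes template columns above a chosen frequency so the retained
low-frequency structure generalizes across calls (the shipped black drum
templates include copies cut at 280 Hz for exactly this reason: their
upper harmonics move a whole bin under natural fundamental-frequency
variation, while the first two harmonics stay put).

Offsets scoring at least the species threshold `theta` become candidate
detections; candidates within one suppression window (default: one
template duration) of a higher-scoring candidate are suppressed, with
ties broken toward the earlier offset, so one call yields one detection.
Detections from different templates of the same species are merged the
same way. Counts per file and per species are the survivors.

Two settings are deliberately explicit configuration because no
principled universal value exists:

* **Threshold `theta`** — calibrated on the synthetic benchmark (below):
  0.5 for black drum (its true-match scores spread lower under natural
  fundamental variation while cross-species scores stay below ~0.45) and
  0.6 for the other species, stored per species in the library
  configuration.
* **Suppression window** — defaults to the template duration; dense
  choruses whose calls start closer together than this are undercounted
  by construction. This undercount is intrinsic to counting by
  non-maximum suppression and is why chorusing files are better treated
  as an intensity category than an exact count.

## The synthetic soundscape generator

Field recordings with exhaustive ground truth do not exist at the scale
needed to calibrate and test a detector, so the package generates them.
The generator emulates the qualitative structure of each species'
repertoire:

* black drum: tonal harmonic calls (fundamental ~100-130 Hz, energy
  within 80-400 Hz, smooth rise/fall envelope);
* silver perch: trains of 5-13 broadband damped pulses (80-5000 Hz) at
  ~12 pulses/s;
* spotted seatrout: grunts (fast ~22 pulses/s trains), drums, and
  staccatos (~21 pulses whose inter-pulse interval shrinks toward the
  call's end);
* red drum: slow 3-5 pulse calls at ~7 pulses/s in the low band;
* background: Gaussian noise plus Poisson-timed broadband snapping-shrimp
  impulses; optional low-frequency burst-modulated "boat" noise.

Morphology constants (pulse widths, damping, carrier frequencies) are
synthesis conventions chosen once to match the described call structure;
they are arguments, not measurements. Injected calls are scaled to a
requested **in-band SNR**: the ratio of call band power to background
band power inside the species band, so "20 dB" means the call stands
20 dB above the background it must be detected in. Every clip carries a
JSON manifest (species, onsets, durations, SNRs, scales, seed) from
which precision and recall are computable exactly.

`makeBenchmark()` assembles the fixed evaluation suite per species:
isolated single calls, multi-call clips with well-separated calls,
chorus clips whose consecutive calls always overlap, shrimp-heavy clips,
boat-noise-masked clips, and background-only clips. Benchmark clips are
8 s at 80 kHz — long enough for three well-separated calls plus margins,
small enough that the full suite (25+ clips per species) generates and
scans in minutes; `assembleSoundscape()` itself defaults to the field
schedule of 2-minute clips. Detector recovery is reported over the
conditions whose events are non-overlapping and at the stated SNR
(isolated, multi, shrimp-heavy); the boat-noise condition deliberately
masks calls below the nominal SNR and the chorus condition deliberately
overlaps them, so those two probe failure modes rather than the recovery
claim.

Because templates are extracted from the same synthesizer that creates
the benchmark calls (with jittered fundamentals, pulse rates, onsets,
and independent noise), a passing benchmark demonstrates the detector's
arithmetic, thresholding, suppression, and counting — it does not prove
field-level accuracy on real calls, whose within-species variability,
propagation effects, and co-occurring species are richer than the
simulation. The evaluation module is exactly the tooling needed to
measure that on annotated field data.

## Evaluation statistics

* **Identification rate**: `IR = (a - b - c)/a * 100` over files, where
  `b` files have false negatives and `c` false positives at the
  presence/absence level.
* **Calling-intensity categories**: 0 none, 1 one call, 2 multiple
  calls, 3 overlapping calls or chorus; recovered from manifests by a
  pairwise overlap test.
* **Nightly aggregation**: sums over noon-to-noon windows (on a
  20-minute file grid this is "12:00 to 11:40 the next day"); the
  half-open `[12:00, 12:00+24h)` convention avoids boundary
  double-counting on any grid. Nights without files are missing, not
  zero.
* **Correlation**: Pearson product-moment correlation with the standard
  t-transform p-value between aligned nightly series.
* **Covariates**: water temperature anomaly (observed minus a 30-day
  moving average — centered and symmetric by default, so a linear
  seasonal trend has zero anomaly in the interior; trailing alignment
  available), lunar phase category (new moon days 27-4 wrapping, first
  quarter 5-11, full moon 12-19, third quarter 20-26 — a partition of
  the 30-day cycle), daily tidal range, and civil day length. Windows
  with gaps are flagged missing rather than filled.

## Numerical choices and degenerate inputs

* dB floor at -200 dB for zero-magnitude bins keeps matrices finite;
  all-silent windows then have zero variance and score 0.
* Indexing is 0-based for frames/bins in the arithmetic (`[n*p,
  n*p + w)` half-open sample windows); trailing samples that cannot fill
  a window are dropped, never zero-padded.
* The scanner computes the correlation numerator by direct (not FFT)
  column-wise cross-correlation and the window statistics by moving
  sums, so scan scores match a brute-force per-offset evaluation to
  ~1e-12.
* `p` is accepted over the full inclusive range `1 <= p <= w`; `p = 1`
  is the maximal-overlap limit in which the frame step equals the sample
  period.
* Band membership of a bin center is judged with a small relative
  tolerance so bands specified exactly at bin centers are inclusive.
* All-zero segments passed to the broadband level are an error by
  default (or `-Inf` with a warning on request) — never a silent `NaN`.

## Known limitations

* Counting in dense chorus undercounts by design (suppression window);
  treat category-3 files as intensity, not counts.
* Templates sit at fixed frequency rows: a call transposed in frequency
  (e.g. temperature-driven fundamental shifts) needs its own template or
  a partition-planed variant.
* The WAV codec covers integer PCM (8/16/24/32-bit) and 32-bit float;
  proprietary recorder formats must be converted upstream.
* Day length uses civil sunrise/sunset only; no twilight correction.
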