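# drumcall

Feature-based detection, classification, and quantification of sciaenid
fish calls in estuarine soundscapes.

Estuaries of the Southeast United States are monitored with bottom-mounted
hydrophone recorders that capture short clips around the clock. The loudest
biological contributors are snapping shrimp and four soniferous fishes of
the family Sciaenidae — black drum (*Pogonias cromis*), silver perch
(*Bairdiella chrysoura*), spotted seatrout (*Cynoscion nebulosus*), and red
drum (*Sciaenops ocellatus*) — whose courtship calling tracks spawning.
Counting calls manually does not scale to the tens of thousands of files a
season produces. `drumcall` is for the scientists running such programs:
it turns raw WAV files into calibrated spectrograms, scans them with a
library of species call templates, counts calls per file, and compares the
automatic counts against manual annotations and environmental covariates.

## The method

1. **Calibration.** ADC amplitudes become sound pressure level through the
   recorder chain's correction factor `S = h + g + 20 log10(1/Vadc)`
   (default `h = -186` dBV/uPa, `g = 20` dB, `Vadc = 1` V, so
   `S = -166` dB); a level `b` in uncalibrated dB is `a = b - S` in dB re
   1 uPa.
2. **Framing.** The signal is reorganized into a matrix of data frames of
   `w` samples starting `p` samples apart, giving time step `dtau = p/fs`
   and frequency resolution `df = fs/w`; a `w`-point rectangular-taper DFT
   per frame yields the calibrated time x frequency SPL matrix.
3. **Template matching.** A call template `A` (a time x frequency SPL
   surface restricted to the species band) is slid along time; each window
   `B` is scored with the normalized centered correlation

       s = sum[(A - mean A)(B - mean B)] /
           sqrt(sum(A - mean A)^2 * sum(B - mean B)^2)  in [-1, 1].

   Windows with `s >= theta` survive non-maximum suppression and are
   counted as calls.
4. **Evaluation.** Automatic versus manual per-file presence gives the
   identification rate `IR = (a - b - c)/a x 100`; nightly (noon-to-noon)
   sums are compared by Pearson correlation; covariates include the
   30-day-moving-average temperature anomaly and lunar phase categories.

A seeded synthetic-soundscape generator (harmonic black drum calls, pulse
trains, staccatos, snapping shrimp, boat noise) produces calibrated clips
with ground-truth manifests, so the whole pipeline is testable and
calibratable without field data. See `vignette("drumcall-methods")`.

## Worked example

Synthesize a two-call clip, build the default template library, and count:

```r
library(drumcall)

lib <- buildDefaultLibrary(seed = 1)
res <- assembleSoundscape(
  events = list(list(species = "silver_perch", onsetS = 2, snrDb = 20),
                list(species = "silver_perch", onsetS = 5, snrDb = 20)),
  durationS = 8, seed = 42, clipId = "demo")
summary <- detectFile(res$clip, lib, sourceFile = "demo")
summary
#> FileDetectionSummary: demo
#>   black_drum: 0 call(s)
#>   silver_perch: 2 call(s) (best s = 0.880)
#>   spotted_seatrout: 0 call(s)
#>   red_drum: 0 call(s)
detections(summary)[, c("species", "timeOffset", "score")]
#>        species timeOffset     score
#> 1 silver_perch     2.0864 0.8797297
#> 2 silver_perch     5.0016 0.8771792
```

Both injected silver perch calls are recovered at their onsets (the
time offsets are quantized to the 3.2 ms frame hop) with matching scores
near 0.88, and no other species fires. Against the clip's manifest this
gives precision and recall of 1:

```r
evaluateRecovery(detections(summary), list(demo = res$manifest), lib)
#>        species nEvents nDetections tp fp fn precision recall
#> 1 silver_perch       2           2  2  0  0         1      1
```

A shell entry point wrapping the same functions ships in
`inst/cli/drumcall` (subcommands `synth`, `build-library`, `detect`,
`evaluate`, `show-config`).

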