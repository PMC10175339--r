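# rgbtresp

Contactless respiratory-rate (RR) estimation from paired visible and thermal
(RGB-T) video.

Exhaled air is warmer than inhaled air, so the skin around the nostrils
oscillates in temperature at the breathing frequency — a signal a long-wave
infrared camera can read without touching the patient. That matters most in
neonatal intensive care, where adhesive impedance electrodes irritate and can
damage premature skin. Thermal imagery alone, however, is too coarse to find
and follow the nostrils reliably. `rgbtresp` implements the dual-stream
solution: a co-mounted visible camera supplies facial landmarks for nostril
ROI selection and tracking-by-detection, a two-phase registration (checkerboard
rig scale adjustment + phase-congruency keypoint matching with a
fast-sample-consensus affine fit) maps visible pixels to thermal pixels, and
the mean-ROI thermal series is despiked (Hampel), smoothed, bandpass filtered
(2nd-order zero-phase Butterworth; 0.1–0.85 Hz adults, 0.5–1.5 Hz neonates)
and analysed in 30 s windows stepped by 20 s with a chirp-Z transform:

```
RR(window) = 60 · argmax_{f ∈ band} |CZT{filtered signal}(f)|   [bpm]
```

The nostril box comes from five landmarks — nose tip `(nx, ny)` and mouth
corners `(mlx, mly)`, `(mrx, mry)`:

```
η = round(√((mlx−nx)² + (mly−ny)²) / 4),   ω = round(|mlx − mrx| / 2)
ROI = [nx − ω, ny − η, 2ω, 3η]
```

Agreement with a reference (e.g. a 10 Hz respiration belt) is summarised by
the average absolute error (AAE), its standard deviation (SDE), Pearson
correlation and Bland–Altman limits of agreement. Because no public dataset
exists for this setup, the package ships a ground-truthed synthetic RGB-T
scene generator (breathing thermal face, fiducial landmarks, known
inter-camera affine, calibration-rig frames, motion/occlusion events) that
exercises every stage end to end.

Intended users: researchers in camera-based vital-sign monitoring and
biomedical image analysis who need a reproducible, fully testable reference
implementation of the RGB-T respiration pipeline.

## Worked example

Simulate a 90 s neonatal recording breathing at 48 bpm behind a scale-3
camera disparity, calibrate from a rig frame pair, and run the full pipeline:

```r
library(rgbtresp)

spec <- scene_spec(duration_s = 90, seed = 7, noise_sd = 0.3 / sqrt(2 * 10))  # 10 dB SNR
sc   <- generate_scene(spec)
rig  <- generate_rig_pair(spec$true_map, seed = 7)
cfg  <- pipeline_config("neonate", seed = 7)
res  <- run_pipeline(sc$seq, cfg, rig_pair = list(rgb = rig$rgb, thermal = rig$thermal))

res$map
#> <affine_map provenance=composed inliers=54 rms=0.8486>
#>              [,1]         [,2]     [,3]
#> [1,] 0.3333211084 -0.000379218 2.123379
#> [2,] 0.0006636795  0.332552144 1.205685

res$rr[, c("window_start", "window_end", "rr_bpm", "spectral_peak_ratio", "quality")]
#> # A tibble: 4 × 5
#>   window_start window_end rr_bpm spectral_peak_ratio quality
#>          <dbl>      <dbl>  <dbl>               <dbl> <chr>
#> 1            0         30     48                42.5 ok
#> 2           20         50     48                41.9 ok
#> 3           40         70     48                41.9 ok
#> 4           60         90     48                40.5 ok
```

The recovered registration matrix is the ground-truth scale-1/3 similarity to
a fraction of a thermal pixel, and all four windows report exactly 48 bpm
with spectral peaks ~40× the whitened in-band noise floor. `autoplot(res$rr)` plots the
windowed series; `metrics_report(res$rr, reference_rr)` with
`plot_bland_altman()` / `plot_correlation()` summarise agreement against a
belt-derived reference.

A command-line interface over the same functions lives at
`inst/cli/rgbtresp.R` (`simulate`, `register`, `run`, `evaluate`).

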