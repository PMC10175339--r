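---
title: "Contactless respiratory rate from RGB-T video: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contactless respiratory rate from RGB-T video: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The measurement principle

Exhaled air is warmer than inhaled air, so the skin around the nostrils of a
breathing subject shows a periodic temperature oscillation at the breathing
frequency. A long-wave infrared camera sees this oscillation directly, without
contact — attractive for neonatal monitoring, where adhesive electrodes damage
premature skin. Thermal imagery, however, is a poor substrate for detecting
and tracking the nostril region itself: resolution is low and anatomical
contrast weak. This package therefore implements a dual-stream design: a
visible (RGB) camera, co-mounted with the thermal camera, provides facial
landmarks for region-of-interest (ROI) selection and tracking; a linear map
from visible to thermal pixel coordinates transfers the ROI; and the thermal
stream supplies the respiratory signal.

The chain is: **register** the two cameras → **select and track** the nostril
ROI in the visible stream → **map** the ROI into the thermal stream →
**extract** the mean-ROI temperature series → **filter** it → **estimate**
the respiratory rate (RR) per sliding window → **evaluate** agreement against
a reference.

# Two-phase RGB-T registration

The cameras differ strongly in resolution (960×720 vs 320×240 by default), so
registration is split in two phases.

**Phase 1 — rig-based scale adjustment.** A checkerboard rig cut from a
poorly heat-conducting material is visible in both modalities (with inverted
contrast in the thermal image). Inner corners are found by a polarity-agnostic
multi-scale quadrant-contrast detector (summed-area tables; subpixel peak
interpolation), ordered row-major, and a similarity transform — isotropic
scale plus translation; rotation optional and off by default, since the
cameras are parallel and co-mounted — is fitted by least squares
(`scale_adjust_from_rig()`). Corner ordering assumes a near-axis-aligned
board (rotations up to a few degrees), which matches how a calibration rig is
held in practice.

**Phase 2 — phase-congruency refinement.** Residual misalignment is corrected
by feature registration that works *across* modalities because it relies on
phase rather than intensity. For image $I$, a bank of 2-D log-Gabor quadrature
filters (scales $k$, orientations $o$) yields even/odd responses
$ER_{ko}, OR_{ko}$ and amplitudes $MR_{ko}=\sqrt{ER_{ko}^2+OR_{ko}^2}$.
Per-orientation phase congruency is

$$PC_o = \frac{\omega_o \,\max\!\big(\textstyle\sum_k E_{ko} - T_N,\, 0\big)}
              {\sum_k MR_{ko} + \varepsilon},$$

where $E_{ko}$ projects each scale's response onto the unit mean-phase vector
(and subtracts the orthogonal component), $T_N$ is a noise threshold, and
$\omega_o$ a sigmoidal weight penalising narrowband (single-scale) responses.
Two readings in the printed presentations of this formula are ambiguous and
were resolved as follows:

* the total amplitude normalising the mean-phase vector is computed as
  $AR_o=\sqrt{(\sum_k ER_{ko})^2+(\sum_k OR_{ko})^2}+\varepsilon$ — the
  vector-magnitude form — because a sum of *signed* responses under a single
  square root can be negative and destroys the unit-vector geometry of the
  mean-phase terms;
* the noise threshold is applied once to the scale-summed energy rather than
  per scale, since soft-thresholding each scale separately subtracts the
  noise estimate $n_{scales}$ times.

$T_N$ itself is not specified by any closed form in the literature this
design follows; we estimate it per orientation from the smallest-scale
amplitude response under a Rayleigh noise model (median-based estimate of the
Rayleigh scale, propagated through the scale sum) and multiply the noise
standard deviation by `noise_k` (default 2.0).

Classical moment analysis of the per-orientation congruency stack produces the
maximum and minimum moment maps $M$ (large on edges *and* corners) and $m$
(large only on corners). The FAST segment test (contiguous arc of 12 on the
16-pixel Bresenham circle, 3×3 non-maximum suppression) runs on the min-max
normalised $M$ and $m$; keypoints are described by SIFT-like histograms of
the *dominant-orientation index map* (argmax over orientations of the
scale-summed amplitude, ties to the lowest index — invariant under positive
intensity scaling, hence usable across modalities); matching is
sum-of-squared-differences with a nearest-neighbour distance-ratio test and
mutual-best filtering; and the affine map is estimated by fast sample
consensus (FSC): minimal 3-point samples propose a fit, inliers are collected,
and the fit is re-estimated on the growing consensus set until the inlier set
is a fixed point. The final map is the refinement composed with the rig map.

*Registration cadence.* The rig map is computed once per session from a
designated calibration pair, the refinement once on the first scene pair, and
the composed map held fixed for the recording — the cameras are rigidly
co-mounted, so the geometry is static. Per-frame re-registration is a
non-goal.

Defaults (all exposed): 4 scales, 6 orientations, minimum wavelength 3 px,
scale multiplier 2.1, $\sigma/f$ 0.55, $\varepsilon=10^{-4}$ — conventional
phase-congruency settings; descriptor patch 72 px with a 6×6 grid; NNDR 0.85;
FSC 2000 iterations with a 2 px inlier tolerance and a mandatory seed.

# ROI selection and tracking-by-detection

Five facial landmarks (eye centres, nose tip, mouth corners) define the
nostril box. With nose tip $(n_x, n_y)$ and mouth corners
$(ml_x, ml_y), (mr_x, mr_y)$:

$$\eta = \mathrm{round}\!\left(\tfrac{1}{4}\sqrt{(ml_x-n_x)^2+(ml_y-n_y)^2}\right),
\qquad \omega = \mathrm{round}\!\left(\tfrac{1}{2}|ml_x - mr_x|\right),$$
$$ROI = [\,n_x-\omega,\; n_y-\eta,\; 2\omega,\; 3\eta\,].$$

Rounding is round-half-to-even (base R `round`). Degenerate geometry
($\eta=0$ or $\omega=0$) is an error; boxes below 2×2 px after clipping count
as detection failure.

The landmark *detector* is a declared contract
(`frame -> list(landmarks, confidence)`): production systems plug in a
pretrained face-landmark network here; this package bundles a
synthetic-fiducial detector that locates the intensity-coded markers planted
by the scene generator. Training or bundling a face network is out of scope —
the pipeline logic, not face appearance modelling, is under test.

Tracking is by detection (TD): a normalised-cross-correlation template
tracker (search radius 8 px, exponential template update with learning rate
0.075, quality = correlation peak) runs while tracking is enabled, the
detector runs every frame, and a selection operator arbitrates via the status
flags $t_s$ (tracking) and $d_s$ (detection):

* $(t_s, d_s) = (\mathrm{T}, \mathrm{T})$: the tracked box is the ROI and
  tracking stays enabled;
* any flag false: tracking is disabled, the ROI comes from detection (or is
  recorded as missing), and a successful re-detection reinitialises the
  tracker.

The first frame always runs detection. The tracker-failure criterion is not
prescribed anywhere authoritative; this package declares $t_s$ false when the
correlation peak drops below `quality_threshold` (default 0.5) — a documented
module decision. The detection confidence threshold defaults to 0.6. The ROI
success rate is $100 \cdot \text{frames with ROI} / \text{total frames}$.

# Respiratory signal and rate estimation

Each frame's ROI is mapped into thermal coordinates (corner mapping, outward
rounding to whole pixels, clipping), and the raw signal is the plain mean of
the W×H mapped ROI. Frames without an ROI are marked invalid and gap-filled
by linear interpolation between neighbouring valid samples (edges held);
gaps longer than 2 s flag the overlapping windows as low quality. The
conditioning chain, applied to the whole record, is:

1. **z-score normalisation** (flat signals are an error);
2. **Hampel despiking** — half-window one second, 3 robust SDs
   ($1.4826\cdot$MAD, MAD floored at $10^{-9}$ so spikes in flat
   neighbourhoods are still caught);
3. **moving average** — centred, `round(fs/3)` forced odd (≈ 0.37 s at
   30 fps), partial windows at the edges;
4. **2nd-order Butterworth bandpass** — −3 dB at the band edges;
   [0.1, 0.85] Hz for adults, [0.5, 1.5] Hz for neonates. The filter is
   applied forward–backward (zero phase), with odd-reflection padding to
   suppress start-up transients; zero-phase filtering is a deliberate choice
   over a single pass, which would lag and distort the breathing waveform.

RR is estimated in 30 s windows advanced by 20 s (the clinical counting
interval, with the step chosen so consecutive windows share 10 s). Within the
band the spectrum is evaluated on a 0.005 Hz grid (0.3 bpm) by the chirp-Z
transform (Bluestein's FFT-convolution algorithm, implemented in-package) —
i.e. spectral zooming well below the 1/30 Hz rectangular-window resolution.
The in-band magnitude peak gives $RR = 60 f_{peak}$ (ties toward the lower
frequency). The quality score is the peak-to-median ratio of the in-band
magnitudes computed on a *whitened* spectrum: because the window passed
through the bandpass, the in-band noise floor is coloured by the filter's
magnitude response, which would bias a raw peak/median ratio upward near the
band centre; dividing the magnitudes by the known forward–backward response
$|H(f)|^2$ restores a flat noise floor (the peak location itself is taken
from the unwhitened spectrum). Windows whose whitened ratio falls below 4
are reported as 0 bpm with quality `"none"`: whitened in-band noise reaches
ratios of about 3, while genuine breathing peaks at 10 dB SNR exceed 10, so
4 separates "no breathing component" (e.g. a breath pause) from a detectable
rate with a wide margin.
One caveat follows directly from zero-phase filtering: the chain's response
settles over roughly $1/f_{low}$ seconds, so a window straddling the instant
breathing *stops* still contains genuine smeared breathing energy and may
legitimately report the pre-pause rate; only windows starting about
$1/f_{low}$ s into a pause measure the pause itself.

The reference RR from a respiration belt (10 Hz force series) is derived by
the *same* windowing, conditioning and chirp-Z chain at the belt's native
rate — a documented assumption, since breath-counting is an equally plausible
but unstated alternative.

# Agreement metrics

With measured and reference rates $BR_m(k), BR_r(k)$ over $N$ aligned
windows and $AE(k) = |BR_m(k)-BR_r(k)|$:

$$AAE = \tfrac{1}{N}\sum_k AE(k), \qquad
SDE = \sqrt{\tfrac{1}{N-1}\sum_k (AE(k)-AAE)^2},$$

plus Pearson correlation and Bland–Altman mean difference with
$\pm 1.96\,SD$ limits of agreement (sample SD throughout). Series are aligned
by window start time and must share the window/step configuration.

# The synthetic scene generator

No public dataset accompanies this class of recordings, so validation runs on
a ground-truthed generator (`generate_scene()`). It emulates the acquisition
geometry — 30 fps, 960×720 visible and 320×240 thermal frames, a known
visible→thermal similarity (default scale 1/3 with a small translation) — and
the physics that matter to the pipeline:

* a warm face ellipse (34 °C) over a 28 °C background, with a nostril patch
  oscillating as $baseline + A\sin(2\pi f t)$ (defaults 33 °C, A = 0.3 °C, a
  physiologically plausible nasal-airflow oscillation);
* thermal sensor noise, Gaussian, default SD 0.05 °C (the sensitivity class
  of the thermal cameras this design targets). Where a scene SNR is stated,
  it is defined per pixel as $10\log_{10}\!\big((A^2/2)/\sigma^2\big)$;
  ROI averaging raises the effective SNR of the extracted signal further.
  Visible-stream noise is uniform of the stated SD (an 8-bit sensor under
  good light is quantisation-dominated);
* five intensity-coded plus-shaped fiducial markers at the landmark
  positions (the detector contract, not face appearance, is under test);
* static structural objects (discs and squares) rendered coherently in both
  modalities — analytically in each coordinate frame, so the streams are
  related *exactly* by the ground-truth map with no interpolation error;
* motion events (piecewise-constant translation) and occlusion events applied
  coherently to both streams;
* piecewise breathing waveforms (`mode_c_waveform()`): phase-continuous
  sinusoid segments; a pause freezes the phase and decays the value with a
  2 s time constant, so segment joins are free of step discontinuities.

All randomness flows from the single scene seed, so identical specs produce
bit-identical frames. Frames are rendered lazily, so each frame's noise is
drawn under its own sub-seed — and those sub-seeds are themselves *sampled*
from the master stream rather than derived arithmetically: streams seeded
with linearly related values are weakly correlated in Mersenne-Twister, and
the frame-to-frame means of such noise carry coherent spectral lines that a
spectral pipeline will faithfully (and misleadingly) detect. Temporally
correlated visible noise is equally forbidden because any periodic component
can entrain the adaptive tracker into periodic sub-pixel ROI jitter with the
same effect.

**What the generator does not emulate** — and hence what passing tests do not
show about real data: real face appearance (the bundled detector reads planted
fiducials, not anatomy, so detector robustness to pose, skin tone or lighting
is untested), lens distortion, non-rigid head motion, radiometric drift,
emissivity variation, blanket occlusion of the anatomy itself, and
apnea-adjacent pathologies beyond simple breath pauses. The registration
scenes carry high-contrast structure in both modalities; scenes poorer in
shared structure will degrade the refinement phase.

# Numerical choices and degenerate inputs

* Frequency-domain filtering uses mirror padding (16 px, rounded up to an
  FFT-friendly size) to suppress wrap-around artefacts; a gentle low-pass
  ($r_c = 0.45$ cycles/px, order 30) tames corner frequencies.
* Orientation argmax ties break toward the lowest index; CZT peak ties toward
  the lower frequency; FSC is deterministic given its seed and breaks score
  ties by lower RMS.
* Affine maps must satisfy $|\det| > 10^{-8}$; inverse-composition round
  trips are exact to ≪ 1 px.
* Constant images yield zero phase congruency (and registration fails
  explicitly at the keypoint stage, carrying the stage name); flat signals
  raise a classed error; empty mapped ROIs are flagged, not silently dropped.
* Problem sizes in the validation suite: 90 s (2700-frame) and 180 s scenes
  for the closed-loop checks, 10–20 randomized registration pairs, 20 tones
  for the spectral oracle — sizes at which every property is measured
  comfortably in minutes on one CPU.

# Known limitations

Single subject per scene (multi-person scenes are out of scope); no
deformable registration; the pretrained-network detector adapter is a
declared slot only; apnea *detection* (as opposed to reporting a quality-gated
0 bpm during a pause) is future work; thermal input is treated as scaled
intensity — absolute radiometric calibration is unnecessary because both the
mean-ROI average and the spectral peak location are invariant under affine
intensity maps.
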