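---
title: "Methods: tuning maps and speech encoding in auditory cortex recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tuning maps and speech encoding in auditory cortex recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Heschl's gyrus (HG) contains the human primary auditory cortex, and
intracranial recordings during natural speech listening show that its
response properties change systematically from its posteromedial (PM) to
its anterolateral (AL) end. `hgtune` implements the full analysis chain
that turns stimulus audio and multichannel neural recordings into five
per-electrode tuning attributes — best frequency (BF), response latency,
best temporal modulation (BTM), speaker invariance (SI) and speech
sensitivity (SS) — and then into joint spatial maps of how those
attributes change along the gyrus. Because clinical iEEG recordings are
not publicly distributable, the package ships a synthetic cohort
generator with known ground truth; every stage of the pipeline is
validated against quantities that are planted by construction.

# The signal chain

## Auditory spectrogram

`auditory_spectrogram()` models cochlear frequency analysis: 128
asymmetric filters equally spaced on a log axis from 180 Hz to 5.5 kHz
(the upper bound matches the Nyquist limit of 11.025 kHz stimulus audio),
cube-root compression, a first-order derivative along the spectral axis
with half-wave rectification (a lateral-inhibition stage), short leaky
temporal integration, and averaging of the 128 channels into 16
contiguous log-spaced bands. Frames are 10 ms (100 Hz), which supports
temporal-modulation analysis up to 50 Hz, comfortably above the rates
studied. The filter skirts are asymmetric — shallow below the center
frequency (0.35 octave Gaussian slope) and sharp above (0.03 octave) — so
that after compression and spectral differentiation, a pure tone still
peaks in the band containing it. The lowest two bands sit at the edge of
the filter bank, where the inhibition stage has no lower flank; tonotopic
labels there are accurate only to within one band.

## High-gamma envelope

`extract_high_gamma()` mirrors standard iEEG practice: resample to
500 Hz, first-order Butterworth high-pass at 1 Hz, second-order IIR
notches of 1 Hz bandwidth at 60/120/180/240 Hz, then eight 10 Hz
sub-bands spanning 70–150 Hz, the magnitude of the analytic signal in
each, and the average of the eight envelopes, downsampled to the
spectrogram frame rate and z-scored to a prestimulus silence window.
Sub-band envelopes are averaged *before* z-scoring (z-scoring is the last
step). All filtering is forward–backward, so filter group delay cannot
bias latency estimates — latency is a headline output of this pipeline
and a one-sided IIR cascade would shift it by several milliseconds.

# The STRF model

`fit_strf()` estimates, per electrode, a linear filter $w$ over stimulus
lags and frequency bands minimizing
$\lVert y - Xw \rVert^2 + \lambda \lVert w \rVert^2$, where $X$ is the
lagged spectrogram (0–300 ms, 31 lags at 100 Hz; the lag window must
contain the empirically observed 30–200 ms latencies with margin). This
ridge solution is the normalized reverse correlation: the
stimulus–response cross-correlation divided by the regularized stimulus
autocorrelation. A sparseness stage optionally zeroes weights below a
fraction of the peak magnitude. Both hyperparameters are selected by
20 contiguous-block cross-validation, and the per-fold held-out Pearson
correlations are retained.

Two numerical choices matter:

* **The ridge grid** spans six decades centered on the mean eigenvalue
  of $X^\top X$ (trace/p). Centering it on the mean column variance
  instead leaves every grid point effectively unregularized: prediction
  accuracy looks fine, but filter weights in weak stimulus directions
  are noise-dominated, and the temporal-modulation estimate is then
  driven by broadband ripple rather than by the filter's real dynamics.
* **Centering**: lagged stimulus columns and responses are mean-centered
  once globally. Held-out correlations are shift-invariant, so this does
  not leak fold information into model selection in any way that affects
  the reported statistic.

`include_electrodes()` gates electrodes with a one-sample t-test of the
20 fold correlations against zero, Benjamini–Hochberg corrected across
electrodes at 0.01.

## Tuning attributes from the filter

* **BF and latency** (`extract_bf_latency()`): the maximal positive
  weight seeds a 4-connected region grown above 50% of that peak; BF and
  latency are the region's power-weighted centroids along log-frequency
  and lag. The threshold is a named argument; recovery holds for any
  value between 30% and 70% (tested). Inhibitory sidebands are excluded
  by construction.
* **BTM** (`modulation_decompose()` + `compute_btm()`): the filter is
  decomposed with directional complex modulation filters over
  time × log-frequency — Gaussians (0.5 octave) on the log-magnitude of
  temporal rate and spectral scale, with upward and downward quadrants
  collapsed by magnitude. Rates are {1, 2, 4, 8, 16, 32} Hz and scales
  {0.25 … 8} cyc/oct. The rate vector is the mean of the 4-D power over
  scale, time and band, and BTM is its power-weighted centroid
  $\sum_i r_i p_i / \sum_i p_i$. The source description of the rate
  average is ambiguous between weighting by power and weighting by rate;
  the power-weighted centroid is implemented because the alternative
  does not depend on the filter at all. Time-reversing a filter leaves
  BTM unchanged (rate magnitudes are symmetric), and the centroid of a
  planted grating is recovered within ±25% even at 2 Hz, where a 640 ms
  window holds barely more than one cycle.

# Phoneme-level analysis

`segment_evoked()` cuts phoneme-aligned windows with a half-open
convention: window $[s, e)$ ms after an onset at frame
$\lfloor t \cdot fr \rfloor$ selects 0-based frames
$\lfloor s \cdot fr/1000 \rfloor$ through
$\lfloor e \cdot fr/1000 \rfloor - 1$. Phoneme lengths are not
normalized. The classifier (`rls_classify()`) is one-vs-rest regularized
least squares on ±1 targets with an intercept, the ridge parameter chosen
on a stratified 10% validation split; classification windows are
70–180 ms after onset, MDS windows 90–150 ms (neural) and 10–70 ms
(acoustic), selectable by the peak of the mean F-statistic across
candidate windows (ties break toward the earlier window).

`speaker_invariance_index()` trains phonetic-attribute classifiers on
all-but-one speakers and tests on the held-out speaker, normalizing by
the within-speaker 10-fold accuracy: $SI = \text{cross}/\text{within}$,
averaged over held-out speakers and the five attributes (manner, place,
voicing, height, backness; the vowel-only attributes are evaluated on
vowel instances). Per-site classifiers use the site's own windowed
samples; a population variant concatenates sites. The index is invariant
to per-site affine rescaling because the classifier standardizes around
the training mean. When the within-speaker accuracy is itself near
chance the ratio is kept but flagged unreliable.

`f_ratio()` is the pooled between/within variance ratio
$(\sum_f SSB_f/(k-1)) / (\sum_f SSW_f/(n-k))$, used to compare speaker
discriminability against manner discriminability in a common response
space, with permutation nulls from `f_ratio_perm()`. `mds_embed()` is
non-metric MDS under Kruskal's stress-1 (via `MASS::isoMDS`, classical
scaling start).

# Speech sensitivity

`speech_sensitivity()` z-scores each trial response by the silence-period
mean and SD, averages over time, and contrasts speech against nonspeech
trial means with an unpaired Student t (Welch optional); with the
standard trial set of 16 speech and 53 nonspeech sounds the statistic has
67 degrees of freedom. Sites are flagged by one-sided BH-FDR at 0.01.
`predicted_sensitivity()` runs the identical statistic on STRF
predictions of the trial spectrograms. A linear filter predicts constant
output in silence, so when the predicted silent interval has zero
variance the normalization falls back to the prediction's overall SD;
the t statistic is invariant to per-site affine changes, so this choice
cannot move the comparison. The actual-vs-predicted contrast isolates
response components beyond linear spectrotemporal tuning: a gain applied
after the linear stage raises actual above predicted sensitivity, while
in a purely linear world the paired difference is centered near zero —
*provided the filter is well identified*. Ridge shrinkage is
anisotropic (directions of low stimulus variance shrink most), which
slightly attenuates predicted contrasts; the linear-world control is
therefore run with 120 s stories and low-noise fits, under which the
residual paired bias is an order of magnitude smaller than the planted
nonlinear effect.

# Spatial maps

`along_hg_distance()` projects electrode (ML, PA) positions onto their
first principal axis, origin at the most medial site, increasing
medially→laterally; a warning is raised when the cloud is nearly
isotropic (eigenvalue ratio < 1.2) and the axis therefore unstable.
`knn_smooth()` (k = 4 nearest neighbors) and `interpolate_surface()`
(barycentric interpolation on a Delaunay triangulation, masked outside
the hull) serve display only; all statistics use raw values.
`impute_missing()` is nearest-neighbor (k = 1) imputation for sites
missing a task. `feature_axis_correlation()` reports Pearson r with a
two-sided t-test p; BF enters as log2(Hz) (tonotopic gradients are
log-linear). Hemisphere contrasts are two-sided Wilcoxon rank-sum tests.

`joint_pca()` z-scores each of the five feature maps (they mix Hz, ms
and t-units; unscaled PCA would be unit-dominated) and fixes each
component's sign so its largest-magnitude weight is positive.
`cca_best_direction()` finds the unit vector over (ML, PA) maximizing
the correlation of the projected coordinates with a tuning projection —
with a one-column Y this coincides with the regression direction, but it
is computed through the general canonical-correlation form. The returned
direction is defined up to the sign of the projection, so directions are
compared axially (mod 180°), and the control distribution of directions
under random projections is tested for circular uniformity with an
(axially doubled) Rayleigh test.

# The synthetic world

`synth_cohort()` builds the study-in-a-box. Its defaults are the study
conditions and are not tuned per analysis:

* **Stimulus**: multi-speaker "stories" synthesized directly in the
  spectrogram domain — phones with log-normal durations (median 90 ms,
  log-sd 0.35, truncated to 30–250 ms; 60 s of story yields ~500–600
  instances), phoneme-specific spectral prototypes built parametrically
  from the attribute inventory, speaker-specific formant warps and
  harmonic stacks at nominal pitches of 92, 104, 174 and 191 Hz, and
  raised-cosine phone envelopes that give a low-pass, speech-like
  modulation spectrum. Synthesizing in the spectrogram domain avoids a
  vocoder dependency; an audio path (`auditory_spectrogram()` on WAV
  input) exists for testing the cochlear front end itself.
* **Sites**: ground-truth STRFs are temporal Gabors (oscillation at the
  planted BTM under a Gaussian envelope) times a spectral Gaussian at
  the planted BF, peaking exactly at the planted latency. Along a
  simulated gyrus axis (default 40°, 20 mm), BF and BTM decrease
  geometrically (4 kHz→300 Hz, 16→2 Hz), latency increases
  (40→190 ms), and the invariance mixture α and speech gain increase.
  The `"line"` layout strings sites along the axis with ~1 mm scatter; the
  `"patch"` layout covers a 2-D area with the gradient keyed to the 45°
  projection — required when the gradient *direction* is the question,
  because a direction estimate from a cloud elongated along that same
  direction is ill-conditioned (its orthogonal component is noise
  amplified by the inverse coordinate covariance).
* **Responses**: true-STRF convolution, optional static nonlinearity,
  speech gain on phone-active frames, white Gaussian noise at a
  requested SNR (verified to ±0.5 dB), and an optional onset-locked
  phoneme code. The code assigns each phonetic-attribute level a random
  temporal profile over a 100 ms bump starting 50 ms after onset —
  shared across speakers for the invariant component, re-drawn per
  speaker for the dependent component (plus a speaker-identity offset);
  the site's α mixes the two. A scalar-amplitude code was tried first
  and rejected: it is rank-1, so five attributes collapse onto one
  decodable dimension and neither regime is legible. The code amplitude
  (4× the STRF-driven response SD) is fixed so that the planted coding
  regime, not the acoustically driven response (which is inherently
  largely speaker-invariant), dominates the classifier's evidence.
* **Sound set**: 16 speech and 53 nonspeech trials (tones, noise,
  AM noise, sweeps, click trains), 1 s inter-trial silences, and a long
  silence segment for normalization. Trials default to 13.5 s with a
  2-minute silence; analyses here use 2 s trials and 20 s of silence to
  stay desk-scale — statistics depend on trial counts, not durations.

**What the synthetic world does not emulate.** The planted phoneme code
is random with respect to acoustics, unlike real phonetic responses,
which are acoustically coherent. At the amplitude needed for regime
separation it acts as stimulus-locked noise for STRF estimation, so the
end-to-end study characterizes sites from two story passes of the same
cohort: one without the code for STRF estimation and one with it for the
invariance analysis. Real recordings need no such split. Passing tests
on this world demonstrates that the estimators recover what was planted
under realistic noise; it does not certify performance under real
cortical nonlinearities, correlated noise, or electrode artifacts
(artifact rejection is out of scope, as is anatomical localization).

# Problem sizes and determinism

The shipped analyses use 50-site cohorts with 60 s stories (120 s for the
sensitivity control), 100-site null cohorts for gate calibration, 10–15
site cohorts for invariance and discriminability, 199-permutation nulls,
and 200-draw direction controls. Every generator call takes an integer
seed and reproduces its output bit-exactly; derived seeds are small fixed
offsets of the master seed.

# Known limitations

* The cochlear filter shapes are a parametric stand-in for a full
  cochlear model; only their tonotopic fidelity and asymmetry are
  constrained by tests.
* BTM for very slow sites (≤2 Hz) is upward-biased inside a 300 ms lag
  window — under one oscillation cycle fits in the window — so gradient
  analyses of BTM rely on ranks and signs, not absolute rates, at that
  end of the scale.
* The SI of a site with near-chance within-speaker accuracy is a ratio
  of two small numbers; it is flagged rather than suppressed.
* `interpolate_surface()` uses an $O(\text{triangles} \times
  \text{grid})$ point-location scan, fine for electrode-scale inputs
  (tens of sites), not for dense meshes.
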