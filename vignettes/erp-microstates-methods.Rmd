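---
title: "Methods: microstate and source analysis of multi-group ERP designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microstate and source analysis of multi-group ERP designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`erpstates` implements a complete analysis chain for high-density
event-related potentials (ERPs) recorded in a mixed design — several
subject groups (a between factor such as musical expertise) crossed with
several stimulus conditions (a within factor such as the syntactic
regularity of a musical closure). The chain has four arms:

1. **Preprocessing** of epoched EEG into average-referenced,
   baseline-corrected ERPs.
2. **Waveform statistics**: pointwise between-group t-tests at selected
   electrodes with a minimum-duration run criterion.
3. **Topographic (microstate) analysis**: segmentation of the grand-mean
   ERPs into quasi-stable scalp topographies, data-driven choice of the
   number of maps, back-fitting to individual subjects and nonparametric
   statistics on microstate durations.
4. **Distributed source imaging**: a 3-shell spherical head model,
   depth-weighted minimum-norm (WMN) inversion, node-wise mixed ANOVA with
   cluster-extent correction calibrated by Monte-Carlo simulation, and
   gatekept Fisher-LSD post-hocs — plus the behavioural arm (signal-detection
   d′ with its own mixed ANOVA).

A synthetic-data generator produces studies with *known* microstate
timelines, known dipolar template sources and known per-cell sensitivity, so
every stage can be validated against ground truth.

# Preprocessing

The stage order is fixed: average reference → band-pass → decimation →
bad-channel interpolation → artifact rejection → averaging with baseline
correction.

* **Band-pass.** A 2nd-order Butterworth design, 0.25–30 Hz, applied
  forward–backward (`signal::filtfilt`). The single-pass design rolls off
  asymptotically at −12 dB/octave on each band edge; zero-phase application
  squares the magnitude response. Zero phase is deliberate: ERP latency
  statements are meaningless if the filter delays components. A causal
  option is not provided.
* **Decimation.** 1000 Hz → 250 Hz by keeping every 4th sample, justified
  because the 30 Hz low-pass sits far below the new Nyquist (125 Hz); no
  extra anti-alias filter is applied.
* **Interpolation.** Perrin spherical splines (order `m = 4`, 50 Legendre
  terms, ridge 1e−5 on the spline system) on the montage's least-squares
  sphere. Interpolating more than half the channels is refused.
* **Artifact rejection.** An epoch is dropped iff any channel-sample
  exceeds 100 µV in absolute value — strictly: a sample at exactly the
  threshold is kept. The visual-inspection step used with real recordings
  has no synthetic counterpart; the threshold rule is the only automated
  stand-in, plus an explicit bad-channel list.
* **Windows.** All analysis windows given in ms are half-open `[start, end)`
  and mapped to the sample grid by membership of the sample time; the epoch
  itself spans −200…750 ms inclusive (951 samples at 1 kHz, 238 at 250 Hz).
  Half-open windows avoid double counting a boundary frame in adjacent
  windows; the baseline is `[-200, 0)`.

# Microstate analysis

**Global field power (GFP)** is the spatial standard deviation of the scalp
map at one time frame; **global map dissimilarity (GMD)** between two maps
is the RMS difference after average-referencing and GFP normalisation and
satisfies `GMD² = 2(1 − r)` with `r` the spatial Pearson correlation.

**Segmentation** (`microstate_segment()`) runs a modified k-means over the
concatenated grand-mean frames of all design cells in `[0, 750)` ms:
frames are assigned to the template with the highest spatial correlation and
templates re-estimated from their frames, iterated to label stability, best
of `n_restarts` random starts by global explained variance (GEV, the
GFP²-weighted mean squared correlation between frames and their templates).
Design choices:

* **Polarity-sensitive by default.** Evoked components have fixed polarity,
  so signed correlation is the appropriate similarity; the
  polarity-invariant mode (absolute correlation, templates as first
  principal directions) is retained for spontaneous-EEG-style use.
* **Initialisation.** Restarts are seeded k-means++-style: the first
  template is a GFP²-weighted random frame and subsequent seeds are drawn
  with probability proportional to `GFP² · (1 − max r²)` against the seeds
  already chosen. Plain uniform seeding needs many more restarts to reach
  the same optima at k ≳ 7 and, when it stalls, can even make GEV
  non-monotone in k.
* **Smoothing.** Labelled segments shorter than 7 frames (28 ms at 250 Hz)
  are rejected at segmentation by reassigning their frames to the
  better-correlated neighbouring template. Back-fitting applies *no*
  smoothing, so individual durations may be fragmented — durations are
  defined purely by frame counts.
* **Ties** in assignment go to the lowest template index; zero-GFP frames
  stay unlabeled.

**Model order** (`choose_k()`) combines two criteria computed over a
consecutive k range (default 2–12): the cross-validation criterion
`CV(k) = σ̂²_residual · ((C−1)/(C−1−k))²` (C = channel count), and a
modified Krzanowski–Lai statistic on the dispersion curve `W(k)`:
`DIFF(k) = W(k−1)^(2/C) − W(k)^(2/C)`, `KL(k) = DIFF(k)/DIFF(k+1)`, defined
as 0 at the endpoints of the range and whenever the ratio is negative or
non-finite (a non-monotone stretch of `W` carries no evidence). The chosen
`k` maximises KL among candidates whose CV exceeds the CV minimum by at most
5%; the 5% gate carries a tiny absolute floor (1e−9 of the CV scale) so that
the saturated regime — noiseless data fitted perfectly from some k on, where
CV is numerical zero for every larger k — does not leave the gate to
floating-point noise.

**Durations.** Back-fitting assigns each frame of an individual ERP in the
analysis window (default `[295, 480)` ms — 46 frames, 184 ms) to its best
template; a map's duration is its frame count × 4 ms. Durations plus
unlabeled time always sum to the window length exactly. Duration statistics
follow a gatekeeping scheme: per map × condition a Kruskal–Wallis ANOVA on
ranks across groups, and only when it is significant at 0.05 the three
pairwise Mann–Whitney U tests with Bonferroni factor 3. Rank tests are used
because durations are bounded, discrete and frequently zero-inflated (a map
may simply not occur in some subjects), which rules out normal-theory ANOVA.

# Source imaging

**Head model.** Three concentric spheres with radius ratios
0.87/0.92/1.00 of the scalp radius and conductivities 0.33/0.0042/0.33 S/m —
the classical parametrisation. The montage is projected radially onto its
least-squares sphere.

**Solution space.** A 6 mm cubic lattice intersected with the spherical
shell `0.45–0.95` of a "gray-matter" radius that is auto-scaled until the
node count lands within 5% of 3005 — a geometric stand-in for an anatomical
gray-matter mask at the reference resolution. Contiguity uses a 10 mm
connection radius (face and edge lattice neighbours).

**Lead field.** The potential of a current dipole in the 3-shell conductor
is computed per spherical-harmonic degree by solving the 5-unknown
boundary-value system (continuity of potential and radial current at the two
interfaces, zero current at the scalp) for the layer coefficients, with the
infinite-medium dipole expansion as the particular solution; 60 series terms
by default. In the equal-conductivity limit this reduces analytically to the
homogeneous-sphere closed form, which the tests exploit as an oracle.
Columns are average-referenced. Amplitudes are *relative*: the absolute
µA/mm³ calibration depends on head-model scaling that cannot be recovered,
and every downstream statistic is scale-invariant.

**Inverse.** Depth-weighted minimum norm: node weights
`w = ‖L_j‖^(−depth_exponent)` (default exponent 1) counteract the
superficial bias of the unweighted minimum norm; the kernel is
`W L' (L W L' + λ I_avg)⁻¹` with `λ = λ_rel ×` the mean eigenvalue of
`L W L'` (default `λ_rel = 0.05`) and the pseudo-inverse taken on the
average-reference subspace. Current density (CD) per node is the Euclidean
norm of the estimated moment; the ERP is averaged over the analysis window
*before* inversion (the operator is linear, so this equals averaging the
moments, at a fraction of the cost). A known limitation documented here
deliberately: a *noiseless* WMN reconstruction of a point source peaks at or
*near* — not reliably *at* — the true node; the peak lands on a neighbouring
node in a substantial fraction of draws. Exact noiseless localization is a
property of standardized estimators (sLORETA-type), not of WMN, and no
parameter setting of the WMN family changes this.

**Statistics.** At every node a classical split-plot ANOVA (between factor
tested against subjects-within-groups; within factor and interaction against
the subject × condition residual), vectorised across nodes. Unequal group
sizes are handled by unweighted-means sums of squares for the between-factor
terms; no sphericity correction is applied (three within levels, and the
reference analyses report uncorrected df). Supra-threshold nodes
(p < 0.005) are clustered under the 10 mm adjacency and only clusters of
≥ 10 nodes are reported. The extent criterion is calibrated AlphaSim-style
(`montecarlo_cluster_p()`): i.i.d. Gaussian node noise is smoothed with a
7 mm-FWHM Gaussian kernel over node distances (rows renormalised, field
re-standardised, kernel truncated at 3σ), thresholded two-sided at 0.005,
and searched for clusters; the per-map probability of a chance surviving
cluster over 10,000 iterations is the calibration estimate. Smoothing is
applied to the surrogate noise only, never to the data. Post-hoc contrasts
at peak nodes use Fisher's LSD — pairwise t-tests on the omnibus error term
with no further correction — reported only when the omnibus test is
significant, which bounds the family-wise error at α for exactly three
groups.

# The synthetic-data generator

`simulate_study()` emulates the reference design: 3 groups of 19/20/20
subjects × 3 conditions, 90 trials per cell, 204 channels at 250 Hz, epochs
−200…750 ms. Each cell's ERP is a piecewise sequence of template
topographies (forward-projected random superficial dipole pairs, average
referenced, unit GFP, pairwise |r| < 0.9) under a smooth strictly-positive
amplitude envelope; the default timeline shares three early maps across all
cells and differentiates maps 4–7 inside `[295, 480)` ms — the "naive" map
dominating group 1 and two late centro-parietal maps dominating group 3,
with the contrast growing with transgression salience. Free parameters the
source study does not pin down, chosen once: peak amplitude 4 µV (a typical
late-component magnitude), single-trial channel noise 8 µV, log-normal
per-subject amplitude jitter with σ = 0.2 on the log scale (needed so that
group statistics are non-degenerate). Noise is white in space and time by
default — real EEG noise is spatially correlated and 1/f in time, so passing
recovery tests here demonstrates correctness of the estimators, not
field-realistic operating characteristics. At study scale the generator is
run in an evoked-level mode whose subject noise SD is `noise_sd/√n_trials`,
the exact distribution of an n-trial average of the trial-level model.

`simulate_behavior()` uses an equal-variance signal-detection model with the
regular endings as the shared noise class. Because two transgression types
with different target d′ share one false-alarm rate, the subject's criterion
is placed at `c + d̄/2` (d̄ = the group's mean transgression d′): hit rates
are `Φ(d′_t − d̄/2 − c)` and the false-alarm rate `Φ(−d̄/2 − c)`, so the
recovered `z(H) − z(FA)` equals each cell's target exactly and the model
reduces to the symmetric unbiased form when the two targets coincide. The
default per-cell targets are the reference group means (non-musicians
0.49/1.60, amateurs 1.54/3.68, experts at ceiling 4.40/4.50); d′ estimates
use the 1/(2N) correction only at empirical rates of exactly 0 or 1 (the
log-linear alternative is not the default because ceiling-level groups then
shrink noticeably below target). The generator draws trial-level binomial
noise only; between-subject d′ spread is therefore narrower than in real
cohorts, which makes the ANOVA power checks conservative statements about
the engine, not about field data.

# Problem sizes used by the test suite

The suite regenerates everything in code: the 204-channel net, the
~3000-node grid and its lead field once per run; 20 simulated studies for
the model-order recovery property; 100 noiseless inversions for the
localization properties; 10,000 Monte-Carlo iterations for the
cluster-extent calibration and the LSD family-wise error simulation; 100
full null studies for the end-to-end false-positive check. These sizes give
Monte-Carlo standard errors comfortably below the margins being asserted.

# Known limitations

* The spherical shell is a crude gray-matter surrogate; no BEM/FEM, no
  individual anatomy, no atlas labelling.
* The cluster-extent criterion is calibrated on a 7 mm-FWHM Gaussian
  surrogate. Current-density noise produced by a minimum-norm inverse is
  spatially correlated over several centimetres — far smoother than the
  surrogate — so the node-wise ANOVA chain's cluster-level false-positive
  rate under a white-sensor-noise null greatly exceeds the surrogate's
  nominal level (the acceptance suite measures this directly). Cluster
  inferences on CD maps under this head model are best read as
  descriptive.
* WMN peak localization is approximate by design (see above); the package
  reports relative CD and statistics on it, not calibrated absolute current.
* The synthetic noise model omits ocular/muscle artifacts and spatial
  correlation; the artifact-rejection stage is exercised only by injected
  threshold violations.
* EDF ingestion is not implemented; epoched data enter through the
  plain-text matrix + JSON-sidecar fixture format.
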