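---
title: "Flip-based lateralization of functional connectivity: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flip-based lateralization of functional connectivity: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement model

`hemiflip` quantifies hemispheric specialization of resting-state functional
connectivity by comparing each within-hemisphere connection with its mirror
image. For a preprocessed BOLD run, ROI time courses are extracted twice:
once from the run as acquired and once after mirroring the volume across the
midsagittal plane (`flip_midsagittal()`, an exact x-index reversal). For a
connection between ROIs $a$ and $b$ the lateralization index is

$$\mathrm{LI}(a,b) \;=\; \operatorname{atanh} r_{ab}^{\text{unflipped}}
\;-\; \operatorname{atanh} r_{ab}^{\text{flipped}},$$

the difference of Fisher-transformed Pearson correlations. Extracting ROI
$a$ from the flipped image reads the signal of $a$'s contralateral
homologue, so for a left-hemisphere pair the subtrahend is the homologous
right-hemisphere coupling: positive LI on a left pair means left
lateralization, and a strongly right-lateralized right-hemisphere pair has
negative LI. Two useful exact identities follow from the mirror geometry
and are enforced by tests: flipping twice is the identity, and running the
whole pipeline on a mirrored run negates every LI.

The analysis is restricted to ipsilateral pairs of a configured set of
lateralization hubs — canonically 9 left-network and 11 right-network
cortical regions, giving 36 left-lateralized and 55 right-lateralized
connections; the left set splits into 15 connections involving a language
hub (Broca or Wernicke area) and 21 that do not. Cross-hemisphere pairs are
ambiguous for lateralization; when requested (`include_mixed = TRUE`) they
are evaluated after mapping the right hub to its mirrored left-hemisphere
ROI, for pattern maps only — they never enter group statistics. Hub
coordinates are a user-supplied CSV: the published coordinates belong to
prior work and are not redistributed here. The shipped
`hubs_synthetic_20.csv` is a synthetic stand-in on the default test grid
(with the standard hub abbreviations), and `hubs_template.csv` documents the
expected columns.

# Preprocessing

The pipeline consumes template-space 4D volumes with realignment
parameters; spatial preprocessing (realignment, normalization, segmentation)
is upstream and out of scope. The implemented chain is:

1. **Linear detrend + zero-phase bandpass**, 0.001–0.1 Hz by default,
   realized as a frequency-domain mask after removing each voxel's best-fit
   line. The mask keeps Fourier bins with $f_{\text{low}} \le f \le
   f_{\text{high}}$; a high corner at or above Nyquist is rejected.
2. **Confound regression** per voxel on [intercept, CSF, WM, soft tissue,
   6 motion parameters] via pivoted QR; residuals are the unique projection
   even when the design is rank-deficient (dependent columns are reported).
3. **Motion scrubbing**: framewise displacement (sum of absolute backward
   differences of the six parameters, rotations converted to arc length on
   a 50 mm sphere; an RMS variant sits behind `method = "rms"`) and DVARS
   (RMS volume-to-volume change over the brain mask, as a percentage of the
   raw mean in-mask intensity). Any transition with either measure above
   0.2 flags the two volumes spanning it; kept volumes are concatenated.
4. **No spatial smoothing, no global-signal or grey-matter regression** —
   smoothing mixes signal across the midline and global regression can
   redistribute hemispheric differences; neither operation exists in the
   package.

Hub SNR (temporal mean over temporal SD of the ROI-mean signal) is computed
on the images *before* cleaning, where scanner drift and baseline intensity
still dominate.

**Ordering.** The original description runs the filter/detrend
"concurrently" with the regression, which fixes no order. We filter first
and regress second. The alternative (regress, then filter) lets two leaks
inflate the residuals: betas on spike-carrying motion regressors are fit
against the full-amplitude in-band signal and re-inject the regressor's
smooth component scaled by that beta, and low-frequency scanner drift
bleeds through every smooth confound's beta. Filtering first removes
out-of-band variance before any beta is estimated; on synthetic runs this
is what keeps baseline DVARS comfortably under the scrubbing threshold.

**DVARS units.** The 0.2 threshold is applied to DVARS expressed as percent
of the run's mean in-mask intensity, making it scale-free; the reference
mean is taken from the raw run because the cleaned data are zero-mean.

# Statistics

Per diagnostic group, each connection gets a two-sided one-sample t-test of
LI against zero (the group's lateralization pattern), with
Benjamini–Hochberg FDR at $q < 0.05$ within the group's connection family.
Group differences use two-sided pooled-variance two-sample t-tests (control
minus autism; Welch is available) with BH-FDR jointly over the whole
ipsilateral family — 91 connections under the full hub set. P values are
reported uncorrected with FDR flags kept separate. Degenerate inputs
(zero variance, fewer than 3 subjects, a missing group) are reported as
untested rather than silently dropped. BH itself is `stats::p.adjust`; the
test suite checks it against a literal step-up enumeration.

Degree-of-lateralization contrasts average each subject's LI over the three
connection groups (left-language, left-nonlanguage, right) and run paired
t-tests per diagnostic group on a common scale, with the right-network mean
negated so that "more lateralized toward its own hemisphere" is positive
for every group.

Severity is the sum of the ADOS social and communication domain totals.
For connections flagged by the group comparison, the package reports
Pearson correlations of LI with severity (autism group, and optionally
autism plus the controls that have ADOS scores) and Spearman correlations
with age and quantitative handedness per group — rank-based for the latter
two because their residuals are not normal in the target data.

**Inclusion criteria.** The base analysis keeps subjects from sites
contributing at least `min_site_n = 20` usable subjects. The stricter
restrictions are: scrubbing retention ≥ 50%; exclusion of sites that may
overlap the samples from which the hub set was derived (the site list is
dataset-specific and user-supplied); right-handed only (after recoding a
positive quantitative handedness score to right-handed, negative to
left-handed, zero to ambidextrous, when the categorical measure is
missing; subjects with no measure at all are retained except under this
restriction); male only; strict autism diagnosis (excluding Asperger and
PDD-NOS); and per-group verbal-IQ matching windows (autism 80–130, control
70–120). The published table labels its analyses A–H
without printing the footnote compositions, so the presets here are the
package's own convention: A = base, B = retention, C = overlap sites,
D = B + C, E = handedness, F = sex, G = diagnosis, H = IQ windows. Every
preset adds restrictions to A, so included counts are monotone
non-increasing — a property the tests check.

# The synthetic cohort generator

`simulate_cohort()` exists so that every downstream stage is testable
without any data download. Its defaults are fixed study conditions chosen
once to emulate the multisite autism resting-state sample the pipeline
targets:

| parameter | default | rationale |
|---|---|---|
| TR, volumes | 2 s, 240 | most target scans are under 10 min |
| base hub coupling | z = 0.3 | moderate resting-state coupling |
| motion spike rate | 0.05 / 0.09 per volume (control / autism) | reproduces pre-scrub FD ≈ 0.11 / 0.15 mm and retention ≈ 82% / 74% with 0.5 mm spikes |
| baseline intensity, drift | 15000, ±150 | hub SNR ≈ 87, inside the plausible 72–110 band |
| signal band, sd | 0.001–0.014 Hz, 100 | keeps baseline DVARS under the 0.2% threshold |
| voxel noise sd | 10 | weak attenuation of ROI correlations |

Hub (and all other lattice-ROI) time courses are band-limited latent
Gaussian signals whose correlation matrix encodes `tanh(base_edge_z)` on
every ipsilateral hub pair in both hemispheres, plus a per-group effect
`dz` added on the *left-hemisphere instance* of each named connection —
so the expected LI equals `dz` on a left pair and `-dz` on a right pair,
in interpretable Fisher-z units. A non-positive-definite request is
rejected outright rather than repaired, naming the offending connections.
Voxels are ROI latent signal + white noise + a global linear scanner drift;
realignment traces are smooth sinusoids plus single-volume translation
spikes; CSF/WM/soft-tissue traces are generated independently of the hub
signals. Phenotypes draw continuous measures uniformly within the printed
demographic ranges of the target sample and categorical shares (sex,
handedness category and availability, diagnosis subtype, ADOS availability
for controls) from its printed counts.

The mid-plane convention — even x-dimension, mirror plane between the two
central voxel columns — makes the flip an exact involution with no
interpolation, which is what lets the antisymmetry tests demand exactness.
`make_symmetric_atlas()` builds the lattice on the left half-grid and
mirrors it, so every ROI has an exact homologue by construction.
`build_lattice()` (for real masks) assigns each grey voxel in the closed
z-range to its nearest lattice seed, ties broken by lowest seed id after
sorting seeds lexicographically by (x, y, z) — a deterministic rule, since
the published description fixes none.

What the generator does **not** emulate: spatial autocorrelation beyond ROI
blocks, slice-timing or susceptibility artifacts, site-specific pulse
sequences, non-Gaussian BOLD dynamics, genuine motion–signal coupling
(spikes perturb the realignment traces, not the haemodynamics), and
realistic anatomy. Passing tests therefore demonstrate the correctness and
calibration of the *pipeline*, not the empirical claims of any real-data
analysis.

# Numerical choices

- Correlations are clipped to $|r| \le 1 - 10^{-12}$ before `atanh`, so
  degenerate duplicate series stay finite; zero-variance ROIs propagate as
  missing values with a warning and are counted in QC.
- FD of the first volume and DVARS of the first volume are 0 by definition.
- The scrub rule flags volumes $t-1$ and $t$ for an excursion at transition
  $t$ because FD and DVARS are transition quantities; a run whose every
  volume is flagged is an error (exclusion is the criteria layer's job).
- The homologue map is computed from the label field itself (an ROI's
  mirror must map voxel-for-voxel), so asymmetric atlases simply have
  missing homologues.
- Determinism: a cohort is generated from a single RNG stream seeded by the
  spec; identical config + seed reproduce byte-identical tables, and the
  study manifest records a config hash.

# Problem sizes in the test suite

The suite runs entirely on synthetic data at desk scale, chosen to keep a
full run in minutes on one CPU: unit fixtures on 8×8×4 grids (32 ROIs, 2+2
hubs), the 20-hub configuration on a 24×24×16 grid, null-calibration at
200 cohorts of 30+30 subjects with 120 volumes each, planted-effect
recovery at the lateralization-table level (100 simulations of 60+60
subjects over all 91 connections), and an end-to-end planted-deficit study
of 12–20 subjects per group. The acceptance script reruns the same kinds of
computation from scratch under a caller-supplied seed.

# Known limitations

- The per-subject LI is noisy when runs are short: a narrow signal band at
  TR 2 s leaves few effective degrees of freedom per correlation, so
  group-level inference is calibrated but single-subject LI values are not
  precise measurements.
- With the planted-deficit magnitudes used in the calibration suites
  (shift 0.15 at subject sd 0.25, 60+60 subjects), sole-detection power
  over a 91-connection FDR family is intrinsically moderate (noncentrality
  ≈ 3.3 against a rank-1 BH cut of ≈ 3.55); detecting subtler deficits
  needs larger cohorts.
- Sites are simulated as balanced allocation only; no site covariate or
  harmonization is applied in the group tests, matching the target
  analysis.
- The whole-lattice (thousands × thousands) mode is supported by the data
  structures but untested beyond the hub-restricted analysis.
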