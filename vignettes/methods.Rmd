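---
title: "Methods: voxel colocalization, synthetic ground truth and mixed-model inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel colocalization, synthetic ground truth and mixed-model inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

The package quantifies 4-channel confocal z-stacks (GFAP astrocytes, 4G8
amyloid-beta, synapsin-1 presynaptic terminals, IBA1 microglia) by
segmenting each channel into a binary mask and counting voxels. All
headline quantities are percentages of **total stack volume**: burden
(`100·|A|/N`), pairwise colocalization (`100·|A∧B|/N`) and triple
colocalization (`100·|A∧B∧C|/N`). This is deliberate: binary co-occupancy
of segmented volumes, not intensity correlation (no Pearson or Manders
coefficients), because the scientific readout is "what fraction of the
imaged tissue is double/triple positive", and a common denominator makes
stacks of equal size directly comparable. Normalizing colocalization by one
channel's volume instead of total volume is a legitimate alternative; the
engulfment-enrichment statistic (below) covers that conditional view, and
total-volume normalization is the headline convention.

Synaptic engulfment is read out conditionally. For synapsin mask *S*,
amyloid mask *β* and glial mask *G*:

* fraction of amyloid-positive synaptic voxels inside glia:
  `f⁺ = |S∧β∧G| / |S∧β|`
* fraction of amyloid-negative synaptic voxels inside glia:
  `f⁻ = |S∧¬β∧G| / |S∧¬β|`
* enrichment ratio `f⁺/f⁻`.

A ratio above 1 means amyloid-carrying synapses are preferentially located
inside the glial volume. Zero denominators (no amyloid-positive synaptic
voxels, say, in an amyloid-free field) yield `NA` with an explicit
`defined = FALSE` flag; downstream models drop those rows listwise rather
than imputing zeros, which would fabricate signal in sparse stacks.

Colocalization at confocal resolution is a proxy for containment or
contact, not proof of internalisation — the diffraction limit means a
synapsin-positive voxel inside a microglial mask may be engulfed material
or apposed membrane. This caveat applies to the real use case exactly as it
applied to the imaging study this pipeline is modelled on.

# Segmentation

The original analyses in this field use unpublished ImageJ/MATLAB scripts;
the segmentation operator here is therefore a documented stand-in, not a
reimplementation of any specific script. The default is per-channel,
whole-stack 3D Otsu thresholding: parameter-free, deterministic, and
appropriate because imaging parameters are constant within a stack (so one
threshold per channel per stack is justified; thresholds are never computed
per slice). Fixed and percentile thresholds are available for sensitivity
analysis. Small-object removal (connected components under 6- or
26-connectivity) is available but **off by default** (`min_object_voxels =
0`) because no size filter is stated in the source protocol. A flat
(constant-intensity) channel makes Otsu undefined and raises a
degenerate-input error rather than guessing.

The no-primary negative-control check segments a designated control stack
and fails if any channel's burden exceeds a tolerance (default 0.5%). With
a data-driven method a control would trivially "find" structure in pure
noise, so the recommended usage carries fixed thresholds over from a
matched stained stack of the same staining batch.

# The synthetic world

Because the source image data are not deposited, every pipeline stage is
validated against a generator with exact ground truth. A scene is built in
physical micrometre coordinates:

* **Synapses**: Poisson-count spheres (default 0.10 puncta/µm³, radius
  0.5 µm — the scale of confocal-resolvable presynaptic puncta; cortical
  synapse density is nearer 1/µm³, but most are unresolvable at this
  modality, so the generator emulates the *detectable* punctum field).
* **Amyloid**: an optional diffuse plaque rendered as a Gaussian intensity
  falloff whose half-intensity surface sits at the stated plaque radius
  (default 8 µm) — reflecting that feline deposits are diffuse rather than
  dense-core — plus amyloid-positive synaptic cores. An amyloid-positive
  terminal is amyloid across its whole punctum footprint: sub-punctum
  cores would be below the PSF and unmeasurable by any operator.
* **Glia**: per glial channel, soma spheres (default 4 somata of radius
  2.5 µm) with straight capsule branches (5 per soma, 12 µm long) — a
  deliberately simple arbor that reproduces realistic glial volume
  fractions (~5–8%) without modelling true morphology.
* **Engulfment**: a target number of puncta (`engulfment_fraction`,
  near-plaque multiplier applied) is drawn without replacement with weights
  multiplied by `engulfment_ab_bias` for amyloid-positive puncta, then each
  selected punctum's centre is relocated to a uniformly chosen voxel inside
  the host glial volume (microglia or astrocyte chosen at random). This
  gives an unambiguous per-punctum `engulfed_by` label in the ground truth.
* **Plaque microenvironment**: within `plaque_radius + halo` (halo 10 µm),
  glial density, engulfment fraction and the synaptic-amyloid fraction are
  multiplied by configurable factors (defaults 1.5/2/2), encoding the
  qualitative biology — gliosis and elevated engulfment near plaques.
* **Optics and noise**: geometry is rendered at unit foreground intensity,
  blurred by a separable Gaussian PSF (default σ = 0.35 µm axial, 0.15 µm
  lateral), then degraded by Poisson photon noise (`photon_scale` = 100
  photons per intensity unit; `Inf` disables shot noise for noiseless
  oracles), Gaussian read noise (σ = 0.02) and a constant background (0.1),
  clamped at zero.

Ground truth (burdens, all pairwise and triple percentages, the punctum
table, the plaque mask) is computed by exact voxel counting on the
**pre-blur binary geometry**; noise never touches the truth.

The field of view of the emulated protocol is 184.7 × 184.7 µm, but the
voxel grid and stack depth are not stated there, so the defaults are
conventions: desk scale is 16 × 128 × 128 voxels at 0.4 × 0.3 × 0.3 µm
(38.4 µm field, 6.4 µm depth), chosen so that a full scene generates in
about half a second and test suites stay fast; full-size fields are
available by passing a larger `shape_vox`.

Cohorts nest stacks in ROI pairs in cases in groups. Defaults mirror the
emulated study: 7 young, 10 aged, 8 CDS cases; 10 stacks per case;
plaque-bearing cases imaged as (plaque, adjacent) pairs and plaque-free
cases as random fields; per-group plaque prevalence taken from the packaged
case table's amyloid scores (3/7, 7/10, 4/8). Group multipliers on the
synaptic-amyloid fraction, glial density, engulfment fraction and amyloid
bias (Young 1/1/1/1; Aged 2/1.3/1.5/2.5; CDS 2.5/1.5/2/2.5) encode the
study's qualitative findings at magnitudes chosen once as realistic —
roughly two-fold pathology elevation in the affected groups. A single
master seed drives one `sample.int()` stream that yields case-level draws
and one child seed per stack, so cohorts are bit-reproducible and stacks
mutually independent.

**What a green test does and does not establish.** The generator emulates
the imaging *structure* (punctate/diffuse/arborized geometry, partial
overlaps, nesting, plaque microenvironment, PSF and noise), not tissue
realism: no tau, no lipofuscin autofluorescence, no staining-batch
variation, no vascular amyloid, no true glial morphology. Passing tests
establish that the *computational* pipeline measures what it claims on
known geometry at realistic SNR — they say nothing about antibody
specificity or biological effect sizes.

# Statistical inference

The inference layer mirrors standard practice for nested imaging designs:

* **Models**: `y ~ Group + (1|Case)` on per-stack outcomes across all
  stacks, and `y ~ PlaqueStatus*Group + (1|Case) + (1|Case:ROI)` on the
  paired design (lme4, REML). AIC/BIC are reported from an ML refit so
  fixed-effect structures are comparable; age enters as a covariate only if
  it improves ML AIC by more than 2 (ties go to the simpler model).
* **Assumption checks**: the visual QQ-plot and residual-vs-fitted checks
  are operationalized as a Shapiro–Wilk test on residuals (subsampled to
  ≤ 5000) and a Spearman test of |residual| against fitted values, both at
  0.05. These thresholds are documented conventions; the original visual
  criteria are not computable.
* **Transformation selection**: identity is kept if both diagnostics pass;
  otherwise sqrt, log (offset = half the smallest positive value when
  zeros exist, recorded), arcsine-sqrt (for percent/proportion outcomes)
  and the best Tukey-ladder exponent from the fixed grid λ ∈ [−2, 2] step
  0.25 (chosen to maximize residual normality) are fitted, and the passing
  candidate with the highest Shapiro–Wilk W wins; if none passes, the
  best-W candidate is returned flagged `assumptions_met = FALSE`. The full
  trail is recorded. Under jointly applied 0.05/0.05 diagnostics, a truly
  Gaussian outcome keeps identity ~90% of the time — the residual ~10% is
  the price of automated checking, not a bug.
* **Contrasts**: estimated marginal means over the fixed-effect grid
  (covariates at their mean), pairwise differences, Tukey
  studentized-range adjustment. Group families adjust over the three group
  means; plaque-within-group families condition on group (two means per
  subfamily, where Tukey reduces to the unadjusted two-sided p — the same
  behaviour as the corresponding `emmeans` call with `| Group`).
* **Degrees of freedom**: Kenward–Roger is not implementable with this
  dependency set (no `pbkrtest`), so the containment (between-within) rule
  is used and the method is recorded in every contrast row. For balanced
  between-case contrasts containment gives `n_cases − n_groups` — e.g. 22
  denominator df for 25 cases in 3 groups, which is also what
  Kenward–Roger yields on balanced data. For within-ROI contrasts it gives
  `n_obs − n_ROI − p_within`. Containment is mildly conservative on
  unbalanced data; the calibration tests show the group test holds its
  nominal 5% level on the designs this package targets.
* **Correlations**: Spearman correlations on one value per case (case
  means over included stacks), per group, with groups under 3 cases
  skipped with a notice.

# Numerical conventions and degenerate inputs

* Voxel centres sit at `(i − 0.5) · voxel_size`; all geometry is evaluated
  against centres, so rasterization is exact and independently checkable
  by brute-force distance loops.
* The plaque's ground-truth mask is the half-intensity surface of its
  Gaussian falloff; with zero PSF and zero noise, any threshold strictly
  inside the intensity gap reproduces binary-object masks exactly, and a
  threshold at half foreground reproduces the plaque mask. With the
  Gaussian skirt, exact mask recovery is knife-edge at exactly half
  intensity — the exactness oracles therefore run on plaque-free noiseless
  scenes.
* Connected components are labelled via an adjacency graph (igraph) —
  6-connectivity by default, 26 available. Plaque calls use the equivalent
  spherical diameter of each component with a default minimum of 10 µm;
  the source protocol states no size criterion, so this is a configurable
  convention separating diffuse deposits from punctate synaptic amyloid.
* Top-k selection breaks amyloid-burden ties by lexicographic stack id;
  shortfalls (fewer than k stacks) keep everything and are recorded.
* TIFF storage is uncompressed little-endian multi-page with 64-bit float
  samples (bit-exact round-trips) and JSON metadata in the ImageDescription
  tag; no TIFF library exists in the supported R dependency set, so the
  reader/writer implements this subset directly and is cross-validated
  against Python's `tifffile` in the test suite.
* The Wilcoxon age-match test uses mid-ranks with normal approximation
  (ties are expected in integer ages) and compares Aged vs CDS in that
  order; on the packaged table it gives W = 37 and group mean ages
  4.71/17.10/16.75. The cohort's published description reports W = 36.5
  and means 4.8/17.2/16.9, implying sub-year ages that the table does not
  carry; the table is kept verbatim and the discrepancy documented rather
  than resolved. The Fisher sex-match test excludes the one unknown-sex
  case.

# Known limitations

* Object-level (per-punctum) engulfment counts and distance-to-plaque
  gradients are out of scope; the design dichotomizes plaque vs no-plaque.
* Glial arbors are geometric stand-ins; morphology-sensitive readouts
  (e.g. ramification indices) cannot be studied with this generator.
* The segmentation default is a documented stand-in for unpublished
  scripts; absolute burden values depend on the thresholding operator, and
  cross-study comparisons should fix the operator.
* Containment df is exact only for balanced designs; strongly unbalanced
  data would warrant a Kenward–Roger or Satterthwaite implementation.
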