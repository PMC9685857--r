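---
title: "Methods: composite evaluation of prostate dose-painting plans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite evaluation of prostate dose-painting plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpeval)
```

## The problem

A prostate dose-painting plan prescribes different dose levels to
ADC-defined sub-volumes of one gland: high-cellularity dominant
intraprostatic lesions (DILs) are boosted (here 70 Gy, lower-risk lesions
66 Gy) while the remaining gland receives 60 Gy and the seminal-vesicle
base 53 Gy. The conventional homogeneity index (HI) and conformity index
(CI) each describe one target against one prescription; a multi-level plan
therefore produces a vector of indices with no agreed scalar summary.
`dpeval` computes composite indices of effectiveness,

$$\mathrm{IOE} = \sum_i x_i \,\frac{CD_i}{CD_p}\,\frac{V_i}{V_T},
\qquad V_T = \sum_i V_i,$$

where $x_i$ is a per-target HI (IOE(H), lower is better) or CI (IOE(C),
closer to one is better), $V_i$ the target volume, and $CD_i/CD_p$ a
relative cell-density weight inferred from ADC. Setting every ratio to one
gives the plain volume-weighted forms; the unweighted means of the $x_i$
are the conventional comparators. The evaluation set defaults to the
70/66/60 Gy CTVs; the 53 Gy seminal-vesicle level is excluded from the
composite (its tissue is not part of the graded intraprostatic risk map),
though it is still planned, dosed and checkable against objectives.

Assumptions worth making explicit: ADC and dose are supplied co-registered
on (or resampleable to) one voxel grid; ADC is inversely related to
cellularity, monotonically, over the prostate; and a target's clinical
importance is proportional to its relative cell density and relative
volume, which is exactly what the IOE weight structure encodes.

## Segmentation and target construction

Voxels inside the (manually delineated, input) prostate mask are
classified by ADC band: high-risk lesion below 750, lower-risk lesion in
[750, 1500), normal tissue in [1500, 5000]. Values are kept on the
scanner-reported $10^{-6}\,\mathrm{mm^2/s}$ scale; physiological prostate
ADC is $\sim 0.75\text{--}1.5\times10^{-3}\,\mathrm{mm^2/s}$, so the
package treats the thresholds as dimensionless scalars on the printed
scale and documents the unit ambiguity rather than rescaling. Band edges
are strict on the upper side (exactly 1500 is normal tissue). Voxels above
the 5000 ceiling are assigned to normal tissue with a warning.

Classified voxels become targets only if they form connected components of
at least `min_component_voxels` (default 400) under a configurable
neighbourhood (default 26). Classification precedes filtering, so one
physical lesion straddling the 750 boundary may legitimately contribute
fragments to both risk classes. The voxel grid on which the 400-voxel rule
is interpreted is itself a free choice (diffusion grids, interpolated CT
grids and display grids all differ); the package applies it on whatever
grid the ADC volume arrives on, and the phantom's default lesions are
sized to clear the filter at the diffusion-geometry voxel size.

CTVs follow the four-level recipe — high-risk DILs → CTV 70 Gy, lower-risk
DILs → CTV 66 Gy (the mapping is a configuration, since the underlying
risk/grade correspondence is not a settled rule), prostate minus DILs →
CTV 60 Gy, seminal-vesicle base → CTV 53 Gy. PTVs are morphological
expansions by physical distance: 8 mm isotropic (53 Gy), 5 mm with the
posterior component zeroed (60 Gy), 2 mm bounded by the whole prostate and
excluding rectum, bladder and urethra (66/70 Gy). The anatomical posterior
direction is declared in configuration (`margin_vector(5, zero = "y+")`),
never inferred from image metadata, because orientation conventions are
the least portable part of any imaging stack.

## Dosimetry, density weighting and TCP

DVHs use fixed-width, left-closed bins (default 0.05 Gy) starting at 0 Gy;
percentile doses $D_{p\%}$ interpolate linearly between bin edges of the
cumulative curve, so halving the bin width moves any $D_{p\%}$ by less
than one bin. HI defaults to the ICRU-83 form $(D_{2\%}-D_{98\%})/D_{50\%}$
— zero for uniform dose, scale-invariant — with $(D_{5\%}-D_{95\%})/D_rx$
selectable. CI defaults to target coverage
$V(\text{target} \cap D \ge rx)/V(\text{target}) \in [0,1]$, with the
Paddick form available when spill outside the target matters. Both
defaults were chosen to match the reported magnitudes and "closer to
zero/one" readings of the indices they generalize. Dose grids that
disagree with a structure's grid are resampled trilinearly first; labels
always resample nearest-neighbour.

Cell density defaults to the inverse-linear map
$CD = (5000 - \overline{ADC})/5000$ of each target's mean ADC; a
reciprocal map and a monotone user table are available, and the summary
statistic (mean/median) is configurable because the literature does not
pin it down. Only ratios enter the IOE, so any positive rescaling of the
map cancels — this is tested, not just asserted. The pooled density
$CD_p$ is read as the volume-weighted mean over the pooled target volume,
under which $\sum_i (V_i/V_T)(CD_i/CD_p) = 1$ exactly and the IOE stays a
weighted average; an unweighted mean of the $CD_i$ is available behind a
flag for sensitivity analysis. A missing target (e.g. no high-risk DIL
survives the filter) drops its term and shrinks $V_T$, preserving the
convex-combination property.

TCP is the Poisson model on the differential DVH:
$\mathrm{TCP} = \exp(-\sum_b \rho\, v_b\, SF(D_b))$ with bin-centre doses
and LQ fractionated survival $SF(D)=\exp(-\alpha D - \beta D\, d)$,
$d = D/n_{\text{fractions}}$ (each bin's dose assumed delivered in the
plan's fraction count). Optional population heterogeneity averages the TCP
over a discretized normal in $\alpha$ (49 nodes over ±3.5 SD,
renormalized, negative values truncated). The default parameters
(α = 0.15 Gy⁻¹, α/β = 1.5 Gy, 10⁷ clonogens/cc, 27 fractions) are
literature-typical prostate values shipped as labelled placeholders:
absolute TCP depends strongly on them, so reported TCPs should be read
comparatively across plans evaluated with one fixed set, never as
calibrated outcome predictions.

## The phantom generator

The generator emulates the imaging and planning conditions the pipeline
expects: a 96×96×48 grid at 1.64×1.64×3 mm (diffusion-MRI geometry), a
prostate ellipsoid of ~38 cc, one to three spherical lesions with Gaussian
ADC noise in the high-risk (default 600 ± 50) and lower-risk (1100 ± 80)
bands against normal tissue at 2000 ± 150 and extra-prostatic background
at 2600 ± 250, clamped to [0, 5000]; plus geometric organ masks (rectum,
bladder, urethra, femoral heads, bowel, seminal-vesicle base). Default
lesion radii (~10 mm) are the smallest that comfortably clear the
400-voxel component filter at this voxel size. All draws descend from one
seed in a documented region order, so phantoms are bit-reproducible.

Dose grids are engineered rather than optimized: each target's voxel doses
are drawn from a piecewise-linear quantile function pinned at
$Q(1-\text{coverage}) = rx$, $Q(0.02) = D_{98\%}$, $Q(0.5) = D_{50\%}$ and
$Q(0.98) = D_{2\%}$ with $(D_{2\%}-D_{98\%})/D_{50\%}$ equal to the
requested HI, then assigned deterministically by distance from the target
centroid (hot core, cool rim). When more than 2% of the target is below
prescription, $D_{98\%}$ lies inside the cold tail; the tail is kept
shallow (bottom 2% within 3% of $D_{98\%}$) so cold-spot severity grows
smoothly with cold fraction instead of exploding — this keeps TCP a
monotone-ish function of coverage across a cohort, which is what makes the
engineered TCP–conformity correlation testable. Requested homogeneity and
coverage are recovered from the generated grids within ±0.01
(property-tested over ten seeds at the default resolution). Outside the
targets, dose decays exponentially in one-voxel shells (default 10 mm
length).

What the phantoms deliberately do **not** emulate: MR noise correlations
and distortion, partial-volume mixing at lesion boundaries, realistic beam
physics or optimizer trade-offs, inter-structure dose correlations, and
registration error (inputs are exactly co-registered by construction).
Passing tests therefore demonstrate correctness of the *computations* and
internal consistency of the pipeline on controlled inputs — not clinical
performance of the segmentation thresholds or indices on patient data.

The synthetic cohort (default n = 20) redraws lesion geometry, region ADC
means, per-target engineered homogeneity (normal around 0.086/0.078/0.151
for the 70/66/60 Gy targets) and per-target coverage (uniform on
[0.92, 0.999]); coverage drives both CI and the DVH cold tail, giving the
cohort a built-in positive coverage–TCP relation. Because the boost
targets are simultaneously the densest and the most homogeneous, the
density-weighted IOE(H) sits below the plain form in every generated
patient — the directional behaviour the composite was designed to show.

## Numerical and design choices

* Grid convention: 1-based `(i, j, k)` indices, `k` the slice axis,
  physical position `origin + (index − 1) · spacing` mm — one convention
  everywhere, chosen to match R's array semantics and NIfTI axis order.
* Rasterization: a voxel belongs to a contour iff its centre is inside
  (even-odd rule) — exactly testable against analytic areas.
* I/O: NIfTI-1 via RNifti for volumes (header value scaling applied on
  read, so dose arrives in Gy); structure sets as one binary label volume
  per structure plus a JSON index, which round-trips losslessly and
  preserves overlapping structures. Scalars are written as float64, so
  write→read is voxel-identical.
* Connected components and physical-margin dilation are implemented in the
  package (breadth-first labelling; structuring-element dilation honouring
  per-direction margins as an ellipsoidal physical-distance test) and
  verified against independent oracles: a min-label-propagation flood
  fill and a brute-force Euclidean-distance dilation.
* Statistics are delegated to the standard implementations
  (`nortest::lillie.test` for the estimated-parameter K–S normality test,
  `stats::wilcox.test` exact for ≤ 25 tie-free pairs, `stats::cor.test`
  Spearman with average ranks); the module adds the preconditions (sample
  sizes, constancy, zero differences) and the cohort-table orchestration.
  All tests are two-sided at 0.05.
* Degenerate inputs: empty prostate or target masks error; empty
  structures in a set warn; an absent risk class drops its CTV with a
  message and evaluation proceeds on the remainder.

## Problem sizes

The test suite exercises small grids (≈ 64×64×32) for unit properties and
the default 96×96×48 geometry for parameter-recovery and cohort checks;
the acceptance script evaluates a 20-phantom cohort at full resolution,
which completes in a few minutes on one core. These sizes were chosen as
the smallest at which voxel-count granularity no longer limits the ±0.01
recovery checks.

## Known limitations

* DICOM I/O is not implemented; volumes and structures travel as NIfTI-1
  and label volumes. Dose-grid value scaling is honoured through the
  NIfTI header mechanism.
* The ADC→cellularity map is relative and uncalibrated; absolute
  cellularity (cells/mm³) is out of scope.
* TCP parameters are placeholders (see above); no NTCP, EUD or
  repopulation modelling.
* The component filter and thresholds are literal implementations of the
  stated rules; their clinical validity on patient data is not addressed
  by the synthetic evidence here.
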