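---
title: "Quantifying choroidal vascularity on EDI-OCT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying choroidal vascularity on EDI-OCT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choroidcvi)
```

## The measurement problem

The choroid is the vascular layer between the retinal pigment epithelium
(RPE) and the sclera. Its thickness is widely used to track chorioretinal
disease, but thickness confounds true vascular change with diurnal
variation, refractive error, age and axial length. The choroidal
vascularity index (CVI) normalizes away much of that nuisance variation: on
an enhanced depth imaging OCT (EDI-OCT) B-scan, the subfoveal choroid is
binarized into dark *luminal* pixels (vessel lumens, area LA) and bright
*stromal* pixels (interstitium, area SA), and

$$\mathrm{CVI} = \frac{LA}{TCA}, \qquad TCA = LA + SA,$$

where TCA is the total area of a 1500 µm-wide choroidal block centred at
the fovea, bounded above by the outer RPE border and below by the
choroid–sclera junction (CSJ). Being a ratio of areas from the same scan,
CVI is invariant to the pixel scales and insensitive to uniform brightness
shifts, which is what makes it a candidate biomarker for longitudinal
monitoring (for instance of panuveitis under immunosuppression, where group
mean CVI dropping from about 74% to 69% over three months is the kind of
signal at stake). The companion LA/SA ratio says whether a change in TCA
is driven by the vascular or the interstitial compartment; note the
algebraic link CVI = (LA/SA)/(1 + LA/SA).

This package implements the full measurement chain — geometry, binarization,
metrics — plus OCTOR-style per-layer summaries over a raster of scans, a
phantom generator with known ground truth, and the paired cohort statistics.

## Inputs and coordinate conventions

A B-scan enters as an 8- or 16-bit grayscale matrix with explicit lateral
and axial scales in µm/px. The scales are mandatory metadata: clinical OCT
exports do not embed them reliably, and the on-image ruler is the usual
source. B-scan pixels are anisotropic (typically ~11.6 × 3.87 µm on a
Spectralis-like device), so **both** scales enter every area:
one pixel covers `lateral_scale * axial_scale` µm². Using the lateral scale
isotropically, as a naive ImageJ calibration would, distorts areas by the
anisotropy ratio; CVI itself is unaffected (the factor cancels), but TCA,
LA and SA are not.

Layer boundaries (ILM, inner/outer RPE, CSJ) are an input, not something
the package segments: they arrive as sparse polylines in a small JSON
format (0-based x/row vertex pairs) and are densified to one row per column
by linear interpolation at load time. Internally everything is 1-based, as
R matrices are; the conversion happens once at the JSON boundary, and
ordering (ILM ≤ RPE_inner ≤ RPE_outer ≤ CSJ wherever all four are defined)
is validated on load, reporting the first offending column in the file's
own 0-based coordinate.

Two conventions the literature leaves unstated had to be fixed:

* **Boundary-pixel ownership.** A row exactly on a boundary belongs to the
  layer *beneath* its inner boundary: the choroidal band in column $c$ is
  $\{r : \mathrm{RPE_{outer}}(c) < r \le \mathrm{CSJ}(c)\}$. This makes
  adjacent layers partition the scan with no shared or orphaned rows
  (retina + RPE + choroid thicknesses sum exactly to the ILM→CSJ
  distance).
* **Window centring.** The 1500 µm window spans
  $w = \mathrm{round}(1500/\text{lateral scale})$ columns,
  $\lfloor w/2 \rfloor$ of them left of the foveal column — deterministic,
  with centre bias at most one pixel. If no foveal column is supplied, it
  is located as the column of minimum ILM→inner-RPE (retinal) thickness,
  ties breaking to the lowest index.

## The binarization chain

The chain mirrors standard practice: (1) 16-bit images are min–max
rescaled to 8 bits (rounding half-up; 8-bit input passes through
untouched); (2) an optional signed brightness offset is applied and clamped
— exposed as a parameter defaulting to 0, because published protocols
"reduce brightness" by an unreported amount; (3) a threshold surface is
computed; (4) ROI pixels strictly below their threshold become luminal,
the rest stromal. The strict-less tie rule makes constant regions stromal —
the conservative choice, since a featureless region carries no evidence of
vessels.

Thresholding methods, all over a $(2r+1)^2$ sliding window with
**reflection padding** at the edges (padding avoids the systematic
threshold bias that zero- or edge-replication padding induces at the ROI
borders):

* **Niblack** (default): $T = \mu_w + k\,\sigma_w$ with $r = 15$ px,
  $k = 0.2$ — the de-facto defaults of the ImageJ auto-local-threshold
  implementation used in the field; $\sigma_w$ is the population sd.
* **Phansalkar**: $T = \mu_w\,(1 + p\,e^{-q\mu_w/255} + k(\sigma_w/R - 1))$
  with $p = 2$, $q = 10$, $R = 127.5$, $k = 0.25$.
* **Otsu**, windowed or global (global computes one threshold from the
  histogram of ROI pixels only). On histograms where the between-class
  variance has a tied plateau — e.g. an exactly two-level image, where
  every split between the levels is equivalent — the plateau midpoint is
  taken, matching the common ImageJ convention and keeping the threshold
  centred between well-separated modes.

Window statistics are computed with summed-area tables, so thresholding is
linear in image size; windowed Otsu is quadratic in the window and meant
for modest images. The original "convert back to RGB and colour-threshold"
step of the published protocol is modelled directly as the mask complement
within the ROI — an equivalent partition without the colour-space detour.

The suite verifies Niblack against a brute-force per-pixel window loop
(exact on random images up to 32×32) and global Otsu against EBImage's
independent implementation.

## Layer metrics over a raster

For OCTOR-style summaries, each layer (retina = ILM→inner RPE, RPE complex,
choroid) yields a per-column thickness profile (µm), a mean intensity
(mean 8-bit value in the band divided by 255, landing on the conventional
0–1 scale), and a volume: per-scan cross-sectional areas are integrated
across the raster by the **trapezoidal rule** at the supplied inter-scan
spacing. The spacing is required input — converting a "20° × 15°" raster to
micrometres depends on axial length, which the package does not model; the
fixture value of 625 µm for 7 scans is an arbitrary documented default, not
a calibration. The unpublished details of OCTOR's intensity definition mean
intensity comparisons are qualitative only.

## The phantom generator

Every pipeline stage is testable without patient data through a
two-compartment phantom: flat (optionally sinusoidal) boundaries, a
choroidal band of bright stroma (level 180) into which dark elliptical
lumens (level 40, semi-axes 2–6 px) are planted at band-uniform random
positions — overlap allowed, the luminal fraction measured on the union —
until the band's luminal fraction reaches the target $f_{true}$. Because
each ellipse adds at most ~1% of the band, the achieved fraction lands
within 0.02 of the target, and it is recomputed from the final mask and
stored as the ground truth. Speckle is modelled as multiplicative unit-mean
gamma noise (the standard first-order surrogate for coherent-imaging
speckle), default variance 0.05, applied before clamping to [0, 255]. The
default geometry is Spectralis-like: 200 × 150 px at 11.6 × 3.87 µm/px
with a 70 px ≈ 271 µm choroidal band, inside the normative subfoveal
thickness range. All randomness flows from one explicit seed; the caller's
RNG state is untouched.

What the phantom does **not** emulate: the OCT point-spread function,
depth-dependent attenuation and vessel shadowing, the graded
Sattler/Haller vessel-calibre structure, or segmentation error in the
boundaries (phantom boundaries are exact). Passing the phantom recovery
tests therefore demonstrates that the measurement chain is unbiased on
two-compartment images with multiplicative noise — not that CVI on clinical
scans is accurate in an absolute sense, where the unknown original
brightness reduction and Niblack window of any published protocol would
matter.

Two recovery regimes anchor the validation:

* noiseless phantoms with the global Otsu threshold recover the achieved
  fraction *exactly* (the binarization has no slack to hide in);
* with speckle variance 0.05 and Niblack defaults, the mean absolute CVI
  error over 30 phantoms per target fraction (0.55, 0.65, 0.75) stays
  below 0.05. The residual error is a small upward bias, largest at low
  fractions: near the bright RPE edge the local window mean rises and
  drags some stroma under the threshold.

## The paired cohort model

`generate_cohort()` emulates a paired longitudinal design with the study
conditions as defaults: 19 eyes, group-mean luminal fraction 0.74 at
baseline falling to 0.69 at follow-up, between-eye sd 0.047 (the observed
baseline spread), and a per-eye paired decrease with sd 0.028 — the
absolute spread implied by a percent change of 6.2 ± 3.8 on a 74.1%
baseline. Each eye keeps its geometry across visits (CSJ jittered ±8 px
between eyes) and receives an independent lumen fill per visit, so
within-eye correlation is high, as in repeated imaging of one choroid.
Under these conditions a paired Wilcoxon signed-rank test on pipeline CVI
detects the drop in essentially all of 100 replicate cohorts
(the validation threshold is ≥ 90%).

## Statistics

The signed-rank test is implemented in-package because the required
conventions are not all available together in `stats::wilcox.test`:
zero differences dropped, average ranks on ties, statistic
$W = \min(W^+, W^-)$, and an **exact, tie-aware** two-sided p-value for up
to 25 effective pairs, computed by dynamic programming over the doubled
ranks (doubling puts tied average ranks on integers). Beyond 25 pairs a
normal approximation with continuity and tie corrections takes over. The
exact path is property-tested against full $2^n$ sign enumeration, and
against `wilcox.test` where the latter's exact path applies (tie-free
data).

t-tests (Welch by default for two samples — the variant is otherwise a
silent assumption — and paired when declared) and one-way ANOVA delegate to
`stats::t.test` and `stats::aov`; ANOVA reports
$R^2 = SS_{between}/SS_{total}$ from the fitted decomposition. Percent
change is baseline-anchored, $100\,(x_{base} - x_{follow})/x_{base}$,
positive for a decrease; the percent change of group means need not equal
the mean of per-eye percent changes, and the package always computes the
latter from per-eye values. P-values are reported unadjusted for multiple
comparisons, mirroring common practice in small cohort studies; treat the
battery's smallest p-values accordingly.

## Degenerate inputs, deliberately defined

* Constant 16-bit image → all-zero 8-bit image (min–max rescale has no
  range), documented rather than an error.
* Empty ROI → empty partition, CVI missing (`NA`); all-luminal ROI →
  LA/SA missing.
* Zero baseline → percent change missing with a warning.
* All-zero paired differences → p = 1 with a warning; all-identical ANOVA
  input → F missing, $R^2 = 0$ with a warning.
* A subfoveal window clipped by the image edge proceeds with a warning
  once more than 10% of the requested width is lost.

## Problem sizes used in the validation suite

The shipped tests and the acceptance script use 30 phantoms per target
fraction for recovery, 100 replicate 19-eye cohorts for the power check,
20 random images for the Niblack oracle and 50 random paired samples for
the signed-rank enumeration oracle — sizes chosen so the whole suite
completes in a few minutes on one core while keeping Monte-Carlo noise
well inside the stated tolerances.

## Known limitations

* The exact Niblack radius/k and the brightness reduction used in
  published clinical protocols are unreported, so per-eye published values
  cannot be pixel-matched; validation rests on phantoms and on the
  published worked example (LA = 1.21, TCA = 1.84 mm² → CVI = 65.76%).
* Sattler/Haller sublayer separation and vessel connectivity are out of
  scope.
* The spreadsheet importer maps a user-declared column layout; deposited
  datasets vary and are not redistributed with the package.
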