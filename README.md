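# choroidcvi

Quantifies the choroid on enhanced depth imaging OCT (EDI-OCT) B-scans.
Given a grayscale B-scan and manually segmented layer boundaries, the
package builds the 1500 µm subfoveal choroidal block, binarizes it into
dark **luminal** (vascular) and bright **stromal** (interstitial) pixels,
and reports the indices used to monitor choroidal disease longitudinally:

- **TCA** — total subfoveal choroidal area (mm²), the block between the
  outer retinal pigment epithelium (RPE) border and the choroid–sclera
  junction (CSJ);
- **LA / SA** — luminal and stromal areas (mm²), with LA + SA = TCA
  exactly;
- **CVI** — the choroidal vascularity index, CVI = LA / TCA, a proportion
  usually reported in percent. Being a within-scan ratio it is robust to
  the physiological nuisance (diurnal variation, age, refraction) that
  confounds raw choroidal thickness;
- **LA/SA** — which compartment drives a change in TCA;
- **SFCT / CT** — subfoveal and mean choroidal thickness (µm).

Binarization follows the standard auto-local-threshold chain: 8-bit
conversion, optional brightness offset, then Niblack thresholding
(T = mean + k·sd over a sliding window; Phansalkar and local/global Otsu
are available alternatives), with pixels below threshold counted as
luminal. Around the core pipeline the package provides OCTOR-style layer
thickness/volume/intensity summaries over a raster of scans, a synthetic
phantom generator with known ground-truth luminal fraction, and the paired
cohort statistics (exact Wilcoxon signed-rank, Welch/paired t, one-way
ANOVA with R², percent change). It is aimed at ophthalmic imaging
researchers validating or applying CVI-style measurements.

## Worked example

Generate a speckled phantom with a known luminal fraction of 0.65 and run
the full pipeline on it:

```r
library(choroidcvi)

ph <- generate_phantom(phantom_spec(f_true = 0.65, speckle_var = 0.05, seed = 42))
ph
#> <phantom_truth> 150 x 200 px, f_true 0.650, achieved 0.6513, speckle var 0.05

metrics <- cvi_pipeline(ph$image, ph$boundaries, eye_id = "demo_eye")
as.data.frame(metrics)
#>     eye_id    visit TCA_mm2 LA_mm2 SA_mm2    CVI LA_SA SFCT_um CT_um
#> 1 demo_eye baseline  0.4054 0.2707 0.1347 0.6678  2.01   270.9 270.9
```

The 1500 µm window at 11.6 × 3.87 µm/px covers 129 columns of a ~70-pixel
band, giving TCA ≈ 0.41 mm². The estimated CVI (0.668) sits within 0.02 of
the phantom's achieved luminal fraction (0.6513); the residual is Niblack's
small upward bias near the bright RPE edge plus window sampling. SFCT and
CT are both 270.9 µm because the phantom band is flat. On the published
normative mean areas the package reproduces the textbook value:

```r
m <- choroid_metrics_from_areas(LA_mm2 = 1.21, TCA_mm2 = 1.84)
round(100 * m$CVI, 2)
#> [1] 65.76
```

Paired statistics work on plain vectors or on long cohort tables
(`eye_id, group, visit, metric, value`; see
`inst/extdata/synthetic_cohort_cvi.csv` for the layout):

```r
ht <- wilcoxon_signed_rank(c(74.8, 71.2, 79.0, 69.9, 75.4, 70.1, 77.7, 72.0),
                           c(70.1, 68.3, 74.2, 66.0, 71.9, 70.8, 71.5, 69.4))
ht
#> <cvi_htest> wilcoxon_signed_rank: W = 1, p = 0.01562, n = 8 [exact]
tidy(ht)   # broom-style one-row summary
```

`autoplot()` renders binarized partitions and phantoms;
`plot_cohort_metric()` draws the group-by-visit box plots. A thin
command-line wrapper over the same functions ships in
`inst/cli/choroidcvi.R` with `compute`, `phantom`, `layers` and `stats`
subcommands.

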