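---
title: "Validating MALDI-MSI lipid images against absolute quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating MALDI-MSI lipid images against absolute quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msiresponse)
```

## The problem and the statistic

MALDI mass spectrometry imaging (MSI) maps lipid ion intensities across a
tissue section at tens-of-micrometer resolution, but ion yield is a strong
function of the local environment: co-extracted analytes suppress each
other (phosphatidylcholine famously suppresses phosphatidylethanolamine in
positive mode), and salt levels, matrix morphology and tissue
microstructure all modulate the signal. A raw ion image is therefore not a
concentration map, and the error is not a global scale factor — it is
tissue-type specific.

This package implements the workflow that quantifies this discrepancy. Two
measurements are combined for each lipid $L$, tissue region $r$ and
ionization modality $m$ (conventional MALDI or laser-postionized MALDI-2):

* the **MSI side**: the mean intensity over the region's pixels, summed
  over the lipid's accessible adduct species
  $\bar I_{L,r,m} = \sum_{a} \operatorname{mean}_{p \in r} I_{L,a,m}(p)$
  (protonated, sodiated and potassiated species in positive mode; the
  deprotonated species in negative mode);
* the **quantification side**: the region's absolute molar concentration
  $c_{L,r}$ in nmol/mm$^3$, obtained by laser-microdissecting the region,
  extracting it with an internal-standard spike, and quantifying by
  internal-standard external calibration of LC-MS peak areas.

Their ratio is the **signal response factor**

$$ R_{L,r,m} \;=\; \frac{\bar I_{L,r,m}}{c_{L,r}} \quad
   \left[\text{intensity per (nmol/mm}^3)\right], $$

"signal intensity per mol". If imaging were quantitative, $R$ would not
depend on $r$; the ratio $R_{L,\mathrm{ML},m} / R_{L,\mathrm{WM},m}$
(molecular layer vs. white matter in the cerebellum application) measures
the region bias, and $R_{L,r,\mathrm{MALDI2}} / R_{L,r,\mathrm{MALDI}}$
measures what postionization changes.

## Lipid mass arithmetic

Lipids are treated at sum-composition level — class plus total acyl
carbons and double bonds, e.g. `PC(34:1)` — because accurate mass alone
cannot resolve acyl isomers. Molecular formulas for diacyl PC, PE and PG
and d18:1 sulfatides are generated from the class composition rules, and
m/z values are summed from an embedded monoisotopic mass table (H
1.0078250319, C 12, N 14.0030740, O 15.9949146, Na 22.9897693, P
30.9737615, S 31.9720707, K 38.9637065, D 2.0141018, electron 0.0005486
Da). The table is fixed in code rather than configurable: every reported
mass is reproducible from the package alone. Adduct deltas include the
electron mass (charged-species convention), so `[M+H]+` adds 1.007276 Da;
users comparing against neutral-fragment arithmetic will see a ~0.55 mDa
offset.

Two consequences of this arithmetic matter for assignment at 5 ppm:

* `find_near_isobars()` enumerates adduct pairs closer than a tolerance.
  The classic trap in this panel is the sodiated PC versus the protonated
  PC with two more carbons and three more double bonds — a
  composition-independent gap of 2.406 mDa (the difference Na + H − C$_2$,
  about 3 ppm at m/z 800).
* `resolvable()` applies FT-type resolution scaling
  $R(m) = R_{200}\sqrt{200/m}$: at a resolving power of 280,000 (stated at
  m/z 200) the FWHM near m/z 867 is ~6.4 mDa, so the 2.4 mDa family is
  *not* resolvable there, while ~28 mDa separations are.

Only diacyl glycerophospholipids and d-series sulfatides are modeled; the
target panel contains nothing else, and ether/plasmalogen chemistry is out
of scope. Deuterated internal standards are written `PC(15:0/18:1)-d7`
and handled by exact H→D substitution.

## The synthetic data generators

No public dataset accompanies the workflow, so the package ships
generators that plant known truth and let every downstream stage be tested
end to end.

**Tissue truth** (`default_ground_truth()`): a deterministic two-region
geometry — a lobed white-matter-like (WM) core inside a molecular-layer-like
(ML) ellipse on a background margin — carrying the measured concentrations
of the six-lipid cerebellum panel (sulfatide 10.2/0.37, PG(34:1)
0.41/0.43, PE(34:1) 1.46/0.46, PC(34:1) 9.07/7.00, PC(38:4) 1.17/1.20,
PC(40:6) 1.25/2.14 nmol/mm³ in WM/ML). The planted response factors
reproduce the observed phenomenology rather than any published number
(none is printed): an ML-biased response for all glycerophospholipids,
amplified under MALDI-2; a MALDI-2 gain for PE/PG in both regions but for
PC only on the ML; and a slightly WM-biased, MALDI-2-attenuated sulfatide
response in negative mode. Adduct fractions default to 0.35/0.40/0.25 for
H/Na/K — untreated fresh-frozen tissue is alkali-adduct rich — and sum to
1 per lipid so that summed-adduct recovery is exact in the noise-free
limit.

**MSI generator** (`simulate_msi()`): each tissue pixel receives, per
panel ion, an expected intensity
$R_{L,r,m} \cdot c_{L,r} \cdot f_{L,a}$ multiplied by lognormal noise of
configurable CV (lognormal keeps intensities positive and matches the
multiplicative character of shot-to-shot variation; the mean is kept at 1
so ROI means are unbiased), with Gaussian m/z jitter in ppm; matrix-derived
peaks appear everywhere, including background; an optional seeded pixel
subset is scaled by a hotspot multiplier, and the mask is returned so
hotspot handling can be verified against truth. MALDI-2 is modeled purely
as a different response-factor table — no plume physics. Pixel spacing is
the only representation of undersampling; ablation-spot geometry, isotope
envelopes, profile-mode spectra and detector saturation are not modeled.
Passing tests therefore demonstrate correct *bookkeeping and statistics*
of the pipeline, not robustness to every artifact of real spectra.

**LC-MS generator** (`simulate_lcms_run()` and relatives): HILIC class
separation is reduced to one retention time per lipid class (PG 3.5, PE
5.0, PC 7.0, sulfatide 9.0 min, σ = 0.05 min), with peak area strictly
proportional to injected amount (10¹² intensity·min per mol) times
lognormal noise. The calibration series mirrors the wet-lab layout: nine
log-spaced levels from 10⁻⁷ to 10⁻⁴ mol/L (stand-ins — the real level list
is not printed), each vial carrying every analyte at that concentration in
the 20 µL extract volume plus the same 5 µL internal-standard spike
(5·10⁻¹⁰ mol per class), measured in three technical replicates.
`simulate_calibration_series(corrupt_level =)` plants a
replicate-to-replicate analyte preparation error with a deterministic
spread pattern, so the exclusion logic can be shown to trigger exactly
there and nowhere else. Dissected-region extracts follow
mol = c · area · thickness · efficiency with 20 µm sections; three
independent section-level extracts each measured in three technical
replicates.

## Imaging pipeline choices

* **Ion images**: "5 ppm accuracy" is implemented as a symmetric ±5 ppm
  window (configurable); in-window centroids are summed by default
  (`max` available).
* **TIC normalization** is provided (`tic_normalize()`) but response
  factors use raw intensities by default: with very unevenly distributed
  dominant species, per-pixel TIC scaling introduces region bias of its
  own.
* **Hotspot removal** is 0.99-quantile clipping with the interpolation
  quantile (values 1..100 clip at 99.01). The commercial feature it
  stands in for is undocumented; quantile clipping is the accepted
  equivalent. One subtlety: with interpolation quantiles a second pass can
  shave the sliver between the two top order statistics, so the operation
  is idempotent only to ~0.1% — tests assert exactly that. Response
  factors default to *raw* (non-clipped) ROI means; clipping is exposed
  via `hotspot_quantile` where image cosmetics matter.
* **Segmentation** uses the per-pixel intensities of the 50 most abundant
  dataset-wide peak bins (binned at the ppm tolerance), TIC-normalized,
  optionally median-filtered on the pixel grid ("weak" = 3×3, "strong" =
  5×5), then k-means with a fixed seed and multiple restarts. Weak
  denoising is the default for noisy data; on noise-free synthetic images
  the filter is counterproductive (it erodes the thin WM lobes at small
  grid sizes), which is why exactness tests run with `denoise = "none"`.
  Background is simply one more cluster — always budget a k that includes
  it.
* **ROI statistics** include zero-intensity pixels in the mean (whether
  the reference software does is unstated; zeros-included is the
  documented choice here). ROI area is pixel count × (pixel size)².

## Quantification choices

* **Peak detection** thresholds local maxima at median + 3·MAD of the
  XIC; bounds walk outward to the nearest valley or the first point below
  1% of apex height. Area is the trapezoid over the bounds — it is
  compared against a fine-grid oracle over the *same* bounds in tests,
  because the 1%-of-apex cut deliberately discards far-tail mass.
* **Calibration** is OLS of mean area ratio vs. concentration with
  replicate-CV level exclusion at 20% ("high deviations" made concrete;
  configurable). `fit_calibration()` defaults to unweighted OLS, but the
  panel-level wrapper `fit_panel_calibrations()` defaults to 1/x
  weighting. The reason is structural, not cosmetic: with levels spanning
  three decades and relative (CV-type) noise, the unweighted intercept
  inherits the *absolute* residuals of the top levels (~±0.015 in ratio
  units at 5% CV), which is the same order as the entire signal of a
  low-concentration sample — back-calculation near the low end then fails
  by factors, not percent. Inverse-concentration weighting restores
  near-constant relative weight and is standard practice for exactly this
  design. Both options are exposed.
* **Back-calculation** clamps negative concentrations to zero with a
  warning; a missing internal-standard peak is a hard error (it signals a
  failed spike or extraction, not a zero concentration).
* **Volume normalization**: amount = conc × 20 µL; volume = area × 20 µm.
  The SD reported per lipid/region is across the three section-level
  extracts with technical replicates averaged first — the replicate
  structure of dissection, not of injection. 100% extraction recovery is
  assumed (the IS is spiked before extraction and corrects losses by
  design); the simulator can inject efficiency < 1 to demonstrate that
  correction.
* **Interference screening**: all XIC peaks outside the expected
  retention window count as interferents; the screen is clean when every
  contribution is ≤ 5% of the main peak area.

## Numerical and reproducibility choices

All stochastic operations take explicit seeds and default to 1; identical
configuration and seed give byte-identical imzML and CSV outputs (the
imzML identifier is derived deterministically from the data). Ties in
k-means are resolved by the fixed seed; quantiles use the default
interpolation definition throughout. The imzML reader/writer covers
processed-mode centroid data with 64-bit little-endian arrays — the only
layout the generators emit — and rejects continuous-mode files rather than
misreading them. Chromatograms are stored as a plain columnar CSV (rt,
m/z, intensity plus header metadata) readable by any table tool.

## What the recovery tests show

The test suite closes the loop at the study's conditions: a 100×100-pixel
two-region image, 10% multiplicative noise, 1 ppm mass jitter, the planted
panel concentrations above, 20 independent seeds. Segmentation-derived
ROIs (labeled by majority overlap with the planted regions) feed the
MSI side; a fresh calibration series and dissected-extract runs feed the
quantification side. Across seeds, the median recovered concentration is
required within 10% of truth for every lipid × region, median response
factors within 15% (and within 10% with no systematic sign bias overall),
and the bias and modality-gain ratios within 15%. Unit tests run the same
machinery at 10×10 to 40×40 and noise-free, where recovery must be exact.
These sizes keep the full suite around a minute; they are statements about
estimator correctness under the stated noise model, not about robustness
to real-tissue artifacts (section folds, matrix crystallization gradients,
mass-axis drift), which the generators deliberately do not emulate.

## Known limitations

* Sum-composition lipid model only; no MS/MS, no ether lipids, no isotope
  patterns beyond single-label substitution.
* The segmentation is plain k-means on peak features — adequate for the
  two-region phantom, not a general tissue classifier.
* Retention-time alignment across LC-MS runs is not implemented; the
  generators emit aligned runs.
* The response-factor comparison is descriptive (ratios), matching the
  source workflow; no inferential statistics are attached.
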