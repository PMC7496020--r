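# msiresponse

Validation of MALDI mass spectrometry imaging (MSI) of membrane lipids
against absolute quantification.

## The problem

MALDI-MSI (and its laser-postionization variant MALDI-2) images lipid ion
intensities across a tissue section, but ion yields depend on the local
tissue environment — ion suppression, salt levels, matrix behavior — so a
raw ion image is not a concentration map, and the distortion differs
between tissue types. This package is for analysts who want to *measure*
that distortion: it combines region-of-interest MSI intensities with
absolute molar concentrations from laser-microdissection (LMD) plus LC-MS
quantification into the tissue- and modality-specific **signal response
factor**

```
R(lipid, region, modality) = mean summed ion intensity in region
                             ─────────────────────────────────────
                             molar concentration [nmol/mm³]
```

("signal intensity per mol"). Ratios of response factors quantify the
region bias (e.g. molecular layer vs. white matter in cerebellum) and the
effect of MALDI-2 postionization.

What's inside, module by module:

* **Lipid mass arithmetic** — shorthand-name parsing (`PC(34:1)`,
  `PE(16:0/18:1)`, `SHexCer(d18:1/24:1)`, deuterated standards
  `...-d7`), molecular formulas, monoisotopic masses, adduct m/z
  (`[M+H]+`, `[M+Na]+`, `[M+K]+`, `[M-H]-`, `[M+OAc]-`), near-isobar
  enumeration and Orbitrap-style resolvability checks.
* **Synthetic data** — ground-truthed generators for two-region MSI
  images (region-specific concentrations and response factors, adduct
  fraction mixes, ppm jitter, lognormal noise, hotspots) and HILIC-type
  LC-MS runs (class retention windows, internal standards, a nine-level
  calibration dilution series, optional isobaric interferents).
* **Imaging pipeline** — imzML I/O (processed-mode centroid),
  ppm-tolerant ion images, TIC normalization, quantile hotspot clipping,
  k-means spectral segmentation with median-filter denoising, ROI means
  and summed-adduct intensities.
* **Quantification** — extracted ion chromatograms, peak detection and
  trapezoidal integration, internal-standard external calibration with
  replicate-CV level exclusion (a classed model object with `coef`,
  `predict`, `plot`, `residuals` methods), tissue-volume normalization
  to nmol/mm³, and a 5% isobaric-interference screen.
* **Response analysis** — response factors, ML/WM bias ratios,
  MALDI-2/MALDI gains, and a combined CSV report.

## Worked example

Mass arithmetic — the protonated PE(40:6) ion and the classic
sodiated/protonated PC near-isobar family:

```r
library(msiresponse)

adduct_mz("PE(40:6)", "[M+H]+")
#> <ion_species> PE(40:6) [M+H]+  m/z 792.5538

head(find_near_isobars("PC", c("[M+H]+", "[M+Na]+"),
                       c(30, 44), c(0, 6), tol_mda = 5)[, c(1, 2, 4, 5, 7)], 3)
#>     name_a adduct_a   name_b adduct_b delta_mda
#> 3 PC(30:1)  [M+Na]+ PC(32:4)   [M+H]+  2.405668
#> 6 PC(31:2)  [M+Na]+ PC(33:5)   [M+H]+  2.405668
#> 9 PC(32:3)  [M+Na]+ PC(34:6)   [M+H]+  2.405668
```

Every sodiated PC sits 2.406 mDa from the protonated PC with two more
carbons and three more double bonds — unresolvable at a resolving power
of 280,000 (at m/z 200) near m/z 750, as `resolvable()` will confirm.

The complete synthetic validation loop — simulate both modalities,
segment, derive ROIs, quantify by calibrated LC-MS, form response
factors:

```r
cfg <- pipeline_config(msi = list(grid_shape = c(40L, 40L)), seed = 1L)
res <- run_full_pipeline(cfg, "demo_out")

res$quant[, c("lipid_name", "region", "tissue_concentration", "sd")]
#>             lipid_name region tissue_concentration     sd
#> 1             PG(34:1)     WM                0.484 0.0107
#> 3             PC(34:1)     WM                8.978 0.5221
#> 6  SHexCer(d18:1/24:1)     WM               10.068 0.3722
#> 9             PC(34:1)     ML                6.961 0.3121
#> 12 SHexCer(d18:1/24:1)     ML                0.385 0.0130
#> ...

res$report$table[res$report$table$lipid_name == "PC(34:1)", ]
#>   lipid_name region modality polarity intensity concentration response
#> 1   PC(34:1)     ML    MALDI        +     41820          6.96     6008
#> 2   PC(34:1)     WM    MALDI        +     18581          8.98     2070
#> 3   PC(34:1)     ML   MALDI2        +     83615          6.96    12012
#> 4   PC(34:1)     WM   MALDI2        +     19702          8.98     2195
#>   bias_ratio modality_gain
#> 1       2.90          2.00
#> 2       2.90          1.06
#> 3       5.47          2.00
#> 4       5.47          1.06
```

Reading the output: recovered concentrations track the planted truth
(sulfatide 10.2/0.37, PC(34:1) 9.07/7.00 nmol/mm³ in WM/ML; this is one
10%-noise realization). Although PC(34:1) is *more* concentrated in white
matter, its response factor is ~3× higher on the molecular layer under
MALDI (`bias_ratio` 2.9) and ~5.5× under MALDI-2 — the image inverts the
chemistry — and postionization doubles the ML response while leaving WM
nearly unchanged (`modality_gain` 2.00 vs 1.06). Those are exactly the
planted distortions, read back by the full pipeline.

A thin command-line wrapper covers the same stages
(`simulate-msi`, `ion-images`, `segment`, `roi-stats`, `quantify`,
`interference`, `response`, `full-run`):

```sh
Rscript inst/cli/msiresponse full-run --config demo.yaml --out demo_out
```

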