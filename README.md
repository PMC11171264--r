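# melbands

Spatial band morphometry and prognostic modelling for multiplex
immunohistochemistry (mIHC) melanoma slides.

Melanoma prognosis leans on Breslow thickness and mitotic rate, yet tumors
of similar thickness diverge widely in outcome. Nuclear morphology and the
spatial arrangement of proliferating tumor cells carry additional signal.
`melbands` extracts that signal from per-cell detection exports (DAPI /
Ki67 / S100 mIHC): it gates each marker adaptively per slide, partitions
the tumor into **superficial / middle / invasive** depth bands, computes
per-band densities and nucleus-size factors, and evaluates them in Cox
proportional-hazards models with concordance statistics. A bundled
synthetic slide/cohort generator with retained latent truth makes the whole
pipeline testable without patient data.

## The method in brief

**Two-phase gating, per slide and marker.** Log intensities are split by
Otsu's criterion — the threshold maximising the between-class variance
σ²_B(t) = ω₀ω₁(μ₀−μ₁)² over 256 histogram bins spanning the 1st–99th
percentile — into background T₀ and foreground T₁. Then log T₁ is fitted
with a two-component Bayesian Gaussian mixture
p(x) = π₁N(x|μ₁,σ₁) + π₂N(x|μ₂,σ₂) by deterministic MAP-EM, and the final
threshold solves π₁N(x|μ₁,σ₁) = π₂N(x|μ₂,σ₂) between the component means;
cells on the higher-mean side are positive.

**Band geometry.** PCA of the tumor boundary gives the depth axis and the
estimated thickness T (epidermis-facing edge to deepest point). A Euclidean
distance transform from the epidermis-adjacent boundary assigns per-pixel
depth; thirds of T cut the tumor into bands ([0,T/3) superficial,
[T/3,2T/3) middle, [2T/3,∞) invasive), and the deep-facing boundary at
depth ≥ 2T/3 is the invasive margin.

**Factors and survival.** Per band: cell density, colocalized
(S100⁺Ki67⁺) cell density, colocalized-to-total and -to-tumor ratios, and
mean nucleus areas (all cells / tumor cells / colocalized cells, µm²),
joined with mitosis, Breslow thickness, estimated thickness and age.
Univariable Cox screens and base+1 multivariable models (mitosis +
thickness + one invasive-band size factor) report hazard ratios with Wald
95% CIs, Harrell's concordance with bootstrap CIs, and leave-one-out
cross-validated concordance.

## Worked example

```r
library(melbands)

sim  <- simulateSlide(slideSimConfig(seed = 42), slideId = "demo")
gate <- gateMarker(sim$cells, "ki67")
gate$gate
#> MarkerGate: demo / ki67 (nucleus mean)
#>   Otsu split: 2.0009 (log), 7.39574 (linear); foreground n = 2390 of 3682
#>   final threshold: 53.8184 (linear), 3.986 (log)

geom <- partitionBands(sim$annotation, resolution = 10)
geom
#> BandGeometry: demo
#>   depth axis: (0.000, 1.000); estimated thickness 3.000 mm
#>   band areas (mm^2): superficial 6.018, middle 6.007, invasive 5.975
#>   raster: 10 um/px; invasive margin: 1201 vertices

cells <- sim$cells
cells$ki67_pos <- gate$positive
cells$s100_pos <- gateMarker(cells, "s100")$positive
cells <- classifyCategories(annotateCells(cells, geom))
feat  <- assembleFeatures(
  data.frame(patient_id = "demo", age = 61, mitosis = 4, thickness = 3.1),
  bandAggregates(cells, geom), geom)
round(t(feat[, c("estimated_thickness", "cell_density_invasive",
                 "coloc_total_ratio_invasive", "nuclei_size_invasive",
                 "tumor_nuclei_size_invasive")]), 3)
#> estimated_thickness          3.000
#> cell_density_invasive      204.847
#> coloc_total_ratio_invasive   0.199
#> nuclei_size_invasive        39.783
#> tumor_nuclei_size_invasive  39.820
```

Reading the output: the Ki67 gate stripped the dark noise floor at log
intensity 2.0 and placed the positivity threshold at 53.8 intensity units;
the 3 mm-deep demo tumor splits into three ~6 mm² bands; in the invasive
band this slide carries ~205 cells/mm², a fifth of them proliferating tumor
cells, with a mean nucleus area near 40 µm². The full cohort driver is one
call — `runPipeline(demoPipelineConfig(seed = 1))` — which simulates 40
patients with a planted severity score coupling invasive-band nucleus size,
thickness and hazard, then runs gating → bands → features → Cox screen →
multivariable models → correlations. A thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

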