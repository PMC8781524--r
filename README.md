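# psoct

Simulation and birefringence analysis of polarization-sensitive optical
coherence tomography (PS-OCT) B-scans of layered, scattering samples —
bladder-wall tissue and the stretched-elastomer phantoms built to mimic it.

## The problem

Weakly birefringent layered tissues such as the bladder wall show a
diagnostic contrast under PS-OCT: the collagen-rich lamina propria (LP) of a
healthy bladder is birefringent (Δn ≈ 1.2 × 10⁻⁴), while carcinoma in situ
collapses the urothelium/LP stratification into a fused, essentially
non-birefringent layer. Realistic test targets for such systems can be made
from PDMS, whose photoelasticity lets a stretched slab reach tissue-level
birefringence (up to 2.1 × 10⁻⁴ at a fivefold stretch of a 20:1 curing-ratio
phantom), while Dragon-Skin-like silicones stay non-birefringent at any
stretch.

`psoct` provides, as one testable pipeline:

* a **forward simulator** of co-registered intensity/retardation B-scans
  from a declarative layered sample model — Beer–Lambert intensity decay
  with per-layer attenuation coefficients, cumulative phase retardation
  δ = 2πΔn·z/λ folded at 90°, multiplicative exponential speckle, additive
  Gaussian phase noise, surface tilt and stretch-induced layer thinning at
  conserved volume;
* the **inverse extraction** used on real images: Otsu-threshold surface
  segmentation, A-scan flattening, lateral averaging (2 mm by default), and
  ordinary least-squares fitting of retardation versus depth, inverted to
  Δn = slope · λ / 360 (slope in degrees per micrometre of physical depth);
* **stretch/stress bookkeeping** (σ = P/A on the relaxed cross-section,
  length-ratio calibration curves with replicate statistics);
* an **end-to-end bladder pipeline** that analyzes normal/diseased samples
  per layer window (urothelium 0–50 µm, LP the next 200 µm), classifies the
  condition from the LP/fused-window Δn, and validates phantom designs
  against thickness/attenuation/birefringence criteria.

Everything downstream of the image is tidy: results are tibbles, fitted
objects have `tidy()`/`glance()` methods, and each result type has an
`autoplot()`.

## Worked example

Simulate the normal bladder phantom at its realized layer birefringence,
analyze it with the standard layer windows, and classify it:

```r
library(psoct)

cfg <- imaging_config(depth_pixels = 640, lateral_pixels = 320)
phantom <- make_bladder_model("normal",
  delta_n = c(urothelium = 3.11e-7, LP = 1.05e-4, MP = 4.50e-5))
pair <- simulate_bscan(phantom, cfg, noise_model(seed = 1))
res <- analyze_sample(pair, bladder_windows("normal"))
res
#> <psoct_analysis> total thickness 1149 um (bottom not visible), noise floor 4.03 deg
#> # A tibble: 3 × 10
#>   layer  delta_n slope_deg_per_um r_squared n_points window_min_um window_max_um
#>   <chr>    <dbl>            <dbl>     <dbl>    <int>         <dbl>         <dbl>
#> 1 urot… -1.87e-6        -0.000519    0.0114       26             0            50
#> 2 LP     1.03e-4         0.0284      0.941        32            50           250
#> 3 MP     4.53e-5         0.0125      0.974       101           450           650
classify_condition(res)
#> [1] "normal"
```

Under speckle and 2° phase noise the LP estimate lands within a few percent
of the configured 1.05 × 10⁻⁴; the thin urothelium fits near zero (slightly
negative fits are reported, not clipped — they are how non-birefringent thin
layers look through this estimator). The MP window sits below the fused/LP
region and is reported as absent when it falls beyond the maximum detection
depth.

A stretch-characterization campaign on a 20:1 PDMS slab (five replicates per
length ratio, noisy imaging) recovers the calibration curve:

```r
slab <- sample_model(list(layer_spec("slab", 1500, 1.5,
  material = material_spec("PDMS", curing_ratio = 20))))
camp <- run_stretch_campaign(slab, ratios = c(1, 2, 3, 5), repeats = 5,
  config = imaging_config(depth_pixels = 900, lateral_pixels = 128),
  noise = noise_model(seed = 2), width_um = 600)
build_characterization_curve(camp)
#>   curing_ratio length_ratio mean_delta_n sd_delta_n n_replicates mean_stress_Pa
#> 1           20            1     7.51e-09   5.34e-08            5          0e+00
#> 2           20            2     4.97e-05   4.95e-07            5          5e+04
#> 3           20            3     9.91e-05   6.29e-07            5          1e+05
#> 4           20            5     2.10e-04   1.75e-06            5          2e+05
```

The measured means track the calibration anchors (5 × 10⁻⁵, 1 × 10⁻⁴,
2.1 × 10⁻⁴) to well under a percent, with replicate scatter from speckle and
phase noise.

## Layout

* `R/` — domain types, simulator, segmentation, fitting, mechanics,
  pipeline, I/O (YAML configs, two-page float-TIFF B-scan stacks), plots.
* `tests/testthat/` — unit, property and end-to-end recovery tests; all
  fixtures are built in code.
* `vignettes/psoct-methods.Rmd` — the model, its assumptions, parameter
  defaults and known limitations.
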