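---
title: "Models and methods behind psoct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind psoct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psoct)
```

`psoct` pairs a forward model of PS-OCT imaging of layered birefringent
samples with the inverse analysis used on real instrument exports. This
vignette is the package's account of both: the physics it assumes, the
defaults it ships, the numerical choices it makes, and what its passing
tests do and do not demonstrate about real data.

## The measurement model

A linearly birefringent medium retards one polarization component relative
to the other. For light that has traveled a one-way physical distance $z$
through material of birefringence $\Delta n$ at centre wavelength
$\lambda$, the cumulative phase retardation is

$$\delta = \frac{2\pi\,\Delta n\, z}{\lambda},$$

which in a stack of layers generalizes to
$\delta(z) = (2\pi/\lambda)\sum_i \Delta n_i\, z_i$ with $z_i$ the path
inside layer $i$. Instruments display $\delta$ in degrees folded into
$[0, 90]$ (a triangle-wave reflection at 0 and 90); the package stores the
retardation channel in exactly that convention and never unwraps. $z$ is
the one-way path: since the same convention is used in the forward
simulation and in the inverse slope conversion, any round-trip factor would
cancel; keeping the stated one-way form makes imported data with the same
convention directly comparable.

Birefringence is recovered by the inverse read of the same relation: an
ordinary least-squares line through mean retardation (degrees) versus
physical depth (µm) has slope $s$, and

$$\Delta n = \frac{s\,\lambda}{360}$$

with $\lambda$ in µm — the degree-valued form of
$\Delta n = s_{\mathrm{rad/m}}\lambda/2\pi$. Unweighted least squares is
used deliberately: the procedure being modeled specifies linear regression
and nothing more, and intensity weighting would couple the retardation
estimate to the speckle realization.

The intensity channel decays as a Beer–Lambert exponential,
$I(z) = I_0 \exp(-\sum_i \mu_i z_i)$, with per-layer attenuation
coefficients $\mu_i$ in mm⁻¹ treated as one-way coefficients on the linear
intensity. No confocal gating or sensitivity roll-off is modeled; the
published per-layer AC values being matched are single scalars, and adding
a roll-off would change what they mean. If the source of an imported AC
table used a round-trip convention, its values should be halved before
simulation — the package documents rather than guesses this.

Axial pixels sample *optical path*: physical depth $z$ inside a medium of
group index $n$ lands at pixel $\mathrm{round}(n z / \Delta_{ax})$. The
inverse conversion (pixels × spacing ÷ $n$, with $n = 1.4$ assumed) is the
standard pixel-to-thickness rule; using the same $n$ in both directions
makes the forward–inverse composition exact up to pixel quantization, which
is why the noise-free recovery tests can demand 0.5 % accuracy.

## The synthetic-data generator

`simulate_bscan()` emulates a 1300-nm PS-OCT system with 5.5 µm axial and
7.8 µm lateral resolution; the default axial pixel spacing is 2.75 µm
(half the axial resolution; Nyquist for the point-spread envelope) and the
default lateral spacing 7.8 µm. Defaults for the bladder models are the
published layer parameters: thicknesses 50 / 400 / 1600 µm and ACs
0.8 / 3.5 / 1.5 mm⁻¹ for urothelium / LP / MP, with tissue-mean
birefringence 0 and 1.18 × 10⁻⁴ for urothelium and LP. The MP of tissue is
too deep to measure, so its default (4.50 × 10⁻⁵) is the value realized in
the corresponding normal phantom — lower than the LP but non-zero, as
smooth muscle should be. The diseased model fuses urothelium and LP into
one 450-µm, near-zero-Δn region with AC graded 2.2 → 1.8 mm⁻¹, represented
as three 150-µm sublayers because the simulator's layers carry scalar ACs.

Noise has two seed-controlled components:

* **Speckle** — unit-mean exponential multiplicative noise on the linear
  intensity, the fully developed speckle limit. Its expectation preserves
  the noise-free profile, which the tests verify over ≥ 100 seeds.
* **Phase noise** — Gaussian noise in degrees added to the *unfolded*
  retardation before folding. The default in noisy studies is 2°.

Neither distribution is asserted by the work being modeled; both are the
standard choices, and both are configuration, not constants.

What the generator does **not** emulate: full Jones/Mueller propagation,
optic-axis contrast, diattenuation, depth-dependent speckle correlation,
confocal/sensitivity roll-off, refraction at tilted interfaces, or motion.
Passing recovery tests therefore show that the *inverse procedure is
consistent with the stated forward physics and robust to its stated noise*,
not that it is robust to every artifact of a physical instrument.

## Surface segmentation choices

`detect_surfaces()` thresholds the **log-compressed** intensity (floored at
10⁻⁶ of the image maximum, a 60 dB display range) rather than the linear
intensity. On linear values, Otsu's criterion places deeply attenuated
tissue in the background class and the analysis depth collapses; on the
display scale, background and tissue form the two classes Otsu assumes.
The procedure being modeled says only "intensity thresholding with Otsu's
method"; thresholding the display-scaled image is the standard reading.

Otsu runs on a 256-bin histogram after linear rescaling to the image range
(bin count configurable). The implementation returns the smallest
co-optimal threshold; the tests pin it to an independent brute-force
maximization of the between-class variance on hundreds of random
histograms. A 3 × 3 median filter precedes thresholding and a run-length
criterion (`min_run = 3` px) rejects isolated speckle hits — neither is
specified by the modeled procedure; both are documented defaults chosen
for speckle robustness before any accuracy measurement, and both are
arguments.

Flattening shifts each column by a whole number of pixels; no subpixel
resampling, because interpolation would alter the retardation values being
averaged. Invalid columns and pixels beyond the maximum detection depth
become `NA` sentinels excluded from every average; flattening retains what
it crops, so `unflatten()` is exactly lossless.

## Fit windows, the fold, and the noise floor

Slab fits default to a window from 10 µm below the surface (skipping
specular surface pixels) to the bottom/maximum detection depth. Tissue
fits use the fixed anatomical windows: urothelium 0–50 µm, LP the next
200 µm, the MP window starting at 450 µm; windows are applied in physical
units, consistent with the $n = 1.4$ thickness convention. A window whose
start lies beyond the deepest averaged point is reported absent rather
than fitted.

Two guards keep the fitted points on the physically linear branch:

* **Fold truncation.** Where the profile's maximum comes within 5° of the
  90° fold, the peak point and everything beyond it are dropped (the peak
  pixel itself may sit just past the crossing, folded back under 90°).
* **Noise-floor exclusion.** Folding at zero biases the mean retardation
  upward wherever the true phase is comparable to the noise: for phase
  noise of sd $\sigma$, the folded mean at zero true phase is
  $\sigma\sqrt{2/\pi}$, decaying as the true phase grows. Fitting through
  that shoulder biases slopes downward. The pipeline estimates $\sigma$
  from above-surface pixels (pure folded noise there, inverting the
  $\sqrt{2/\pi}$ relation) and excludes profile points whose mean lies
  below $2\sigma$. The factor 2 places the cut where the residual fold
  bias is below one percent of the signal. When fewer than three points
  survive — a genuinely non-birefringent window — the guard steps aside
  and the full window is fitted, which is also why near-zero layers can
  report small or negative Δn instead of failing. With noise off the
  estimated floor is 0 and nothing is excluded, so the guards never touch
  the deterministic recovery paths.

Slightly negative estimates are reported unclipped: a thin, non-birefringent
layer legitimately fits a negative slope through noise, and clipping would
bias ensemble means.

## Stretch mechanics and calibration

`apply_stretch()` thins every layer by $1/r$ at length ratio $r$: the
clamps fix the width, so incompressibility puts all thinning into the
thickness (not $1/\sqrt{r}$, which would apply if both transverse
dimensions were free). Stress is $\sigma = P/A$ on the *relaxed*
cross-section $A = L_1 L_{2,0}$. The clamp width $L_1$ is never published
as a number and is therefore a required configuration input (default
10 mm in the shipped models, used only for stress scaling).

Induced birefringence versus stretch is a user-editable anchor table,
interpolated piecewise-linearly and never extrapolated (clamp slipping
bounds the measurable range, differently per curing ratio, and no
functional form — linear or saturating — is established; anchors are left
configurable rather than guessed). Two anchor families are fixed facts:
$(r = 1, \Delta n = 0)$ for every curing ratio, and the 20:1 maximum of
$2.1\times10^{-4}$ at $r = 5$. Every other shipped anchor is marked
`synthetic` in the table's `source` column and should be replaced by
measured values for quantitative use. The scatterer weight fraction is
decoupled from the calibration — scattering is tunable without altering
the photoelastic response — and a non-photoelastic material pins Δn at 0
at any stretch. Campaign force values come from a linear toy
stress–stretch law (default slope 50 kPa per unit strain), synthesized
only so that Δn-versus-stress curves can be assembled; it is not a
constitutive model.

## Classification and validation

The condition call uses only the LP/fused window (the disease being
mimicked is non-muscle-invasive, so the MP carries no contrast). The
default threshold is the geometric mean of the measured normal-LP
(1.18 × 10⁻⁴) and diseased-LP (3.21 × 10⁻⁵) means, ≈ 6.2 × 10⁻⁵ — the
log-scale midpoint, appropriate for a quantity whose biological spread is
multiplicative. Values exactly at the threshold are assigned to
*diseased*: the clinically conservative tie.

Design validation bins Δn into classes `none` / `low` / `moderate` with
boundaries at 1 × 10⁻⁵ and 7 × 10⁻⁵. These boundaries are
artifact-defined conveniences chosen to separate the published tissue and
phantom values; they are not measured quantities. Thickness is compared
within a fractional tolerance (default 20 %) only where the segmentation
can actually measure it — a slab's outer surfaces; internal layer
boundaries are not segmented, so multi-layer thickness verdicts rest on
birefringence class alone. Validation is monotone by construction:
tightening a tolerance can only turn passes into failures.

## Problem sizes and determinism

Simulated studies in the tests and the acceptance script use B-scans of
640 × 320 pixels (≈ 1.26 mm physical depth at $n = 1.4$, 2.5 mm width —
enough to hold the 2-mm lateral averaging region and all tissue fit
windows) and 20-seed ensembles for noisy recovery, sizes at which the
estimator's standard error is a few percent and the full suite runs in
well under a minute. Every stochastic path takes an explicit integer seed,
restores the caller's RNG state, and is bit-reproducible; noise-free
analyses are deterministic outright.

## Known limitations

* Retardation is analyzed only on the pre-fold branch; samples whose
  window of interest lies past the first fold need a shorter window or a
  longer wavelength, as on a real instrument.
* The fused layer's graded AC is a three-step approximation to a
  continuous gradient.
* Surface detection assumes the sample is the brightest connected
  structure; strong specular reflexes above the surface would need masking
  that the package does not implement.
* The calibration's synthetic anchors make stretch campaigns
  *self-consistent* demonstrations, not predictions of any particular
  elastomer batch.
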