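---
title: "Passive arterial mechanics with vasomech: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive arterial mechanics with vasomech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasomech)
```

# Scope

`vasomech` turns raw passive-mechanics recordings and section images of
rodent arteries into the scalar stiffness and remodeling metrics that
group comparisons are run on: wire-myography slopes and Laplace
diameters, pressure-myography stress–strain exponents, MRI lumen-area
kinetics, transit-time pulse wave velocity, elastin rectilinearity, and
stained-section quantities. This vignette explains the underlying
models, the tunable parameters and their defaults, what the synthetic
generators do and do not emulate, and the numerical decisions taken
where the design was genuinely open.

# Wire myography

A ring of artery mounted on two wires is stretched stepwise; at each
step the internal diameter $d$ (µm) and the wall tension $T$ (mN/mm)
are recorded. Force is converted to tension over the two wall strips
that bear the load, $T = F/(2L)$ with $L$ the segment length.

The analysis fits $T = \beta_1 d + \beta_0$ by ordinary least squares.
Three read-outs follow:

* **slope** $\beta_1$ (mN·mm⁻¹·µm⁻¹) — stiffness; steeper means a
  stiffer wall;
* **$Y_0 = -\beta_0/\beta_1$** — extrapolated diameter at zero tension
  (unloaded size, remodeling);
* **$d_{100}$** — the diameter where the fitted line crosses the
  Laplace isobar $T = P\,d/2$ at $P = 100$ mmHg. With $P$ in mmHg
  (133.322 Pa/mmHg) and $d$ in µm the isobar is $T = k\,d$,
  $k = P \cdot 133.322\times10^{-6}/2$ mN·mm⁻¹·µm⁻¹, so
  $d_{100} = -\beta_0/(\beta_1 - k)$.

A recording with non-positive slope is non-physiologic: the fit is
returned with $Y_0$ and $d_{100}$ undefined rather than erroring, so
cohort runs can flag and skip it. `estimateD100()` itself accepts any
finite slope (a flat recording still has a well-defined isobar
crossing); it errors only when the line is parallel to the isobar or
the intersection is non-positive. Channel discalibration QC excludes
recordings whose unit-vs-software force discrepancy exceeds 5 (strict
inequality; the unit is configurable because acquisition software
reports it inconsistently).

Because the true tension–diameter curve of an exponential wall is
convex, a linear fit over the whole 3–120 mmHg-equivalent range
misplaces $d_{100}$ by up to tens of percent. Wire protocols in
practice probe the stretched, quasi-linear regime, so
`tensionPairsFromPressure()` — which converts a pressure series into
wire-style tension pairs — defaults to the 60–120 mmHg window; there
the linear $d_{100}$ tracks the true 100 mmHg equilibrium diameter to
a few tenths of a percent. The window is an explicit argument.

# Pressure myography

Inner and outer diameters $D_i, D_e$ (µm) are measured under passive
(0 Ca²⁺) conditions over a pressure staircase, nominally 3 to
120 mmHg in 20 mmHg steps (the final step, 103→120, is 17 mmHg; the
pressure grid is taken from the data file, not enforced). Derived
per-pressure quantities:

* wall thickness $WT = (D_e - D_i)/2$, wall:lumen $= (D_e-D_i)/(2D_i)$;
* incremental distensibility
  $= 100\,\Delta D_i / (D_i^{\mathrm{ref}}\,\Delta P)$ (%/mmHg). The
  reference is the lower-pressure diameter of each step by default; a
  midpoint reference is available (`reference = "midpoint"`) since the
  convention is not universal;
* circumferential strain $\varepsilon = (D_i - D_{00})/D_{00}$ with
  $D_{00}$ the inner diameter at the lowest (3 mmHg) pressure;
* circumferential stress
  $\sigma = P \cdot 133.4\times10^{3} \cdot D_i/(2\,WT)$ in dyn/cm²
  (diameter units cancel).

Each animal's stress–strain curve is fitted to
$\sigma = \sigma_{orig} e^{\beta\varepsilon}$. The fit is log-linear
(OLS of $\ln\sigma$ on $\varepsilon$): closed-form, variance
stabilizing on multiplicative noise, and identical to nonlinear least
squares on clean data (asserted against `minpack.lm` in the tests).
The incremental elastic modulus is $E_{inc} = \beta\sigma$, strictly
increasing in $\beta$ at fixed stress, so $\beta$ alone orders groups
by stiffness. Fitting is strictly per animal; group comparison then
acts on the per-animal $\beta$ values — no pooled fit, which would
conflate between-animal geometry differences with wall stiffness.

# The synthetic vessel generator

`vesselModel()`/`makePressureSeries()` generate pressure series from an
exponential-wall vessel closed by two assumptions:

* **incompressible wall**: constant wall cross-sectional area `wallCsa`
  across pressures, so $WT(D_i) = (\sqrt{D_i^2 + 4\,\mathrm{CSA}/\pi}
  - D_i)/2$;
* **equilibrium**: at each pressure, $D_i$ solves
  $\sigma_{orig} e^{\beta\varepsilon} = P \cdot 133.4\times10^{3}
  \cdot D_i/(2\,WT(D_i))$ by bracketed root finding on
  $(D_{00}, 10\,D_{00})$ with tolerance $10^{-6}$ µm (a generous
  physiologic range; an unbracketed root aborts with the offending
  parameters).

Because $D_{00}$ is *defined* as the diameter at 3 mmHg, equilibrium
at the reference pressure ties $\sigma_{orig}$ to the geometry:
$\sigma_{orig} = 3 \cdot 133.4\times10^{3} D_{00}/(2\,WT(D_{00}))$.
The constructor therefore derives whichever of `sigmaOrig`/`wallCsa`
is omitted and rejects inconsistent pairs — otherwise the generated
series would have $D_i(3\,\mathrm{mmHg}) \ne D_{00}$ and refitting
would recover $\beta \cdot D_i(3)/D_{00}$ instead of $\beta$, silently
breaking parameter-recovery tests.

Measurement noise is additive Gaussian on both diameters (the
instruments report no error model, so this is the simplest defensible
choice). Default study conditions, chosen once: diameter noise 1 µm,
wire-tension noise 0.05 mN/mm, MRI area noise 0.01 mm² (about 1% of a
mouse aortic lumen), fiber-image SNR 5. All generators take explicit
integer seeds, restore the global RNG state, and are byte-deterministic
given seed and parameters.

What the generators do **not** emulate: pressure-dependent wall CSA
(poro-elastic effects), axial stretch, active tone, spatially
correlated image noise, uneven illumination beyond a smooth background,
out-of-plane fibers, and staining variability across scanners. Passing
recovery tests therefore demonstrates correctness of the computational
chain, not robustness to every artifact of real acquisitions.

# MRI kinetics and PWV

Lumen-area–time curves sampled at heart-rate-dependent intervals are
linearly interpolated onto a uniform 1 ms grid and cut at 150 ms
(beyond that, differing cycle lengths prevent alignment). Missing
samples are substituted from the time-matched lower imaging plane
before interpolation; without a secondary curve, a coverage gap larger
than a quarter heart period is an error. Derived metrics: the initial
ascending slope (OLS of area on time over the first 20 ms, mm²/ms —
an area–time distensibility readout, deliberately *not* pressure
normalized), incremental area $A(t)-A(0)$, radius strain
$(r(t)-r(0))/r(0)$ with $r = \sqrt{A/\pi}$, and total strain as the
trapezoidal integral of the strain curve on the 1 ms grid (units ms).
The trapezoid on a 1 ms grid is stable to well under 0.5% against
4-fold refinement.

PWV is path distance over the transit time between R-to-foot times at
the ascending aorta and femoral artery (mm/ms ≡ m/s). Foot times are
inputs: the feet were placed manually in the workflow this package
models, and the provided intersecting-tangent detector
(`detectFoot()`) is explicitly experimental.

# The elastin rectilinearity toolbox

Elastin lamellae imaged by autofluorescence are reduced to centre-line
branches and scored by
$\mathrm{rectilinearity} = \sum \mathrm{chord} / \sum \mathrm{arc}$
over all branches, in $(0, 1]$: 1 for perfectly straight lamellae,
lower for wavier ones. Pipeline and choices:

1. **Preprocess** — median filter (radius 2 px default) then
   rolling-ball background subtraction, implemented as grayscale
   morphological opening with a disc (radius 25 px default; choose it
   larger than the fiber width and smaller than illumination
   structure). The opening leaves a residual of roughly
   (background slope × radius) under a linear gradient.
2. **Segment** — Otsu by default; Kapur maximum entropy or a fixed
   numeric threshold are available. A fixed value is the reproducible
   stand-in for an interactively chosen cutoff. Coordinates are
   0-based with half-open ROIs.
3. **Skeletonize** — 8-connected components smaller than
   `minComponentPx` (default 64) are removed, then Guo–Hall thinning
   extracts 1-px centre lines. Guo–Hall was chosen over Zhang–Suen
   because the latter leaves redundant staircase pixels that create
   spurious junctions on smooth curves. Component labelling is an
   in-package 8-connected flood fill (4-connected labelling shreds
   diagonal skeleton runs).
4. **Branch decomposition** — the skeleton is cut at junction pixels,
   detected by crossing number (number of 0→1 transitions around the
   8-neighborhood) ≥ 3, which is robust to diagonal adjacency where a
   raw neighbor count misfires. Paths are traced end-to-end from an
   endpoint; neighbor ties break in row-major offset order. Closed
   loops (no endpoints) get the maximum pairwise distance as chord and
   a `cyclic` flag. Fragments shorter than 3 px (junction debris) are
   dropped.
5. **Length measurement** — the geodesic branch length is, by default,
   the length of the polygonal chain through every 4th path pixel
   (endpoints always kept). The classical chain-code sum (1 per
   orthogonal, $\sqrt2$ per diagonal step) is available as
   `lengthMethod = "steps"` but overestimates true curve length by up
   to 8% depending on orientation (about 4% averaged over a
   unit-slope sinusoid), an error larger than the 2% accuracy this
   toolbox targets; the polygonal estimator is exact on straight
   paths, never shorter than the endpoint chord (so the ratio stays in
   $(0,1]$), and keeps digital circles and sinusoids within a fraction
   of a percent. Spacing 4 px balances orientation bias (shrinks with
   spacing) against corner cutting (grows with spacing) at the
   curvature scales of elastin lamellae.

The same resampled-chord estimator measures lumen and outer contours
in `mediaMorphometry()`, keeping a digital circle's perimeter within
1% of $2\pi r$; media thickness is media area divided by the midline
length, approximated as the mean of inner and outer contour lengths —
robust to irregular, non-circular sections.

# Histology, immunofluorescence, SHG

Color classification uses HSV hue bands: red [0°, 30°] ∪ [330°, 360°]
(muscle in trichrome), green [70°, 170°] (collagen in trichrome; thin
bundles under polarized picrosirius), orange-yellow [20°, 60°] (thick
bundles), with saturation and value floors of 0.15 below which a pixel
is unclassified. The bands are arguments, since staining protocols
shift hues.

The Kapur maximum-entropy threshold maximizes the summed Shannon
entropies of the sub- and supra-threshold classes over a 256-bin
histogram spanning the observed intensity range; ties take the first
maximizer; a single-valued histogram is an error. It backs the
integrated-density immunofluorescence mode (background-robust) and is
the default signal cutoff for SHG amount/density, where no threshold
is prescribed by the acquisition. Intensity values are normalized to
the control-group median, which maps the control median to exactly 1.

SHG texture reports Pearson kurtosis $m_4/m_2^2$ (normal = 3, matching
the "more or less peaked than normal" reading) with an `excess` flag,
and skewness $m_3/m_2^{1.5}$. Nuclei are counted by Otsu +
connected components with a minimum-area filter; an optional watershed
on the distance map splits touching nuclei.

# Statistics

Outliers are excluded by the iterative two-sided Grubbs (maximum
normalized residual) test: remove the most extreme point while
$G = \max_i |x_i - \bar x|/s$ exceeds
$G_c = \frac{n-1}{\sqrt n}\sqrt{t^2/(n-2+t^2)}$, $t$ the upper
$\alpha/(2n)$ Student quantile with $n-2$ df, recomputing after each
removal, with at most $\lfloor n/5 \rfloor$ removals — an explicit
safety cap so small cohorts cannot be eroded; each removal is logged
with its $G$. A zero-variance sample warns and excludes nothing. Note
the test's resolving power at $n=5$: a point must lie beyond about
6.5 within-sample SDs to be flagged at $\alpha = 0.05$, since $G$ is
bounded by $(n-1)/\sqrt n \approx 1.79$.

Group comparisons cover pooled-variance and Welch t, Mann–Whitney,
one-way ANOVA with Šidák-adjusted pairwise t comparisons
($p' = 1-(1-p)^k$), and two-way ANOVA for curve data (factors group ×
pressure/time) with Šidák-adjusted per-level contrasts. Slope
comparisons default to the per-animal design (one regression per
vessel, then a two-sample test on slopes), matching per-segment
fitting; pooled ANCOVA (group × diameter interaction) is available but
not the default because it weights animals by their number of points.

# Pipeline

`runPipeline()` reads a YAML config, validates that every referenced
file exists (error names the path), runs each modality, applies
Grubbs exclusion per metric and group, compares groups, and writes
per-modality CSVs, `group_comparisons.csv` and a JSON manifest (seed,
parameters, every exclusion with a reason). Per-animal stages never
see group labels, mirroring blinded analysis. Numeric CSV output is
formatted at 15 significant digits so reruns are byte-identical; the
manifest carries no timestamps for the same reason.

# Problem sizes and determinism

The test-suite and acceptance computations use sizes chosen to make
Monte-Carlo error comfortably smaller than the tolerances they check:
50 replicate seeds for β and ascending-slope recovery, 10 000 null
samples of n = 10 for the Grubbs type-I rate, 100 random histograms
for threshold-oracle agreement, 10⁶ draws for moment calibration, and
~300×110 px images for the geometry oracles (straight line, half
circle, unit-slope sinusoid), which are fully deterministic. All
stochastic steps are seeded; image-geometry results do not depend on
the seed at all.

# Known limitations

* The wall model behind the generator (incompressible, purely
  exponential) is a deliberate idealization; real vessels show
  pressure-dependent CSA changes and viscoelasticity.
* $d_{100}$ from a linear fit is window-dependent on convex data; the
  60–120 mmHg default is a convention, and an exponential refit would
  be the natural extension.
* The rectilinearity score pools all branches; it does not track
  individual lamellae across sections, handle 3D stacks, or separate
  crossing fibers (junction pixels are simply removed).
* Hue-band classification assumes reasonably calibrated color; no
  stain deconvolution or cross-scanner normalization is attempted.
* Media/adventitia/lumen masks are inputs; the package does not
  segment layers.
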