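---
title: "Models and methods behind lspcyto"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lspcyto}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lspcyto)
```

`lspcyto` turns one angular light-scattering profile (LSP) per cell into
four biophysical properties, a cell-type call, and per-sample tumour-cell
counts.  This vignette records the models, the defaults and why they were
chosen, and what the package's synthetic tests do and do not demonstrate
about real measurements.

## 1. Forward model: the coated sphere

A cell is modelled as two concentric homogeneous spheres: a nucleus core
of diameter (N/C)·D and refractive index RI_N inside a cytosol shell of
outer diameter D and index RI_C.  This is the simplest scatterer with an
exact series solution (the Aden–Kerker extension of Mie theory) whose
parameters are exactly the four properties the instrument reports.  The
assumptions it carries:

* sphericity — cells in suspension relax to near-spherical shapes; red
  blood cells do not, and are handled as an *equivalent homogeneous
  sphere* of index 1.40 with N/C fixed at 1 (their true biconcave shape
  is out of scope);
* concentric compartments with sharp interfaces and uniform indices;
* real refractive indices (no absorption) — adequate at 632.8 nm for
  unstained cells;
* single scattering in the far field.

The N/C ratio is a *diameter* ratio (core diameter = N/C × D).  The
reference values of the built-in classes, 0.78–1.00, are consistent with
this reading; a volume-ratio reading would map them to implausibly large
cores.

The series is truncated at `n_max = x + 4.05 x^{1/3} + 2` (the standard
Wiscombe criterion) with size parameter x = πD·n_med/λ; inputs with
x > 300 are refused rather than extrapolated.  Riccati–Bessel functions
are generated by downward (Miller) recurrence for ψ and upward recurrence
for χ, and the core only enters the coefficients through the logarithmic
derivative ψ′/ψ, which keeps the series stable across the whole supported
domain.  The compiled implementation agrees with an independent reference
implementation (SciPy spherical Bessel functions, frozen values shipped
with the tests) to better than 10⁻⁶ relative over x ∈ [0.5, 150], reduces
exactly to the homogeneous Mie series when the two indices coincide, and
matches the closed-form Rayleigh dipole shape within 1 % for x ≤ 0.1.

The recorded intensity is the unpolarized Mueller element
S11 = (|S1|² + |S2|²)/2.  The acquisition geometry is fixed at 2°–30° in
0.1° steps (281 points); the laser wavelength (632.8 nm) and medium index
(1.334, phosphate-buffered saline with 0.4 wt% polyethylene oxide,
optically water-like) are configurable in `optical_setup()`.

## 2. Inversion: look-up table plus bounded refinement

Absolute scattered intensity depends on laser power, exposure and
collection efficiency, none of which the profile model captures, so
profiles are compared by a *scale-invariant* distance: the cosine distance
between log10 intensities after unit-maximum normalization.  The log
compresses the four-decade dynamic range of forward scattering so that
the deep interference minima — the most parameter-sensitive features —
contribute to the match.  Intensities are floored at 10⁻¹² of the maximum
before taking logs.

Stage one matches the measured profile exhaustively against a precomputed
table.  The production grid (`default_grid()`) spans D 4.00–25.00 µm
(step 0.25), N/C 0.60–1.00 (step 0.005), RI_C 1.34–1.41 and RI_N
1.36–1.45 (step 0.01): 550,800 entries, covering every built-in class
with margin.  Distance ties — which arise systematically from the
degeneracies below — are broken deterministically: smallest D, then
smallest N/C, then smallest indices.  Ties are detected at 10⁻⁹, far
below any physically meaningful profile difference but above the
last-bit noise of vectorized summation.

Stage two minimizes the same distance continuously inside a box of ±1
grid step per axis around the coarse match (box-constrained quasi-Newton
iterations; a monotone compass search is the fallback), and reports the
result at the instrument resolutions: 0.01 µm for D, 0.01 for both
indices, 0.005 for N/C.  Two pragmatic safeguards matter in practice:

* *multi-start*: the profile distance is oscillatory in D, and the best
  grid entry occasionally sits in a neighbouring local basin.  The top
  `top_k = 10` coarse candidates are refined independently and the best
  final residual wins.  If the winning residual still exceeds 10⁻⁹ —
  implausible for a profile the forward model can represent — the
  inversion retries once with 25 candidates.
* *re-centring*: when a refinement converges onto its box boundary with a
  clearly non-zero residual, the box is re-centred on the current best
  fit and refinement repeats (at most 8 hops), letting the fit walk a few
  grid steps along the valley.

Two exact degeneracies shape the design.  When RI_N = RI_C the core/shell
interface vanishes and N/C has *no* effect on the profile; when N/C = 1
the core fills the sphere and RI_C has none.  Both families collapse to a
homogeneous sphere.  `invert_lsp()` therefore always refines a
homogeneous (two-parameter) reading of each candidate alongside the full
four-parameter one and, on a numerical near-tie, prefers the simpler
homogeneous model, reported as N/C = 1 with a single index.  Without this
rule an anucleate cell would be assigned an arbitrary N/C and shell index
from whatever tied table entry happened to be scanned first.

### What precision the inversion achieves

`inversion_benchmark()` draws cells uniformly over the nucleated-class
ranges (D 6.6–21.9 µm, N/C 0.784–0.975, RI_C 1.355–1.365, RI_N
1.375–1.425), synthesizes noiseless profiles and inverts them.  The RI_C
band is the narrow range shared by all nucleated reference classes, which
keeps the core/shell contrast at or above 0.01: as the contrast
approaches zero the profile approaches the homogeneous limit and *no*
method can recover N/C — such draws would measure the degeneracy, not the
algorithm, and the pipeline reports them as homogeneous instead.  Across
seeds, the maximum absolute recovery errors are ≈ 0.005 µm for D and
≈ 0.0025 for N/C — at the reporting resolutions, i.e. dominated by the
final rounding, within the stated 0.01 µm and 0.005 precisions.  The
benchmark's matching table (`benchmark_grid()`, 158,355 entries) restricts
the production grid to the benchmarked ranges at a 0.01 N/C pitch so that
one benchmark run stays at an interactive scale (a few minutes on one
core); the refinement stage is unaffected by this restriction.

## 3. Microfluidic alignment criterion

Viscoelastic focusing in the round feed channel (radius R = 25 µm, length
L = 0.35 m) is summarized by the dimensionless alignment parameter
θ = 3·Wi·β²·L/(2R), with Weissenberg number Wi = 2λ_f·Ū/(2R) (fluid
relaxation time λ_f = 0.197 ms, mean velocity Ū = 1496 µm/s) and
β = r₁/R the cell-to-channel radius ratio; centreline focusing is
predicted when θ > −ln(3.5β).  The package evaluates the criterion and
returns every intermediate quantity for audit.  With the default
constants Wi = 0.0118 and every cell radius from 2 to 12 µm aligns, so
the criterion acts as a design check rather than a per-cell filter.  Unit
handling is internal (ms → s, m → µm); only the criterion is implemented,
not the underlying viscoelastic flow field.

## 4. Classification and enumeration

Cell types are assigned by a support-vector machine with a quadratic
polynomial kernel, box constraint 1, and one-vs-one multiclass voting, on
z-score-standardized features (statistics from the training split only).
RBC records carry no nucleus index; for classification RI_N is imputed as
RI_C and N/C is 1, consistent with their homogeneous model.  The
comparison set mirrors the classifiers evaluated in the original study:
linear SVM, fine-Gaussian SVM (kernel scale √P/4), medium KNN (k = 10)
and kernel naive Bayes.  No installed R package provides a KDE-based
naive Bayes, so a small one (per-class, per-feature Gaussian-kernel
densities with normal-reference bandwidths) is implemented in-package.
Cross-validation is stratified 5-fold with identical fold assignment
across algorithms — the original study does not state its validation
protocol, so this standard choice is ours.

On synthetic populations of the five reference classes (200 cells/class)
the quadratic SVM reaches ≥ 99 % cross-validated accuracy and is never
outscored by kernel naive Bayes.  Two caveats: the published accuracies
(99.8 %, 97.3 %, 99.5 %, 99.2 %, 92.2 %) were measured on ~705 real
cells that are not published, so they cannot be reproduced, only
echoed qualitatively; and because the synthetic generator draws features
independently within each class, naive Bayes is nearly optimal on
synthetic data and can saturate at 100 % alongside the SVMs — the real
ranking among near-perfect classifiers is not resolvable at this scale.

Per-sample reports count the six classes and convert to percentages of
the sample total.  Multi-sample aggregates are the *unweighted mean of
per-sample percentages*, not the pooled-count ratio: the two statistics
differ (samples differ greatly in size), and only the former reproduces
the published per-class aggregates of the nine-sample count table shipped
with the package.

## 5. Synthetic data generator

`sample_population()` draws class-conditional features: D ~ Normal(mean,
SD) truncated positive, using the published per-class mean ± SD (the
uncertainty is treated as a population SD, not a standard error); RI_C
and RI_N ~ Normal(point, 0.005); N/C ~ Normal(point, 0.0025) truncated to
(0, 1].  Only the diameter has a published spread, so the RI and N/C
jitters default to *half the instrument reporting precision* — small,
explicit and overridable via `class_parameters()`.  Granulocytes have no
published parameter row and therefore no built-in defaults; scenarios
that need them must supply parameters explicitly (`class_parameters(extra
= ...)`), and the generator fails loudly otherwise.  Scenario mixtures
("adenocarcinoma-like", the culture time-course steps) reproduce published
composition percentages as multinomial mixture fractions only — the
culture-time *dynamics* are not modelled.

What passing synthetic tests show: that the forward model, inversion,
classifier and reporting compose correctly, recover known inputs at the
stated precisions, and are deterministic under seeding.  What they cannot
show: robustness to the ways real profiles deviate from the coated-sphere
ideal — aspherical and granular cells, camera noise and saturation, beam
misalignment, coincident cells — nor the true inter-cell correlation
structure of biophysical features, which the independent-Gaussian
generator does not attempt to capture.

## 6. Numerical choices and edge cases

* Profile intensities are floored at 10⁻¹² of maximum before logs.
* Grid axes are generated from (min, step, count) arithmetic to avoid
  floating-point `seq` pitfalls; axis cardinalities are exact integers.
* Refinement never returns a worse distance than its seed (monotone by
  construction) and clips iterates to physical validity
  (RI ∈ [1.30, 1.60], N/C ∈ (0, 1], D > 0).
* The rendering/averaging pair for 2D diffraction patterns uses a
  piecewise-constant (nearest grid angle) radial mapping, so a noiseless
  render followed by azimuthal averaging reproduces the profile exactly;
  more than 10 % empty angular bins is an error, isolated empty bins are
  interpolated.
* All randomness flows from explicit integer seeds; identical seeds give
  bit-identical populations, noise draws and reports.
* The look-up table persists through R native serialization
  (`write_lut()`/`read_lut()`, bit-identical round trip).

## 7. Known limitations

* The coated-sphere model cannot represent aspherical, multi-nucleated or
  strongly granular cells; for red blood cells the homogeneous-equivalent
  treatment reproduces plausible profiles but not their orientation
  dependence.
* Inversion precision claims hold for noiseless, model-representable
  profiles.  Under measurement noise the residual is no longer a
  reliable degeneracy detector, and near-homogeneous cells (N/C → 1 or
  RI_N → RI_C) remain fundamentally ambiguous.
* The classifier is only as good as its training distribution; the
  built-in synthetic trainer assumes the published class parameters
  transfer to the sample at hand.
* Throughput, camera control and real-time operation are out of scope;
  the package processes recorded profiles and images only.
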