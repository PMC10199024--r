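---
title: "Quantitative flux imaging with SISA: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative flux imaging with SISA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sisaflux)
```

## The problem

Mass spectrometry imaging (MSI) of tissue from animals fed a stable-isotope
tracer (U-¹³C glucose) records, at every pixel, the intensities of each
isotopologue M0..Mn of a target metabolite. Unlike pool-size images, which
are confounded by pixel-specific matrix effects (co-ionizing molecules alter
ionization efficiency differently in tumor and healthy tissue), isotopologue
*ratios* are robust: all isotopologues of one metabolite share an ionization
efficiency, so any multiplicative per-pixel factor cancels. `sisaflux` turns
those ratios into per-pixel maps of fractional biosynthetic flux.

The pipeline is: read imzML → (optional per-pixel mass recalibration) →
extract isotopologue ion images for a target list → segment tissue from
background → (optional blur / normalization) → screen isotopologues for
background interferences using unlabeled control tissue → natural-abundance
correction → fractional labeling → per-pixel model fitting.

## Labeling descriptors

With isotopologue abundances $a_0 \dots a_n$ for a metabolite with $n$
carbons, the fractional labeling of isotopologue $x$ is

$$f_x = \frac{a_x}{\sum_{j=0}^n a_j},$$

and the fractional carbon-atom labeling — the fraction of the metabolite's
carbon that is ¹³C — is

$$L = \frac{\sum_{j=0}^n j\, a_j}{\, n \sum_{j=0}^n a_j}.$$

Isotopologues flagged as interfered are excluded from both sums and the
remainder renormalized (`labeling_distribution()` masks). We renormalize
rather than impute because imputing from the very model being fitted would
bias the fit toward itself.

## The ISA family of models

A fatty acid is a polymer of 2-carbon acetyl units: palmitate is built from
8, stearate from 9. If each unit is drawn independently from a monomer mass
distribution $(m_0, m_1, m_2)$ (0, 1 or 2 heavy carbons), the product's
isotopologue distribution is the $k$-fold self-convolution
`monomer_power(m, k)` — a polynomial in the monomer labeling.

**Classical ISA** assumes the tracer-derived monomer labeling $T$ is known
and infers the tracer contribution $D$ and the fractional turnover $g(t)$:

$$P = g(t)\, \mathrm{conv}^n\!\big((1-D)N + D\,T\big) + (1-g(t))\, \mathrm{conv}^n(N),$$

where $N$ is the pre-existing (unlabeled) monomer pool.

**SISA** replaces $(D, T)$ with a single inferred monomer distribution $X$:

$$P = g(t)\, \mathrm{conv}^n(X) + (1-g(t))\, \mathrm{conv}^n(N).$$

This matters in vivo: acetyl-CoA labeling cannot be measured by MSI, varies
between anatomical regions, and in brain contains substantial M1 (CO₂
recycling, malic enzyme), so no single $T$ can be assumed. For palmitate,
17 isotopologue fractions constrain 4 free parameters ($X$ on a 2-simplex
plus $g$), so the system remains overdetermined; setting
$X = (1-D)N + DT$ recovers classical ISA exactly (an algebraic identity the
test suite asserts to machine precision).

**Elongation** (stearate) splits synthesis into full de novo synthesis and
single-unit elongation of pre-existing palmitate:

$$P = g\, \mathrm{conv}^9(X) + e\, X * \mathrm{conv}^8(N) + (1-g-e)\, \mathrm{conv}^9(N),$$

with $g, e \ge 0$, $g + e \le 1$. With unlabeled pre-existing pools,
elongation alone produces M2 stearate.

Note on index conventions: the monomer components are written $X_0, X_1,
X_2$ (number of heavy carbons); 1-based labels $X_1, X_2, X_3$ occasionally
appear in the literature for the same three components. `sisaflux` uses the
0-based convention throughout.

## Fitting

Parameters are estimated per pixel by minimizing the sum of squared
differences between observed and predicted fractions over the *unmasked*
isotopologues; both observation and prediction are renormalized over the
unmasked set so exclusions do not bias the fit. Two implementation choices
matter:

* **Profiled flux fractions.** Every model above is linear in $g$ (and
  $e$), so for fixed $X$ the optimal flux fractions are a closed-form
  least-squares solution constrained to the unit interval (SISA) or to the
  triangle $g,e \ge 0,\ g+e \le 1$ (elongation; solved exactly by checking
  the unconstrained optimum and the triangle edges). Renormalization over a
  masked subset makes the prediction a ratio in $g$; substituting
  $\gamma = g\,s_A / (g\,s_A + (1-g)\,s_C)$ (with $s_A, s_C$ the unmasked
  mass of the two mixture components) restores exact linearity, and $\gamma$
  maps bijectively back to $g$. Numerical optimization therefore runs only
  over $X$, parameterized as squared-then-normalized coordinates so any
  unconstrained point is a valid simplex point.
* **Multi-start.** The polynomial objective can be multimodal in $X$.
  Fits start from a point near $N$, the uniform distribution, two skewed
  simplex points, and seeded random draws (`fit_sisa()` default); per-pixel
  maps use three starts as a cost/robustness balance. Convergence uses a
  relative objective tolerance of 1e-12 (1e-9 for maps, which is far below
  the noise floor of real images). Noiseless recovery of random parameter
  sets to |ĝ − g| < 1e-3 is asserted in the tests.

The pre-existing pool defaults to $N = (1,0,0)$ because fitting follows
natural-abundance correction; `natural_monomer(p13)` supports fitting
uncorrected fractions instead. Pixels below a configurable minimum summed
intensity are skipped rather than fitted to noise, and `t` (the labeling
duration, 48 h in the motivating experiments) is metadata only — $g(t)$ is a
fractional turnover over that period, not a rate constant.

## Natural-abundance correction

Column $j$ of `na_correction_matrix(n, p13)` is the binomial pattern with
which a molecule carrying $j$ tracer labels is observed when each of its
remaining $n-j$ carbons picks up a ¹³C with probability `p13` (default
0.0107, terrestrial abundance). Correction solves $Mx = a$ by non-negative
least squares rather than direct inversion, because inversion produces
negative isotopologues at low signal. Totals are conserved, so pool-size
images are unchanged by correction. Only carbon is corrected — the tracer
is U-¹³C glucose and H/N/O isotope contributions are neglected, a documented
approximation; resolved isotope fine structure is likewise out of scope.

When an isotopologue is interference-flagged, its row is excluded from the
least-squares residual so a contaminant cannot leak into neighboring
isotopologues; the then-underdetermined system is stabilized with a tiny
Tikhonov term (1e-6 of the mean channel intensity), which perturbs the
solution far below every tolerance used here.

## Interference screening

In unlabeled control tissue, nothing above M0 should survive correction.
`screen_interferences()` flags any isotopologue whose tissue-mean corrected
fractional abundance exceeds a threshold (default 0.02 — the rule is
standard, the numeric cutoff is this package's choice and is configurable).
M0 is never flagged, and the absence of a control yields an explicit
"unscreened" status, never a silent pass. The flagged pattern (e.g.
palmitate M1/M4/M5 under DESI, or NAA M1) propagates as a mask into
correction, labeling and fitting. With DESI, slide-background palmitate adds
an unlabeled dilution to every pixel, so fitted $g$ underestimates absolute
turnover uniformly; regional *comparisons* are unaffected and no background
correction is attempted.

## Preprocessing choices

* Segmentation: PCA on per-pixel channel vectors (default 5 components, or
  all channels if fewer) followed by 2-means clustering; the cluster with
  the higher mean total ion current is tissue. The component count, the
  k-means seed and the tissue rule are this package's choices — the
  upstream method statement specifies only "PCA + k-means (k = 2)".
* De-noising: 3×3 Gaussian blur, σ = 1 pixel (σ unspecified upstream),
  reflection at edges, kernel normalized to sum 1; applied to raw intensity
  images before ratio formation (a config switch allows blurring fractional
  images instead). Blur is off by default in the flux examples here because
  it mixes intensities across the tumor boundary.
* Normalization: optional TIC scaling (per-pixel channel vector divided by
  its total, rescaled by the grid-median TIC). Fractional labeling is
  provably invariant to it; it exists for comparing raw-intensity images.
* Recalibration: per-pixel linear fit of ppm shift vs m/z over matched
  reference annotations, falling back to a constant offset with fewer than
  3 matches and to the grid-median model with fewer than 2. The upstream
  "adaptive pixel" method is cited without formulas, so this simple robust
  variant is the package's own and is validated on synthetic shift fields
  (residual < 1 ppm for pixel-dependent linear shifts).
* Extraction: ±10 ppm windows by default, motivated by ~43,000 FWHM
  resolving power; overlapping windows across targets are logged, not
  merged — exclusion is the screen's job.

## The phantom generator

`generate_phantom()` emulates a coronal brain section with a unilateral
tumor: an elliptical tissue region (~60% of a 60×40 grid) containing a
tumor ellipse (~16% of tissue area). Defaults are the package's study
conditions: palmitate $g$ = 0.55 (tumor) / 0.20 (healthy) — a ~2.75-fold
lipogenesis elevation — and stearate $g + e$ = 0.40 / 0.05 (~8-fold);
monomer labeling $X$ = (0.35, 0.25, 0.40) in tumor and (0.55, 0.25, 0.20)
elsewhere, reflecting in vivo acetyl-CoA with appreciable M1; 2× pool-size
scaling in tumor to emulate matrix effects; natural-abundance convolution at
p13 = 0.0107.

The noise model is per-channel multiplicative log-normal with relative SD
1% (`noise_rel = 0.01`) plus an optional additive floor — proportional
noise, as appropriate for detector counts, which cannot push near-zero
isotopologues negative. Additive Gaussian noise *on fractions* (clipped at
zero, renormalized) is a separate switch (`noise_frac`) used to build
calibration phantoms for the error-propagation analysis, because that is the
noise model that analysis injects. The distinction matters: additive
fractional noise with clipping inflates the apparent labeling tail and
biases ĝ upward by ~0.02 at σ = 0.01 (healthy-tissue parameters) — a bias
the error-propagation analysis is designed to quantify, not one the phantom
should silently embed in every test.

What the phantom does *not* emulate: thousands of background peaks, peak
shape/centroiding artifacts, spatially correlated noise, ion-mobility
separation, or partial-volume mixtures at region boundaries. Passing tests
therefore demonstrate correctness of the computational pipeline under
realistic signal structure, not robustness to every artifact of real
acquisitions.

## Error propagation

`measure_labeling_error()` scores measurement error as the mean absolute
deviation between uncorrected unlabeled-tissue fractions and the theoretical
natural-abundance pattern. `noise_gradient_simulation()` draws random
feasible parameters (uniform $D$ and flux fractions, random simplex $T$ —
the sampling ranges are this package's choice), generates forward labeling,
adds Gaussian noise on fractions over a gradient of σ (default 8 log-spaced
levels in [0.001, 0.05], 200 reps each), refits, and regresses mean |ĝ − g|
on σ; `project_error()` evaluates that regression at the measured error.
For palmitate the simulation also fits classical ISA at the true $T$, and
the SISA and classical error curves are statistically indistinguishable on
classical-ISA-generated data — inferring the extra unknown costs no
accuracy.

## Problem sizes and numerical tolerances

Default problem sizes (60×40 phantom ≈ 1,430 tissue pixels; 100-draw
identifiability checks; 200×5 noise-gradient draws) were chosen so a full
desk run — simulate, extract, screen, correct, fit both targets, error
propagation — completes in a few minutes on one core. Forward models
conserve total fraction to 1e-12; NA correction inverts its forward
convolution to 1e-8; noiseless fits recover parameters to 1e-3; phantom
region means are recovered within ±0.02 at 1% noise (±0.01 with the
interference-masked fit). Degenerate inputs (all-zero pixels, all-masked
ladders, empty ROIs, missing controls) raise explicit errors or flagged
statuses rather than propagating NaNs.

## Known limitations

* Fractional turnover, not absolute flux: converting $g(t)$ to moles per
  time needs pool sizes, which MSI cannot quantify reliably.
* Single-timepoint: no isotopically nonstationary modeling across labeling
  durations.
* Acetyl-CoA compartmentation (separate cytosolic/mitochondrial pools) is
  folded into the single inferred $X$.
* Carbon-only NA correction; tracer isotopic impurity is not corrected.
* DESI background dilution biases absolute $g$ downward (regional contrasts
  preserved).
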