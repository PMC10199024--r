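# sisaflux

Per-pixel biosynthetic flux imaging from stable-isotope-labeled mass
spectrometry imaging (MSI) data.

When an animal is fed a ¹³C tracer (U-¹³C glucose), every pixel of an MSI
dataset carries an isotopologue distribution for each metabolite. Pool-size
images are distorted by pixel-specific matrix effects, but isotopologue
*ratios* are not — all isotopologues of a metabolite ionize with the same
efficiency. `sisaflux` exploits this to produce quantitative maps of
fractional biosynthesis from imzML data: it reads and writes imzML, extracts
isotopologue ion images for a target list, recalibrates masses per pixel,
segments tissue, screens isotopologues for background interferences against
unlabeled control tissue, corrects natural ¹³C abundance, and fits, at every
pixel, **Spatial Isotopologue Spectral Analysis (SISA)**.

## The model

A fatty acid with `n` acetyl-CoA subunits (palmitate: 8; stearate: 9) built
from monomers with mass distribution `X = (X0, X1, X2)` has isotopologue
fractions given by the n-fold convolution `conv^n(X)`. SISA models the
observed fractions as a mixture of newly synthesized and pre-existing
polymer and infers the monomer labeling jointly with the fractional
turnover `g(t)`:

    P = g(t) * conv^n(X) + (1 - g(t)) * conv^n(N)

For palmitate this leaves 17 isotopologue equations for 4 unknowns — still
overdetermined, and unlike classical ISA it needs no assumed acetyl-CoA
(precursor) labeling, which cannot be measured by MSI and varies across
tissue regions. Setting `X = (1-D)N + D*T` recovers classical ISA exactly.
A stearate extension adds an elongation term `e(t)` for single-unit
elongation of pre-existing palmitate:

    P = g*conv^9(X) + e*(X * conv^8(N)) + (1-g-e)*conv^9(N)

An error-propagation module measures noise from unlabeled tissue and
projects it into expected flux-parameter error via a simulated noise
gradient, and a phantom generator emulates a two-region (tumor/healthy)
labeled brain image so the entire pipeline is testable without instrument
data.

## Worked example

```r
library(sisaflux)

# synthetic two-region brain: palmitate g = 0.55 (tumor) / 0.20 (healthy),
# 1% intensity noise, with an unlabeled twin
ph   <- generate_phantom(phantom_spec())
mask <- segment_tissue(ph$labeled, seed = 1)

screen_interferences(ph$unlabeled, ph$unlabeled$targets, tissue_mask = mask)
#> Interference report (screened, threshold 0.02):
#>   no isotopologues flagged

corr <- na_correct_stack(ph$labeled, tissue_mask = mask)
fx   <- flux_image(corr, "palmitate", tissue_mask = mask, t_hours = 48)
fx
#> Flux image: palmitate (sisa model), t = 48 h
#>   1428 pixels fitted (0 skipped, 0 failed); g: median 0.201 [0.190, 0.557]

region_summary(fx, ph$truth$tumor, ph$truth$healthy)
#> Region comparison (g, 1 replicate):
#>   ROI A: 0.5500 +/- 0.0029 (n = 232)
#>   ROI B: 0.1999 +/- 0.0030 (n = 1196)
#>   ratio A/B = 2.751; t = 1701.741, p = 0
```

The median g of 0.201 reflects the dominant healthy region; the tumor ROI
mean of 0.550 against 0.200 elsewhere recovers the simulated 2.75-fold
elevation of de novo lipogenesis. A single fit is an ordinary model object:

```r
fit <- fit_sisa(sisa_forward(c(0.4, 0.2, 0.4), c(1, 0, 0), 0.5, 8),
                N = c(1, 0, 0), n_subunits = 8)
fit
#> SISA fit (sisa, 8 subunits)
#>   g = 0.5000
#>   X = (0.4000, 0.2000, 0.4000)
#>   sse = 2.65e-17 over 17 isotopologues
```

with `coef()`, `predict()`, `residuals()`, `summary()`, `simulate()` and
(for flux images) `plot()` methods.

Real data enter through `read_imzml()` plus a target list
(`inst/extdata/targets_brain_dnl.tsv` shows the format); the same pipeline
is scriptable from a shell via `inst/cli/sisaflux.R` with subcommands
`simulate`, `extract`, `screen`, `flux` and `errorprop` driven by a YAML
config (`inst/extdata/example_config.yaml`).

See `vignettes/sisa-flux-imaging.Rmd` for the models, assumptions, numeric
choices and limitations.

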