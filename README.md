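# epoRtraffic

Single-cell ensemble modelling of erythropoietin receptor (EpoR)
trafficking.

Cytokine receptors such as EpoR are rare at the cell surface and turn over
rapidly; how much signalling-competent receptor a cell presents is set by
the balance of synthesis, degradation, transport to and from the plasma
membrane, ligand-induced internalization, recycling and lysosomal
degradation. Live-cell imaging gives per-cell fluorescence time courses of
these pools, but the rates themselves are latent: they must be estimated by
fitting trafficking ODE models, and because every cell is different, by
fitting one model per cell *jointly* across an ensemble of cells.

This package is for quantitative cell biologists and systems biologists who
want to run that analysis end to end:

* a family of linear trafficking models — a basic
  synthesis/degradation/transport/binding/endocytosis core extended by four
  optional routes for the internalized ligand-receptor complex (A: direct
  recycling to the membrane; B: recycling to the intracellular pool with
  retention of the consumed ligand; C: degradation with ligand export; D:
  degradation with ligand retention), giving 16 variants with 6 ODEs and
  7–11 kinetic parameters each, plus reduced 3-ODE models for
  photobleaching (5 parameters) and cycloheximide (3 parameters)
  experiments;
* cell-ensemble fitting: global Epo binding constants, per-cell kinetic
  rates and initial concentrations, shared fluorophore scaling factors, and
  quadratic distribution constraints that tie the log-parameter means and
  variances of the experimental groups together;
* model discrimination by the corrected Akaike criterion
  (AICc = chi^2 + 2k + 2k(k+1)/(n-k-1)) with nesting-consistent
  continuation fits, and a greedy parameter-fixing ladder;
* profile-likelihood confidence intervals (pointwise delta-chi^2 = 1) with
  open-end flags for non-identifiable directions;
* post-fit biology: reaction fluxes, concentration control coefficients
  r = (k/X) dX/dk, cell-to-cell CVs, log-scale parameter correlations with
  t-test p-values, and the covariance-removal experiment that quantifies
  how correlated kinetics of opposing transport processes buffer
  variability;
* a synthetic single-cell data generator reproducing the imaging study's
  layout (16 Epo + 10 bleach + 7 CHX cells, 5-/10-min sampling grid,
  multiplicative noise, correlated multivariate log-normal cell
  parameters), so the entire pipeline is testable without microscopy data.

## Worked example

```r
library(epoRtraffic)

# synthetic study: 6 Epo, 4 bleach, 3 CHX cells, true variant ACD
cfg <- generator_config(n_epo_cells = 6, n_bleach_cells = 4, n_chx_cells = 3,
                        seed = 101)
ds  <- generate_dataset(cfg)

fit <- epor_fit(ds, variant = "ACD", n_starts = 25, seed = 1)
fit
#> Cell-ensemble trafficking model fit (variant ACD)
#>   conditions: epo + bleach + chx | cells: 13 | data points: 1496
#>   objective 712.1 (data chi2 710.6 + penalty 1.529), 108 parameters, AICc 945.1
#>   multi-start: best of 25 starts, seed 1
```

The objective is the weighted residual sum of squares over all 1496 data
points plus the distribution-constraint penalty; with a relative error of
10% a value of the order of half the number of points indicates a fit
within the noise. `summary(fit)` lists the per-cell rate estimates and
their cell-to-cell CVs, `coef(fit, "cells")` returns the cells x parameters
matrix, and

```r
profile(fit, which = "epo_01.k_EpoR_deg")
#> Profile-likelihood 1-sigma confidence intervals (1 parameters, threshold 1)
#>           parameter    best ci_lower ci_upper includes_zero infinite_upper relative_ci
#> 1 epo_01.k_EpoR_deg 0.01575 0.008215  0.02441         FALSE          FALSE       1.028
```

profiles one degradation rate: the cell's value 0.016/min is identified,
with a 1-sigma interval spanning roughly a factor of three (per-cell
degradation rates are among the broader intervals, as in the study's
identifiability analysis). Model discrimination and the
variability analyses follow the same pattern:

```r
sel <- select_variant(ds, n_starts = 25, seed = 1)   # all 16 variants
head(sel$table, 3)

st  <- parameter_stats(coef(fit, "cells")[1:6, kinetic_param_names("ACD")[-(1:2)]])
cx  <- covariance_experiment(generator_stats(cfg), n_samples = 1000, seed = 1)
cx
#> Covariance-retaining sampling experiment (1000 virtual cells)
#>   CV [EpoR*_m](5h)  = 0.426 (MC SE 0.017)
#>   CV [EpoR*_RE](5h) = 0.448 (MC SE 0.015)
```

Sampling the same distribution with all covariances of the four EpoR*
transport parameters removed (`reduced = TRUE`) raises the CV of the
membrane complex to ~0.60: the correlated kinetics of opposing transport
processes buffer cell-to-cell variability.

See the vignette (`vignettes/epor-cell-ensemble.Rmd`) for the model
definitions, the fitting strategy, and the calibration of the generator
defaults.

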