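# auxselect

Information criteria for auxiliary-variable selection in incomplete data
analysis.

## The problem

Suppose the variables of scientific interest — the *primary variables*
`X = (Y, Z)` — are only partially observed: `Y` is recorded in every
dataset, while the label `Z` is latent (never observed).  Alongside `Y`, the
training data contain *auxiliary variables* `A` that will not be available
(or will not be used) at prediction time.  Modeling `B = (Y, A)` jointly can
sharpen the estimate of the predictive distribution of `X` when `A` is
related to the latent structure — and can badly damage it when `A` is
unrelated noise, because the joint model adds parameters and is easily
misspecified.

`auxselect` turns the decision "use `A` or not" into model selection under a
Kullback–Leibler risk for the *complete* primary data.  With
`θ̂_b` the MLE of the primary parameters from the joint `(Y, A)` model and
`θ̂_y` the MLE from the `Y`-only model, the package computes a family of
generalized Akaike-type criteria, all on the familiar `-2n·loglik + penalty`
scale:

    risk̂_x;b = -2n ℓ_y(θ̂_b) + 2 tr(Î_b⁻¹ K̂_b,y) + tr(Î_z|y Î_b⁻¹ Ĵ_b Î_b⁻¹)
    AIC_x;b  = -2n ℓ_y(θ̂_b) + tr(Î_x Î_b⁻¹) + tr(Î_y Î_b⁻¹)
    AIC_x;y  = -2n ℓ_y(θ̂_y) + tr(Î_x Î_y⁻¹) + d
    AIC_y;b  = -2n ℓ_y(θ̂_b) + 2 tr(Î_y Î_b⁻¹)
    AIC_y;y  = -2n ℓ_y(θ̂_y) + 2d                      (classical AIC)
    TIC      = -2n ℓ_y(θ̂_y) + 2 tr(Î_y⁻¹ Ĵ_y)        (classical TIC)

where `Î_b, Ĵ_b` are the empirical sandwich (information) matrices of the
observable-data log-likelihood, `Î_x, Î_y` the complete-data and
observed-data information, `Î_z|y = Î_x − Î_y` the information of the latent
part given the observed part, and `K̂_b,y` the cross-product of the
observable and marginal scores.  The auxiliary variable is declared useful
for predicting `X` exactly when `AIC_x;b < AIC_x;y`.  A latent-variable
leave-one-out cross-validation estimator, asymptotically equivalent to
`risk̂_x;b` up to a model-independent shift, is also provided.

The candidate model throughout is a two-component Gaussian mixture: `Y`
(and, jointly, one auxiliary variable `A`) is drawn from one of two Gaussian
components with a shared covariance, and `Z` is the component label.
Estimation is by EM with structured multi-start and guards against
degenerate and spurious solutions.

## Worked example

```r
library(auxselect)

# Case 1 of the simulation design: the auxiliary variable carries the
# latent label; the joint model is correctly specified
d  <- generate_case("case1", n = 500, seed = 73)
df <- as.data.frame(d)
set.seed(74); df$noise <- rnorm(500)     # and one pure-noise candidate

res <- select_auxiliary(df, primary = "y", candidates = c("a", "noise"),
                        target = "x", seed = 75)
res
#> Auxiliary-variable selection (target: x )
#>   label criterion    value failed
#>  <none>    AIC_xy 1754.931  FALSE
#>       a    AIC_xb 1754.669  FALSE
#>   noise    AIC_xb 1754.832  FALSE
#> best: a
```

The informative auxiliary variable attains the minimum criterion and is
selected.  Note the scale of the differences: the criteria share the same
`-2n` goodness term up to the fit used, so what separates candidates is a
few criterion units of penalty and likelihood — here `a` beats the
no-auxiliary model by 0.26 on one n = 500 replicate (the difference averages
about −3.2 over replicates, with replicate-to-replicate noise of the same
order).  The iid-normal `noise` candidate lands within a whisker of the
no-auxiliary model: a joint model with an independent Gaussian auxiliary is
still correctly specified, so its criterion difference hovers around zero.
Structurally misspecified noise — e.g. a bimodal auxiliary unrelated to the
latent label, Case 2 of the simulation design — is rejected far more
decisively (about 85% of replicates at n = 100, essentially always by
n = 1000).

The LOOCV counterpart and its equivalence diagnostic:

```r
d <- generate_case("case1", n = 120, seed = 82)
cv <- loocv_risk(d, control = fit_control(seed = 83))
cv
#> LOOCV risk = 1.864026  (n = 120, failed refits = 0)
eq <- loocv_equivalence(cv, d)
round(unlist(eq[c("lhs", "rhs", "gap")]), 4)
#>      lhs      rhs      gap
#> 447.3663 448.1049   0.7386
```

`lhs` is `2n` times the LOOCV risk; `rhs` is `risk̂_x;b` minus twice the
estimated posterior cross-entropy shift; their gap (here ~0.7 on a ~447
scale) is the finite-sample remainder of the asymptotic equivalence.

A command-line interface wraps the same operations:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "auxselect.R", package = "auxselect"))')" \
  select --input data.csv --primary y --aux a1,a2 --criterion x --seed 1 --out out/
```

## Package layout

- `R/params.R`, `R/density.R` — the mixture parameter container and its
  log-densities / posteriors.
- `R/em.R` — EM fitting (observed-data and complete-data MLEs).
- `R/scores.R`, `R/infomat.R` — analytic/numeric score vectors and the six
  empirical information matrices.
- `R/criteria.R` — the criteria family and `select_auxiliary()`.
- `R/loocv.R` — latent-variable LOOCV and the equivalence diagnostic.
- `R/truth.R`, `R/quadrature.R`, `R/simulation.R` — the simulation truth,
  quadrature losses, and experiment runners.
- `R/cli.R`, `inst/cli/auxselect.R` — command-line entry points.
- `vignettes/auxiliary-selection.Rmd` — the methods vignette (model,
  assumptions, numerical choices, limitations).
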