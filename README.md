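# recruitr

Trait- and density-based cohort models of recruitment in sessile
organisms.

Early post-settlement mortality decides how many settlers of a sessile
marine invertebrate — the motivating system is an intertidal barnacle
cohort censused photographically in fixed quadrats — survive to recruit
into the adult population. Classical settler–recruit analyses use
density alone; this package implements an integrative alternative in
which survival depends on *resource use*, the product of density and
mean individual body size (cover), so that individual growth and
mortality jointly shape the settler–recruit curve. It is aimed at
population ecologists who want to (i) explore what curve shapes the
model can produce, (ii) fit it to their own quadrat censuses, and
(iii) probe the individual-level mechanisms behind it.

## The model

A closed cohort evolves in discrete time as

    N[t+1] = N[t] * lambda(N[t] * phi[t])
    phi[t+1] = phi[t] * exp(-K) + phi_inf * (1 - exp(-K))

where `N` is density, `phi` mean body size (Ford–Walford / von
Bertalanffy growth), and the survival fraction `lambda(u)` declines
with cover `u = N * phi` under one of three two-parameter forms

    exponential:  lambda = alpha * exp(-beta * u)
    logistic:     lambda = 1 / (1 + alpha' * exp(beta * u)),  alpha' = 1/alpha - 1
    hyperbolic:   lambda = alpha / (1 + beta * u)

with `alpha` the resource-independent per-step survival and `beta` the
resource-use-dependent mortality parameter (`1/beta` scales with
carrying capacity). Iterating from a grid of initial densities gives
settler–recruit maps whose shape (monotone, one hump, several points of
compensation) diagnoses the form and the growth–mortality balance.

For data, the package fits each form by OLS on its linearised scale
after standardising interval survivals to a common 30-day base
(`S_30 = S^(30/T)`), compares body-size descriptors (density, basal
cover, operculum cover) by adjusted R², and extends the best model with
period-varying `alpha` and dead-shell cover selected by AIC. A
synthetic census generator with known ground truth and a spatial
individual-based simulator (Poisson settlement, neighbourhood crowding,
threshold vs. geometric mortality) round out the toolkit. See the
vignette `vignettes/trait-density-recruitment.Rmd` for the full
methods account.

## Worked example

Generate a study-shaped synthetic census (2 shores x 52 quadrats of
25 cm², censused June/July/October/February) and fit one shore:

```r
library(recruitr)

obs <- simulate_dataset(study_design(), truth_params(), seed = 11)
shore1 <- obs[obs$shore == "shore1", ]

fit_all_forms(shore1)
#>    shore  descriptor exponential logistic hyperbolic
#> 1 shore1     density       0.132    0.123      0.124
#> 2 shore1 basal_cover       0.180    0.146      0.178
#> 3 shore1 operc_cover       0.301    0.275      0.291

fit_extended(shore1)
#> Linearised logistic survival fit (descriptor: operc_cover)
#>   alpha by period:
#>     June-July: 0.9722
#>     July-October: 0.9206
#>     October-February: 0.9096
#>   beta_live = 0.041
#>   beta_dead = 0.02922
#>   n = 156, adjusted R2 (transformed scale) = 0.882, AIC = -450.8

select_extended(shore1)
#> AIC model selection (4 candidates)
#>  alpha_by_period include_dead_cover k    aic delta_aic
#>             TRUE               TRUE 6 -450.8     0.000
#>             TRUE              FALSE 5 -443.2     7.628
#>            FALSE               TRUE 4 -249.3   201.510
#>            FALSE              FALSE 3 -170.2   280.596
#> Best: alpha_by_period = TRUE, include_dead_cover = TRUE
```

Reading the output: operculum cover predicts survival much better than
density alone or basal cover (adjusted R² 0.30 vs. 0.13 / 0.18),
because the generated basal area shrinks plastically with crowding
while operculum area tracks true resource use. The extended fit
recovers the generator's ground truth — per-period `alpha` of 0.97 then
0.92, `beta_live = 0.04`, `beta_dead = 0.036` — and AIC prefers the
model carrying both temporal effects.

Settler–recruit maps of the deterministic model:

```r
sp <- survival_params("logistic", alpha = 0.99, beta = 0.2)
g  <- growth_params(K = 0.01, phi_inf = 1, phi_0 = 0.01)
m  <- recruitment_map(sp, g, steps = 0:500)
max(apply(m$values[, -1], 2, count_local_maxima))
#> [1] 4
```

The logistic map develops four points of compensation at later steps —
overcompensation multiplying as the cohort grows — while the
exponential form keeps a single flattening hump and the hyperbolic form
stays monotone (`map_shape_by_step()`).

A command-line dispatcher over the same functions (subcommands
`simulate-map`, `fit`, `select`, `ibm`, `generate`) is installed at
`system.file("cli", "recruitr-cli.R", package = "recruitr")`.

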