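# fracbioheat

Time-fractional Pennes bioheat modelling for nanoparticle-assisted
hyperthermia of perfused tissue.

## The problem

Mild hyperthermia therapy heats tumour-bearing tissue to roughly 40–45 °C
to sensitise malignant cells to radio- and chemotherapy.  Intravenously
delivered nanoparticles (gold, carbon nanotubes, magnetite) raise the
effective conductivity of the perfusing blood and so change how heat from
a heated boundary penetrates the tissue.  `fracbioheat` is for modellers
who want a fast, fully deterministic 1-D simulator of that process with a
*memory-carrying* (fractional) time derivative, plus the wall
heat-transfer (Nusselt) bookkeeping used to compare particle species and
shapes.

## The model

On the dimensionless slab `y ∈ [0, 1]`, the package solves

    ᶜD_t^α ϑ = D ∂²ϑ/∂y² − c ϑ + s,     α ∈ (0, 1]

where `ᶜD_t^α` is the Caputo derivative and

    D = (r_k / r_cp)(1 + 4R/3),   c = γ − λ/r_cp,   s = γ + β/r_cp,

with `r_k`, `r_cp` the nanofluid-to-blood conductivity and heat-capacity
ratios (volume-weighted mixture rules and the Hamilton–Crosser
shape-factor correlation), `R` the Rosseland radiation parameter, `γ` the
blood-perfusion parameter, `λ` the metabolic heat-source parameter and
`β` the porous-structure parameter.  Initial/boundary values default to
37 (tissue) and 45 (heated wall).

Two independent solution routes are implemented and cross-validated
against each other:

* **Laplace route** — the closed-form transform-domain solution
  (`laplace_solution()`), inverted numerically by Durbin's Fourier-series
  method or Zakian's five-term rational approximation
  (`durbin_invert()`, `zakian_invert()`, `invert_field()`);
* **Finite-difference oracle** — an implicit Caputo L1 scheme
  (`solve_fd()`), which reduces exactly to backward Euler at `α = 1` and
  also runs in dimensional mode to check the nondimensionalisation.

Post-processing computes wall Nusselt numbers
`Nu = −(k_nf/k_b)(1 + 4R/3) ∂ϑ/∂y|wall` from the analytic
transform-domain derivative, enhancement percentages with the
three-decimal truncation convention of the published comparison tables,
and tidy parameter sweeps.  See the methods vignette
(`vignettes/fracbioheat-methods.Rmd`) for assumptions, numerical design
and limitations.

## Worked example

```r
library(fracbioheat)

cfg <- default_config(mixture = list(phi = 0.04),
                      grids = list(y_points = 5, t_values = c(0.5, 1, 2)))
fld <- simulate_field(cfg)
round(fld$values, 3)
#>        [,1]   [,2]   [,3]
#> [1,] 37.000 37.000 37.000
#> [2,] 38.147 38.168 38.180
#> [3,] 39.830 39.865 39.883
#> [4,] 42.095 42.126 42.143
#> [5,] 45.000 45.000 45.000
```

Rows are positions `y = 0, 0.25, …, 1`, columns the times `t = 0.5, 1, 2`:
the tissue warms from the heated wall (`y = 1`, pinned at 45) towards the
skin (`y = 0`, pinned at 37), and each interior point creeps upward in
time toward the steady profile.

```r
nusselt_table(therapy_params(), phis = c(0, 0.02, 0.04))
#>   particle    shape  phi      Nu enhancement_pct
#> 1     gold platelet 0.00 -4.1936           0.000
#> 2     gold platelet 0.02 -5.8254          38.910
#> 3     gold platelet 0.04 -7.5271          79.488
```

Loading the blood with gold platelets strengthens the wall heat transfer
(`|Nu|` grows with `φ`).  The *absolute* Nu scale depends on the chosen
evaluation time and parameter set; only relative enhancements are
meaningful across configurations.  The published reference columns ship
as data, and the package's truncating percentage arithmetic reproduces
every printed cell from them:

```r
recompute_enhancement(published_nusselt("species"))[c(5, 10, 20), ]
#>    particle  phi     Nu    pct pct_recomputed
#> 10     gold 0.04 24.307 16.412         16.412
#> 20    swcnt 0.04 23.776 13.869         13.869
#> 5     fe3o4 0.04 22.602  8.247          8.247
```

A thin command-line wrapper lives at `inst/cli/fracbioheat.R`:

    Rscript inst/cli/fracbioheat.R simulate --config cfg.yaml --out results/
    Rscript inst/cli/fracbioheat.R sweep --param R --values 0,0.5,1 --out results/
    Rscript inst/cli/fracbioheat.R validate --quick

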