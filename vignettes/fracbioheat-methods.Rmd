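---
title: "Methods: the time-fractional bioheat model and its numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the time-fractional bioheat model and its numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracbioheat)
```

## The model

`fracbioheat` simulates the temperature of perfused tissue during
nanoparticle-assisted hyperthermia.  The starting point is the Pennes
bioheat balance for a one-dimensional tissue slab of thickness $a$ whose
pores are perfused by blood loaded with nanoparticles: conduction through
the nanofluid, a perfusion sink/source $\omega_b (\rho c_p)_{nf}
(\theta_b - \theta)$, a metabolic source $Q_m (\theta - \theta_0)$, a
porous-matrix contribution, and Rosseland-linearised thermal radiation,
which folds into the conduction term as an enhanced diffusivity factor
$(1 + \tfrac{4}{3} R)$ with radiation parameter $R \ge 0$.

Time memory of biological tissue is modelled by replacing the first time
derivative with a Caputo fractional derivative of order
$\alpha \in (0, 1]$.  After nondimensionalising with $y = y^*/a$,
$t = \alpha_1 t^*/a^2$ ($\alpha_1 = k_b/(\rho_b c_{p,b})$ the blood thermal
diffusivity) the governing equation is

$$
{}^{C}\!D_t^{\alpha}\,\vartheta \;=\; D\,\partial_y^2 \vartheta
\;-\; c\,\vartheta \;+\; s, \qquad y \in [0, 1],
$$

with

$$
D = \frac{r_k}{r_{cp}}\Bigl(1 + \tfrac{4}{3}R\Bigr), \qquad
c = \gamma - \frac{\lambda}{r_{cp}}, \qquad
s = \gamma + \frac{\beta}{r_{cp}},
$$

where $r_k = k_{nf}/k_b$ and $r_{cp} = (\rho c_p)_{nf}/(\rho c_p)_b$ are
the nanofluid-to-blood property ratios and $\gamma$, $\lambda$, $\beta$
are the dimensionless perfusion, metabolic-source and porous-structure
groups.  This is the unique reading under which dividing the dimensional
energy balance by $(\rho c_p)_{nf}$ and applying the scaling reproduces
the dimensionless equation term by term; the package verifies it
mechanically by integrating the dimensional equation directly
(`solve_fd_dimensional()`) and overlaying the nondimensionalised result on
the dimensionless solve (agreement to $10^{-13}$ at $\alpha = 1$).

Since $a$, $\omega_b$, $Q_m$ and the porous permeability rarely come as a
consistent published set, $\gamma$, $\lambda$, $\beta$ and $R$ are direct
user inputs.  The defaults $\gamma = 1$, $\lambda = 0.5$, $\beta = 0.5$,
$R = 0.5$, $\alpha = 0.8$ are round mid-range values of the sweeps the
model is typically exercised over; they produce therapy-like fields (a
heated wall at 45, tissue near 37) and are not fitted to any dataset.

### Boundary conventions

Two equivalent conventions are supported through
`therapy_params(boundary_mode = )`:

* `"printed"` (default): $\vartheta(y, 0) = 37$, $\vartheta(0, t) = 37$,
  $\vartheta(1, t) = 45$ — the Celsius-like scale in which the published
  transform-domain solution of this model family is usually written;
* `"physical"`: the affinely mapped scale
  $\vartheta \to (\vartheta - 37)/8$, i.e. $0$ initial/skin and $1$ at the
  heated wall, which is what the nondimensionalisation
  $\vartheta = (\theta - \theta_0)/(\theta_b - \theta_0)$ literally
  produces.

The two differ only by an affine map (checked in the test suite); all
qualitative conclusions are identical.

## Materials

`material_db()` carries the standard thermophysical constants:

| material | $\rho$ (kg/m³) | $c_p$ (J/kg K) | $k$ (W/m K) |
|----------|---------------:|---------------:|------------:|
| blood    | 1050  | 3617 | 0.52 |
| gold     | 19300 | 129  | 318  |
| SWCNT    | 2600  | 425  | 6600 |
| MWCNT    | 1600  | 796  | 3000 |
| Fe₃O₄    | 5180  | 670  | 9.7  |

Mixture density and volumetric heat capacity follow the volume-weighted
rules; conductivity follows Hamilton–Crosser with empirical shape factor
$m$.  The package ties $m$ to sphericity by $m = 3/\psi$ (the
Hamilton–Crosser convention; at $\psi = 1$ both orientations of the
formula agree and give the sphere's $m = 3$), with defaults

```{r}
shape_db()
```

These come from standard sphericity tables.  A caveat worth stating
plainly: published enhancement tables for this model family order shapes
as platelet > cylinder > blade > brick, which no single standard $m$
table reproduces (a blade's $m \approx 8.6$ would rank it first).  The
shape factors are therefore configurable, and the package never asserts
its own Nusselt ordering against published absolute values.

## The Laplace route

Transforming the dimensionless equation in time gives a second-order ODE
in $y$ whose solution with the model's boundary values is, with
$\mu = \sqrt{(q^\alpha + c)/D}$ and the particular part
$F_p(q) = (\vartheta_0 q^\alpha + s)/(q (q^\alpha + c))$,

$$
\bar\vartheta(y, q) = F_p
+ \Bigl(\tfrac{\vartheta_L}{q} - F_p\Bigr)
  \frac{\sinh\bigl((1-y)\mu\bigr)}{\sinh \mu}
+ \Bigl(\tfrac{\vartheta_R}{q} - F_p\Bigr)
  \frac{\sinh\bigl(y\mu\bigr)}{\sinh \mu},
$$

algebraically identical to the usual $A \cosh + B \sinh$ form but better
conditioned.  Numerical choices:

* $q^\alpha$ and $\sqrt{\cdot}$ use principal branches; every inversion
  contour keeps $\operatorname{Re} q > 0$, so no branch cut is crossed and
  $\operatorname{Re}\mu \ge 0$.
* The $\sinh$/$\cosh$ ratios are evaluated with decaying exponentials
  only ($e^{-y\mu}$, $e^{-(1-y)\mu}$, $e^{-2\mu}$), so $|\mu|$ up to
  several hundred cannot overflow, and the boundary identities
  $\bar\vartheta(0,q) = \vartheta_L/q$, $\bar\vartheta(1,q) =
  \vartheta_R/q$ hold to machine precision by construction.
* $|\mu| < 10^{-6}$ falls back to the analytic $\mu \to 0$ limits.
* A vanishing $\sinh\mu$ on the contour (resonant spatial mode, only
  possible for $c < 0$) and a vanishing $q^\alpha + c$ (resonant pole)
  are detected and reported, not silently inverted.

The long-time limit solves $D\vartheta'' - c\vartheta + s = 0$ in closed
form (`steady_state()`), with the $c = 0$ polynomial and $c < 0$
trigonometric branches handled separately.

## Numerical inversion

### Durbin

`durbin_invert()` evaluates the transform on $q_k = a + i k \pi / T$,
$k = 0..N$, with $T$ = `durbin_period_factor` $\times\, t_{\max}$ and
$a T$ = `durbin_shift` (default 6), and sums

$$
f(t) \approx \frac{e^{a t}}{T} \Bigl[ \tfrac12 \operatorname{Re} F(a)
+ \sum_{k=1}^{N} \operatorname{Re} F(q_k) \cos \tfrac{k \pi t}{T}
- \operatorname{Im} F(q_k) \sin \tfrac{k \pi t}{T} \Bigr].
$$

(This is Durbin's trapezoidal Bromwich rule; texts that write the
prefactor $2 e^{at}/T$ use frequencies $2 k \pi/T$ with $T$ the full
period — the two conventions are the same rule.)  Two accuracy mechanisms
matter for this model:

* **Aliasing**: the periodisation error is
  $O(e^{-2 a T})\,|f(t + 2T)| \approx 6\times10^{-6}$ relative at the
  default shift — the accuracy floor for bounded solutions.
* **Truncation**: the bioheat transform decays only like
  $k^{-(1+\alpha)}$ (and like $k^{-1}$ wherever $f(0^+) \ne 0$), so plain
  partial sums converge slowly.  Two measures address this.  First, the
  initial value $f(0^+) = \lim_{q\to\infty} q F(q)$ is estimated at a
  large real frequency, the transform is inverted as $F - f_0/q$ and
  $f_0$ is added back (`durbin_subtract_f0`, on by default); this removes
  the $k^{-1}$ tail exactly and is what makes near-boundary points of the
  temperature field invertible to $10^{-3}$ accuracy.  Second, the
  default term count is deliberately large (`durbin_terms = 50000`):
  the transform evaluation is vectorised and cheap, and the measured
  worst-case error of the analytic validation battery is then below
  $10^{-4}$, with the Laplace-vs-finite-difference discrepancy below
  $3\times10^{-3}$.  A warning reports when the last retained term still
  contributes more than `warn_tail` of the inverted value.

### Zakian

`zakian_invert()` implements
$f(t) \approx \tfrac{2}{t} \sum_{i=1}^{5}
\operatorname{Re}[K_i F(\alpha_i/t)]$ with the five classical
conjugate-pair constants, shipped as a plain-text fixture
(`extdata/zakian_constants.csv`) and validated by the $1/q$ test.  Zakian
is essentially exact ($\sim10^{-7}$) for transforms with rational
structure, which makes it a sharp cross-check at early and moderate
times.  Two documented limitations follow from its nature as a fixed
5-term rational approximation of $e^{st}$:

* branch-cut (fractional-power) transforms are approximated to only
  $\sim10^{-3}$ relative — the fractional pair of the validation battery
  is therefore held to a $10^{-2}$ band for Zakian while Durbin meets
  $10^{-4}$;
* once a mode has decayed ($\lambda t \gtrsim 30$) its contribution is
  reproduced with $O(10^{-2})$ *absolute* error, so Zakian drifts near
  steady state while Durbin stays on the closed form.  The dual-method
  agreement check consequently uses the window $t \in [0.05, 0.5]$, with
  Durbin (itself validated against the finite-difference oracle) as the
  accurate reference at later times.

`invert_field()` defaults to Durbin and never inverts $t = 0$ (both
formulas are singular there); the initial condition is written directly.

## The finite-difference oracle

`solve_fd()` discretises the Caputo derivative with the L1 weights
$b_j = (j+1)^{1-\alpha} - j^{1-\alpha}$ and implicit central differences
in space: one constant tridiagonal system per run, factored once, with
the full memory sum retained (no short-memory truncation — at the grid
sizes used, the $O(n_t^2)$ cost is irrelevant, and at $\alpha = 1$ the
weights vanish and the scheme collapses exactly to backward Euler, which
the suite checks to $10^{-10}$ against an independent implementation).
The implicit form is unconditionally stable, so parameter sweeps are not
grid-fragile.  Expected orders are $2-\alpha$ in time and 2 in space.

The oracle exists to catch coefficient-assembly or transform-algebra
mistakes: `cross_validate()` runs the matrix
$\alpha \in \{0.7, 1\} \times \phi \in \{0, 0.04\} \times R \in \{0,
0.5\}$ on a 21-point profile at four time slices and requires
$\le 10^{-2}$ maximum absolute discrepancy between the two routes.  The
oracle grid (81 spatial points; 2000 steps, 8000 at $\alpha = 1$ where
steps are memoryless and cheap) puts the oracle's own error well below
that band; measured discrepancies are $\sim 2.5\times10^{-3}$ and are
dominated by the inversion, not the oracle.

## Nusselt numbers and enhancement tables

The wall heat-transfer number is

$$
\mathrm{Nu} = -\frac{k_{nf}}{k_b}\Bigl(1 + \tfrac43 R\Bigr)
\left.\frac{\partial\vartheta}{\partial y}\right|_{y = y_w,\ t = t_{\mathrm{eval}}},
$$

with the gradient obtained by inverting the *analytic* transform-domain
derivative (`laplace_solution_dy()`) — no finite differencing at the
boundary.  The absolute Nu scale of published comparison tables for this
model family is not reproducible (their $t_{\mathrm{eval}}$, wall and
parameter set are unpublished), so absolute values are never asserted;
what the package does reproduce, exactly, is the enhancement arithmetic:
`enhancement_percent()` truncates (toward zero) at three decimals, which
regenerates all 40 published percentage cells from the published Nusselt
columns, where rounding fails several.  A round-to-9-decimals guard
precedes truncation so decimal-exact cells (e.g. 6.25) are not knocked
down by binary representation.  `published_nusselt()` ships those columns
as data; `nusselt_table()` computes the model's own table.

## Study conditions, and what passing tests do and do not show

The package generates all of its own inputs; there is no external data
and no randomness anywhere (identical configurations give byte-identical
outputs).  The default study conditions — gold platelet particles at
$\phi = 0.02$ in blood, $\alpha = 0.8$, $R = \lambda = \beta = 0.5$,
$\gamma = 1$, walls 37/45, $y$ on 21 points, $t \in \{0.25, 0.5, 1, 2\}$
— emulate a mild-hyperthermia setting: a tissue slab initially at body
temperature heated from one face to 45.

What the validation battery *does* establish: the closed-form transform
satisfies its ODE and boundary identities; two independent solution
routes agree to $\sim3\times10^{-3}$ across fractional orders, loadings
and radiation strengths; limiting cases (integer order, equilibrium,
steady state) collapse to exact counterparts; and the physical trends —
temperature non-decreasing in $\phi$, $R$, $\lambda$, $\beta$ and $t$ —
hold quantitatively on the default ranges.  What it does *not* show: that
any particular clinical temperature is reached (the dimensionless groups
are not calibrated to a measured tissue), nor that the absolute Nusselt
scale of the published tables is recovered.  Real tissue additionally has
multi-layer structure, temperature-dependent perfusion and 2-D/3-D
geometry, none of which are modelled.

## Known limitations

* One spatial dimension, single homogeneous layer, constant properties.
* No momentum equation: particle loading affects conduction and heat
  capacity only (no viscosity model), so "temperature rises with
  $\phi$" here is a conduction/capacity statement.
* Zakian's method should not be used for long-time or strongly
  oscillatory content (see above); it is provided as the cross-check the
  dual-method design calls for, with Durbin as the production method.
* The Caputo order $\alpha$ is a phenomenological memory parameter; the
  package varies it directly and makes no claim about rescaling time
  between different orders.
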