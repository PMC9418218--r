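# Dimensionless fractional bioheat model: coefficient assembly, the
# Laplace-domain closed-form solution and its spatial derivative, and the
# long-time steady state.
#
# The governing dimensionless equation on y in [0,1] is
#
#   D_t^alpha theta = D theta_yy - c theta + s
#
# with a Caputo derivative of order alpha in (0,1], effective diffusivity
# D = (r_k / r_cp) (1 + 4R/3), linear reaction c = gamma - lambda / r_cp and
# constant source s = gamma + beta / r_cp, where r_k and r_cp are the
# nanofluid-to-blood conductivity and heat-capacity ratios, R the radiation
# parameter, gamma the perfusion parameter, lambda the metabolic heat-source
# parameter and beta the porous-structure parameter.

#' Dimensionless therapy parameters
#'
#' Collects the dimensionless groups of the fractional bioheat model and the
#' initial/boundary temperature values.
#'
#' Two boundary conventions are supported.  `"printed"` keeps the boundary
#' and initial values on the Celsius-like scale (37 at the skin/initial
#' state, 45 at the heated wall), matching the published transform-domain
#' solution.  `"physical"` uses the affinely mapped scale where the initial
#' state is 0 and the heated wall is 1.  The two differ only by the affine
#' map `theta -> (theta - 37)/8` applied to initial and boundary data.
#'
#' @param alpha Caputo fractional order in (0, 1]; 1 recovers the classical
#'   integer-order model.
#' @param R Radiation parameter (>= 0); enters through the Rosseland
#'   diffusion enhancement factor `1 + 4R/3`.
#' @param gamma Blood-perfusion parameter (>= 0).
#' @param lambda Metabolic heat-source parameter (>= 0).
#' @param beta Porous-structure parameter (>= 0).
#' @param boundary_mode `"printed"` (default) or `"physical"`; sets the
#'   default temperature values below.
#' @param theta_init Initial dimensionless temperature (default 37 / 0).
#' @param theta_left Boundary value at `y = 0` (default 37 / 0).
#' @param theta_right Boundary value at `y = 1` (default 45 / 1).
#'
#' @return An object of class `therapy_params`.
#' @export
#' @examples
#' therapy_params(alpha = 0.8, R = 0.5)
#' therapy_params(boundary_mode = "physical")
therapy_params <- function(alpha = 0.8, R = 0.5, gamma = 1, lambda = 0.5,
                           beta = 0.5,
                           boundary_mode = c("printed", "physical"),
                           theta_init = NULL, theta_left = NULL,
                           theta_right = NULL) {
  boundary_mode <- match.arg(boundary_mode)
  chk <- function(v, nm, lo = 0, lo_open = FALSE, hi = Inf) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        (if (lo_open) v <= lo else v < lo) || v > hi) {
      stop(sprintf("'%s' must be a finite scalar in %s%g, %g]", nm,
                   if (lo_open) "(" else "[", lo, hi), call. = FALSE)
    }
  }
  chk(alpha, "alpha", 0, TRUE, 1)
  chk(R, "R"); chk(gamma, "gamma"); chk(lambda, "lambda"); chk(beta, "beta")
  defaults <- if (boundary_mode == "printed") c(37, 37, 45) else c(0, 0, 1)
  if (is.null(theta_init)) theta_init <- defaults[1]
  if (is.null(theta_left)) theta_left <- defaults[2]
  if (is.null(theta_right)) theta_right <- defaults[3]
  stopifnot(is.numeric(theta_init), is.numeric(theta_left),
            is.numeric(theta_right))
  structure(list(alpha = alpha, R = R, gamma = gamma, lambda = lambda,
                 beta = beta, boundary_mode = boundary_mode,
                 theta_init = theta_init, theta_left = theta_left,
                 theta_right = theta_right),
            class = "therapy_params")
}

#' @export
print.therapy_params <- function(x, ...) {
  cat(sprintf(paste0("<therapy_params> alpha = %g, R = %g, gamma = %g, ",
                     "lambda = %g, beta = %g\n  %s boundaries: theta(y,0) = %g, ",
                     "theta(0,t) = %g, theta(1,t) = %g\n"),
              x$alpha, x$R, x$gamma, x$lambda, x$beta, x$boundary_mode,
              x$theta_init, x$theta_left, x$theta_right))
  invisible(x)
}

#' PDE coefficients of the dimensionless bioheat equation
#'
#' Direct constructor for the triple (D, c, s) of
#' `D_t^alpha theta = D theta_yy - c theta + s`.  Normally produced by
#' [assemble_coefficients()]; the direct form is useful for model-agnostic
#' numerical studies.
#'
#' @param D Effective diffusion coefficient (> 0).
#' @param c Linear reaction coefficient (any sign).
#' @param s Constant source term.
#'
#' @return An object of class `pde_coefficients`.
#' @export
pde_coefficients <- function(D, c, s) {
  stopifnot(is.numeric(D), length(D) == 1L, is.finite(D),
            is.numeric(c), length(c) == 1L, is.finite(c),
            is.numeric(s), length(s) == 1L, is.finite(s))
  if (D <= 0) stop("'D' must be positive", call. = FALSE)
  structure(list(D = D, c = c, s = s), class = "pde_coefficients")
}

#' @export
print.pde_coefficients <- function(x, ...) {
  cat(sprintf("<pde_coefficients> D = %.6g, c = %.6g, s = %.6g\n",
              x$D, x$c, x$s))
  invisible(x)
}

#' Assemble dimensionless PDE coefficients from therapy parameters
#'
#' With `r_cp = (rho cp)_nf / (rho cp)_b` and `r_k = k_nf / k_b`:
#' `D = (r_k / r_cp)(1 + 4R/3)`, `c = gamma - lambda / r_cp`,
#' `s = gamma + beta / r_cp`.  With no particles (`phi = 0`) and no
#' radiation (`R = 0`), `D = 1` under the adopted time scaling.
#'
#' @param params A [therapy_params()].
#' @param mix Optional [nanofluid_mixture()]; `NULL` means pure blood
#'   (`r_cp = r_k = 1`).
#'
#' @return A [pde_coefficients()] object.
#' @export
#' @examples
#' assemble_coefficients(therapy_params(R = 0))
assemble_coefficients <- function(params, mix = NULL) {
  stopifnot(inherits(params, "therapy_params"))
  if (is.null(mix)) {
    r_cp <- 1
    r_k <- 1
  } else {
    pr <- mixture_properties(mix)
    r_cp <- pr$r_cp
    r_k <- pr$r_k
  }
  D <- (r_k / r_cp) * (1 + 4 * params$R / 3)
  stopifnot(D > 0)
  pde_coefficients(D = D,
                   c = params$gamma - params$lambda / r_cp,
                   s = params$gamma + params$beta / r_cp)
}

# sinh(f mu)/sinh(mu) and cosh(f mu)/sinh(mu) for complex mu with
# Re(mu) >= 0, written with decaying exponentials only so that |mu| of
# several hundred cannot overflow.  For |mu| below 1e-6 the analytic limits
# f and (1/mu -> handled by caller) are substituted.
.ratio_sinh <- function(f, mu) {
  out <- (exp(-(1 - f) * mu) - exp(-(1 + f) * mu)) / (1 - exp(-2 * mu))
  small <- Mod(mu) < 1e-6
  if (any(small)) out[small] <- f
  out
}

.check_sinh <- function(mu) {
  bad <- Mod(1 - exp(-2 * mu)) < 1e-14 & Mod(mu) >= 1e-6
  if (any(bad)) {
    stop("sinh(mu) vanishes on the inversion contour (resonant spatial mode); ",
         "shift the contour or perturb c", call. = FALSE)
  }
}

#' Laplace transform of the spatially uniform particular solution
#'
#' `F_p(q) = (theta_init q^alpha + s) / (q (q^alpha + c))`, the transform of
#' the y-independent response to the initial state and the constant source.
#' When `s = c * theta_init` it collapses to `theta_init / q` for every `q`
#' and `alpha` (equilibrium).
#'
#' @param q Complex frequency (vectorised); must have positive real part.
#' @param coeff A [pde_coefficients()].
#' @param params A [therapy_params()].
#'
#' @return Complex vector of transform values.
#' @export
laplace_particular <- function(q, coeff, params) {
  stopifnot(inherits(coeff, "pde_coefficients"),
            inherits(params, "therapy_params"))
  q <- as.complex(q)
  if (any(Re(q) <= 0)) stop("Re(q) must be positive", call. = FALSE)
  qa <- q^params$alpha
  den <- qa + coeff$c
  if (any(Mod(den) < 1e-12)) {
    stop("q^alpha + c vanishes on the contour (resonant pole); ",
         "shift the contour", call. = FALSE)
  }
  (params$theta_init * qa + coeff$s) / (q * den)
}

#' Laplace-domain solution of the fractional bioheat model
#'
#' Closed-form transform of the dimensionless temperature,
#' `theta_bar(y, q) = A cosh(y mu) + B sinh(y mu) + F_p(q)` with
#' `mu = sqrt((q^alpha + c)/D)`, `A = theta_left/q - F_p` and `B` fixed by
#' the `y = 1` boundary value.  Evaluated in an overflow-safe exponential
#' form; the boundary identities `theta_bar(0, q) = theta_left/q` and
#' `theta_bar(1, q) = theta_right/q` hold to machine precision.
#'
#' @param y Position in \[0, 1\] (scalar).
#' @param q Complex frequency with positive real part (vectorised).
#' @param coeff A [pde_coefficients()].
#' @param params A [therapy_params()].
#'
#' @return Complex vector of transform values.
#' @export
#' @examples
#' p <- therapy_params(); co <- assemble_coefficients(p)
#' laplace_solution(0, 2 + 1i, co, p)  # = 37 / (2 + 1i)
laplace_solution <- function(y, q, coeff, params) {
  stopifnot(is.numeric(y), length(y) == 1L, y >= 0, y <= 1)
  Fp <- laplace_particular(q, coeff, params)
  q <- as.complex(q)
  mu <- sqrt((q^params$alpha + coeff$c) / coeff$D)
  .check_sinh(mu)
  Fp + (params$theta_left / q - Fp) * .ratio_sinh(1 - y, mu) +
    (params$theta_right / q - Fp) * .ratio_sinh(y, mu)
}

#' Spatial derivative of the Laplace-domain solution
#'
#' `d theta_bar / dy = mu (A sinh(y mu) + B cosh(y mu))`, evaluated in the
#' same overflow-safe form as [laplace_solution()].  Used for wall heat-flux
#' (Nusselt number) computations.
#'
#' @inheritParams laplace_solution
#' @return Complex vector of transform-domain derivative values.
#' @export
laplace_solution_dy <- function(y, q, coeff, params) {
  stopifnot(is.numeric(y), length(y) == 1L, y >= 0, y <= 1)
  Fp <- laplace_particular(q, coeff, params)
  q <- as.complex(q)
  mu <- sqrt((q^params$alpha + coeff$c) / coeff$D)
  .check_sinh(mu)
  A1 <- params$theta_left / q - Fp
  A2 <- params$theta_right / q - Fp
  small <- Mod(mu) < 1e-6
  out <- mu * (-A1 * (exp(-y * mu) + exp(-(2 - y) * mu)) +
                 A2 * (exp(-(1 - y) * mu) + exp(-(1 + y) * mu))) /
    (1 - exp(-2 * mu))
  # mu -> 0 limit: linear steady interpolation gradient (theta_R - theta_L)/q
  if (any(small)) out[small] <- (A2 - A1)[small]
  out
}

#' Bundle the transform-domain evaluators of the model
#'
#' Packages [laplace_solution()] and [laplace_solution_dy()] as functions of
#' `(y, q)` for use with [invert_field()].
#'
#' @param coeff A [pde_coefficients()].
#' @param params A [therapy_params()].
#'
#' @return An object of class `laplace_field`: a list with elements `value`
#'   and `dy` (functions of `y` and complex `q`), plus the generating
#'   `coeff` and `params`.
#' @export
laplace_field <- function(coeff, params) {
  force(coeff); force(params)
  structure(list(
    value = function(y, q) laplace_solution(y, q, coeff, params),
    dy = function(y, q) laplace_solution_dy(y, q, coeff, params),
    coeff = coeff, params = params
  ), class = "laplace_field")
}

#' Long-time steady-state temperature profile
#'
#' Closed-form solution of `D theta'' - c theta + s = 0` with the model's
#' boundary values.  For `c > 0` this is
#' `s/c + A0 cosh(y sqrt(c/D)) + B0 sinh(y sqrt(c/D))`; for `c = 0` the
#' quadratic profile `theta_left + (theta_right - theta_left) y +
#' s y (1 - y) / (2D)`; for `c < 0` the trigonometric analogue (rejected at
#' resonance `sqrt(-c/D) = n pi`).
#'
#' @param y Positions in \[0, 1\] (vectorised).
#' @param coeff A [pde_coefficients()].
#' @param params A [therapy_params()] (supplies the boundary values).
#'
#' @return Numeric vector of steady temperatures.
#' @export
#' @examples
#' p <- therapy_params(boundary_mode = "physical")
#' steady_state(0.5, pde_coefficients(1, 1, 0), p)  # sinh(0.5)/sinh(1)
steady_state <- function(y, coeff, params) {
  stopifnot(inherits(coeff, "pde_coefficients"),
            inherits(params, "therapy_params"),
            is.numeric(y), all(y >= 0), all(y <= 1))
  D <- coeff$D; cc <- coeff$c; s <- coeff$s
  thL <- params$theta_left; thR <- params$theta_right
  if (cc > 0) {
    mu0 <- sqrt(cc / D)
    base <- s / cc
    A0 <- thL - base
    B0 <- (thR - base - A0 * cosh(mu0)) / sinh(mu0)
    base + A0 * cosh(y * mu0) + B0 * sinh(y * mu0)
  } else if (cc == 0) {
    thL + (thR - thL) * y + s * y * (1 - y) / (2 * D)
  } else {
    om <- sqrt(-cc / D)
    if (abs(sin(om)) < 1e-10) {
      stop("steady state is resonant (sqrt(-c/D) at a multiple of pi)",
           call. = FALSE)
    }
    base <- s / cc
    A0 <- thL - base
    B0 <- (thR - base - A0 * cos(om)) / sin(om)
    base + A0 * cos(y * om) + B0 * sin(y * om)
  }
}
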