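# Independent finite-difference solver: implicit Caputo L1 scheme in time,
# central differences in space.  Serves as the brute-force oracle against
# which the Laplace-path solution is cross-validated, and as a dimensional
# check on the nondimensionalisation.

#' Uniform finite-difference grid
#'
#' @param ny Number of spatial points including both boundaries (>= 3).
#' @param nt Number of time steps (>= 1).
#' @param t_max Final dimensionless time (> 0).
#' @param length Domain length (default 1, the dimensionless slab).
#'
#' @return An object of class `fd_grid` with `dy = length/(ny-1)`,
#'   `dt = t_max/nt` and the full `y`/`t` vectors.
#' @export
fd_grid <- function(ny, nt, t_max, length = 1) {
  stopifnot(is.numeric(ny), ny >= 3, ny == as.integer(ny),
            is.numeric(nt), nt >= 1, nt == as.integer(nt),
            is.numeric(t_max), t_max > 0, is.numeric(length), length > 0)
  structure(list(ny = as.integer(ny), nt = as.integer(nt), t_max = t_max,
                 dy = length / (ny - 1), dt = t_max / nt,
                 y = seq(0, length, length.out = ny),
                 t = seq(0, t_max, length.out = nt + 1)),
            class = "fd_grid")
}

#' L1 weights of the Caputo derivative
#'
#' `b_j = (j+1)^(1-alpha) - j^(1-alpha)` for `j = 0..n-1`.  `b_0 = 1` for
#' every order; at `alpha = 1` the memory vanishes and the weights reduce to
#' `(1, 0, 0, ...)` (backward Euler).
#'
#' @param alpha Fractional order in (0, 1].
#' @param n Number of weights (>= 1).
#'
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' caputo_l1_weights(0.5, 3)  # 1, sqrt(2)-1, sqrt(3)-sqrt(2)
caputo_l1_weights <- function(alpha, n) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1,
            is.numeric(n), n >= 1)
  j <- 0:(n - 1)
  lo <- j^(1 - alpha)
  lo[1L] <- 0  # 0^(1-alpha) -> 0, including the alpha = 1 limit
  (j + 1)^(1 - alpha) - lo
}

#' Temperature field container
#'
#' Temperatures on a `(y, t)` grid with provenance metadata.
#'
#' @param values Numeric matrix, `length(y)` rows by `length(t)` columns.
#' @param y Spatial grid.
#' @param t Time grid.
#' @param method Provenance string (e.g. `"laplace-durbin"`, `"fd-l1"`).
#' @param settings Solver/inversion settings used (stored as-is).
#'
#' @return An object of class `temperature_field`.
#' @export
temperature_field <- function(values, y, t, method, settings = NULL) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(y), ncol(values) == length(t))
  if (any(!is.finite(values))) {
    stop("temperature field contains non-finite values", call. = FALSE)
  }
  structure(list(values = values, y = y, t = t, method = method,
                 settings = settings),
            class = "temperature_field")
}

#' @export
print.temperature_field <- function(x, ...) {
  cat(sprintf("<temperature_field> %d x %d (y x t), method = %s\n",
              nrow(x$values), ncol(x$values), x$method))
  cat(sprintf("  y in [%g, %g], t in [%g, %g], theta in [%.4g, %.4g]\n",
              min(x$y), max(x$y), min(x$t), max(x$t),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Long-format data frame of a temperature field
#'
#' @param x A [temperature_field()].
#' @param ... Unused.
#' @return A data frame with columns `y`, `t`, `theta`, `method`.
#' @export
as.data.frame.temperature_field <- function(x, ...) {
  data.frame(y = rep(x$y, times = length(x$t)),
             t = rep(x$t, each = length(x$y)),
             theta = as.vector(x$values),
             method = x$method,
             stringsAsFactors = FALSE)
}

#' Implicit L1 finite-difference solve of the fractional bioheat model
#'
#' Discretises `D_t^alpha theta = D theta_yy - c theta + s` with the Caputo
#' L1 weights in time (implicit, unconditionally stable) and second-order
#' central differences in space.  Each step solves
#' `(sigma_alpha + c + 2D/dy^2) theta_i - (D/dy^2)(theta_{i-1} + theta_{i+1})
#'  = sigma_alpha (history) + s` with `sigma_alpha = dt^-alpha / Gamma(2-alpha)`;
#' the full history sum is retained (no short-memory truncation).  Boundary
#' rows are pinned to the configured boundary values; the `t = 0` column
#' carries the initial state.
#'
#' @param params A [therapy_params()] (supplies `alpha` and the
#'   initial/boundary values).
#' @param coeff A [pde_coefficients()].
#' @param grid An [fd_grid()].
#'
#' @return A [temperature_field()] on the full grid (including `t = 0`).
#' @export
solve_fd <- function(params, coeff, grid) {
  stopifnot(inherits(params, "therapy_params"),
            inherits(coeff, "pde_coefficients"),
            inherits(grid, "fd_grid"))
  alpha <- params$alpha
  ny <- grid$ny; nt <- grid$nt
  ni <- ny - 2L
  sig <- grid$dt^(-alpha) / gamma(2 - alpha)
  w <- caputo_l1_weights(alpha, nt)
  lam <- coeff$D / grid$dy^2
  # constant tridiagonal system; factor once
  M <- diag(sig + coeff$c + 2 * lam, ni)
  if (ni > 1) {
    idx <- seq_len(ni - 1)
    M[cbind(idx, idx + 1)] <- -lam
    M[cbind(idx + 1, idx)] <- -lam
  }
  Minv <- solve(M)
  U <- matrix(params$theta_init, ny, nt + 1L)
  U[1L, -1L] <- params$theta_left
  U[ny, -1L] <- params$theta_right
  DU <- matrix(0, ni, nt)
  u <- rep(params$theta_init, ni)
  hist_free <- alpha == 1  # memory weights vanish at integer order
  for (n in seq_len(nt)) {
    hist <- if (!hist_free && n >= 2L) {
      as.vector(DU[, seq_len(n - 1L), drop = FALSE] %*% w[n:2])
    } else 0
    rhs <- coeff$s + sig * (u - hist)
    rhs[1L] <- rhs[1L] + lam * params$theta_left
    rhs[ni] <- rhs[ni] + lam * params$theta_right
    un <- as.vector(Minv %*% rhs)
    if (any(!is.finite(un))) {
      stop(sprintf(paste0("L1 solve became non-finite at step %d ",
                          "(ny = %d, nt = %d, dt = %g, dy = %g)"),
                   n, ny, nt, grid$dt, grid$dy), call. = FALSE)
    }
    DU[, n] <- un - u
    u <- un
    U[2:(ny - 1L), n + 1L] <- un
  }
  temperature_field(U, grid$y, grid$t, method = "fd-l1",
                    settings = list(ny = ny, nt = nt, t_max = grid$t_max,
                                    alpha = alpha))
}

#' Dimensional-mode finite-difference solve
#'
#' Integrates the dimensional (integer-order) bioheat equation directly:
#' `(rho cp)_nf dtheta/dt* = k_nf (1 + 4R/3) d2theta/dy*2
#'   + omega_b (rho cp)_nf (theta_b - theta) + eps_K + Qm (theta - theta_0)`
#' on a slab of thickness `a`, with wall temperatures `theta_left` /
#' `theta_right` and uniform initial state `theta_init` (all in deg C).
#' Dividing by `(rho cp)_nf` reduces this to a linear reaction-diffusion
#' problem that is solved with the same implicit machinery as [solve_fd()]
#' at `alpha = 1`; under the scaling `y = y*/a`, `t = alpha_1 t*/a^2`
#' (`alpha_1 = k_b/(rho_b cp_b)`) its nondimensionalised solution must
#' overlay the dimensionless solve, which is the arbitration check on the
#' coefficient assembly.
#'
#' @param mix A [nanofluid_mixture()] (or `NULL` for pure blood).
#' @param a Slab thickness, m.
#' @param omega_b Blood perfusion rate, 1/s.
#' @param Qm Metabolic heat-source coefficient, W/(m^3 K).
#' @param eps_K Porous-structure constant source, W/m^3.
#' @param R Radiation parameter (dimensionless).
#' @param theta_0 Reference (initial tissue) temperature, deg C.
#' @param theta_b Blood temperature, deg C.
#' @param theta_init,theta_left,theta_right Initial and wall temperatures,
#'   deg C; default `theta_0`, `theta_0`, `theta_b`.
#' @param grid An [fd_grid()] whose `t_max` and `length` are in dimensional
#'   units (`length` should equal `a`).
#' @param base Base-fluid properties used for the scaling (default blood).
#'
#' @return A [temperature_field()] in dimensional units, with the implied
#'   dimensionless groups (`gamma`, `lambda`, `beta`, scaling constants) in
#'   its `settings`.
#' @export
solve_fd_dimensional <- function(mix = NULL, a, omega_b, Qm, eps_K, R,
                                 theta_0 = 37, theta_b = 45,
                                 theta_init = theta_0, theta_left = theta_0,
                                 theta_right = theta_b, grid,
                                 base = get_material("blood")) {
  stopifnot(inherits(grid, "fd_grid"), a > 0, omega_b >= 0, R >= 0)
  if (is.null(mix)) mix <- nanofluid_mixture(base = base, particle = base,
                                             phi = 0)
  pr <- mixture_properties(mix)
  # divide the energy balance by (rho cp)_nf
  Ddim <- pr$k * (1 + 4 * R / 3) / pr$rho_cp
  cdim <- omega_b - Qm / pr$rho_cp
  sdim <- omega_b * theta_b + (eps_K - Qm * theta_0) / pr$rho_cp
  p <- therapy_params(alpha = 1, R = R, gamma = 0, lambda = 0, beta = 0,
                      theta_init = theta_init, theta_left = theta_left,
                      theta_right = theta_right)
  co <- pde_coefficients(Ddim, cdim, sdim)
  fld <- solve_fd(p, co, grid)
  alpha_1 <- base$k / (base$rho * base$cp)
  fld$method <- "fd-l1-dimensional"
  fld$settings <- list(
    a = a, omega_b = omega_b, Qm = Qm, eps_K = eps_K, R = R,
    theta_0 = theta_0, theta_b = theta_b, alpha_1 = alpha_1,
    gamma = a^2 * omega_b / alpha_1,
    lambda = a^2 * Qm / base$k,
    beta = a^2 * eps_K / (base$k * (theta_b - theta_0)))
  fld
}

#' Laplace-vs-finite-difference cross-validation matrix
#'
#' For each `(alpha, phi, R)` combination, solves the model with the L1
#' finite-difference oracle and with the inverted closed-form transform, and
#' reports the maximum absolute discrepancy on `ny_eval` spatial points at
#' the requested time slices.
#'
#' @param alphas,phis,Rs Vectors of fractional orders, volume fractions and
#'   radiation parameters to cross (defaults: the validation matrix
#'   `{0.7, 1} x {0, 0.04} x {0, 0.5}`).
#' @param t_slices Time slices compared (default `c(0.1, 0.5, 1, 2)`).
#' @param ny_eval Number of evaluation points in y (default 21).
#' @param params Base [therapy_params()]; its `alpha` and `R` are
#'   overridden per case.
#' @param particle,shape Mixture used when `phi > 0` (default gold
#'   platelets).
#' @param fd_ny,fd_nt Oracle grid (defaults 81 and 2000; at `alpha = 1` the
#'   memoryless scheme is cheap and `4 * fd_nt` steps are used to keep the
#'   backward-Euler time error comparable).
#' @param settings An [inversion_settings()] for the Laplace path.
#'
#' @return Data frame with one row per case and a `max_abs_diff` column.
#' @export
cross_validate <- function(alphas = c(0.7, 1), phis = c(0, 0.04),
                           Rs = c(0, 0.5), t_slices = c(0.1, 0.5, 1, 2),
                           ny_eval = 21, params = therapy_params(),
                           particle = "gold", shape = "platelet",
                           fd_ny = 81, fd_nt = 2000,
                           settings = inversion_settings()) {
  stopifnot((fd_ny - 1) %% (ny_eval - 1) == 0)
  y_eval <- seq(0, 1, length.out = ny_eval)
  step <- (fd_ny - 1L) / (ny_eval - 1L)
  t_max <- max(t_slices)
  out <- list()
  for (al in alphas) for (phi in phis) for (R in Rs) {
    p <- therapy_params(alpha = al, R = R, gamma = params$gamma,
                        lambda = params$lambda, beta = params$beta,
                        boundary_mode = params$boundary_mode,
                        theta_init = params$theta_init,
                        theta_left = params$theta_left,
                        theta_right = params$theta_right)
    mix <- if (phi > 0) nanofluid_mixture(particle = particle, phi = phi,
                                          shape = shape) else NULL
    co <- assemble_coefficients(p, mix)
    nt <- if (al == 1) 4L * fd_nt else fd_nt
    fd <- solve_fd(p, co, fd_grid(fd_ny, nt, t_max))
    lp <- suppressWarnings(
      invert_field(laplace_field(co, p), y_eval, t_slices, settings))
    jt <- vapply(t_slices, function(t1) which.min(abs(fd$t - t1)), integer(1))
    d <- max(abs(fd$values[seq(1, fd_ny, by = step), jt, drop = FALSE] -
                   lp$values))
    out[[length(out) + 1L]] <- data.frame(alpha = al, phi = phi, R = R,
                                          max_abs_diff = d)
  }
  do.call(rbind, out)
}
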