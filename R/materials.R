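# Thermophysical property database and nanofluid mixture correlations.

#' Thermophysical properties of a material
#'
#' Bundles the density, specific heat and thermal conductivity of a base
#' fluid (blood) or a nanoparticle species.
#'
#' @param name Material name (single string).
#' @param rho Density in kg/m^3 (positive scalar).
#' @param cp Specific heat in J/(kg K) (positive scalar).
#' @param k Thermal conductivity in W/(m K) (positive scalar).
#'
#' @return An object of class `material_props`.
#' @seealso [material_db()] for the built-in property table.
#' @export
#' @examples
#' material_props("blood", rho = 1050, cp = 3617, k = 0.52)
material_props <- function(name, rho, cp, k) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  for (nm in c("rho", "cp", "k")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("'%s' must be a positive finite scalar (got %s)", nm,
                   paste(format(v), collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(name = name, rho = rho, cp = cp, k = k),
            class = "material_props")
}

#' @export
print.material_props <- function(x, ...) {
  cat(sprintf("<material_props> %s: rho = %g kg/m^3, cp = %g J/(kg K), k = %g W/(m K)\n",
              x$name, x$rho, x$cp, x$k))
  invisible(x)
}

#' Built-in thermophysical property table
#'
#' Properties of blood and of the nanoparticle species commonly used in
#' hyperthermia studies: gold, single- and multi-wall carbon nanotubes and
#' magnetite.
#'
#' @return A data frame with columns `name`, `rho` (kg/m^3), `cp` (J/(kg K))
#'   and `k` (W/(m K)).
#' @export
#' @examples
#' material_db()
material_db <- function() {
  data.frame(
    name = c("blood", "gold", "swcnt", "mwcnt", "fe3o4"),
    rho  = c(1050, 19300, 2600, 1600, 5180),
    cp   = c(3617, 129, 425, 796, 670),
    k    = c(0.52, 318, 6600, 3000, 9.7),
    stringsAsFactors = FALSE
  )
}

#' Look up a material by name
#'
#' @param name Material name; matched case-insensitively against the table.
#' @param db Property table, by default [material_db()].  User-supplied
#'   tables must carry the same columns.
#'
#' @return A [material_props()] object.
#' @export
#' @examples
#' get_material("gold")
get_material <- function(name, db = material_db()) {
  stopifnot(is.character(name), length(name) == 1L)
  i <- match(tolower(name), tolower(db$name))
  if (is.na(i)) {
    stop(sprintf("unknown material '%s'; available: %s", name,
                 paste(db$name, collapse = ", ")), call. = FALSE)
  }
  material_props(db$name[i], db$rho[i], db$cp[i], db$k[i])
}

# Hamilton-Crosser shape factors m = 3/psi from standard sphericities.
# The ordering platelet > cylinder > blade > brick printed in the reference
# enhancement tables is not reproducible from any single standard m-table;
# these defaults are documented, overridable, and never asserted against
# published Nusselt values.
.shape_defaults <- data.frame(
  name = c("sphere", "brick", "cylinder", "platelet", "blade"),
  m    = c(3.0, 3.7, 4.9, 5.7, 8.6),
  stringsAsFactors = FALSE
)
.shape_defaults$psi <- 3 / .shape_defaults$m

#' Particle shape factor table
#'
#' @return Data frame with columns `name`, `m` (empirical Hamilton-Crosser
#'   shape factor) and `psi` (sphericity, `3/m`).
#' @export
shape_db <- function() .shape_defaults

#' Particle shape with Hamilton-Crosser shape factor
#'
#' The empirical shape factor is tied to sphericity by `m = 3/psi`, so the
#' sphere (`psi = 1`) has `m = 3` and less spherical particles have larger
#' `m`.  Either `m` or `psi` may be overridden; the other is derived.
#'
#' @param name One of `"sphere"`, `"brick"`, `"cylinder"`, `"platelet"`,
#'   `"blade"`, or any name when `m` or `psi` is supplied explicitly.
#' @param m Shape factor override (>= 3).
#' @param psi Sphericity override in (0, 1].
#'
#' @return An object of class `particle_shape` with fields `name`, `m`, `psi`.
#' @export
#' @examples
#' particle_shape("platelet")
#' particle_shape("custom", psi = 0.7)
particle_shape <- function(name, m = NULL, psi = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.null(m) && is.null(psi)) {
    i <- match(tolower(name), .shape_defaults$name)
    if (is.na(i)) {
      stop(sprintf("unknown shape '%s'; available: %s (or supply m/psi)", name,
                   paste(.shape_defaults$name, collapse = ", ")), call. = FALSE)
    }
    m <- .shape_defaults$m[i]
    psi <- .shape_defaults$psi[i]
  } else if (is.null(m)) {
    if (!is.numeric(psi) || length(psi) != 1L || psi <= 0 || psi > 1) {
      stop("'psi' must be a scalar in (0, 1]", call. = FALSE)
    }
    m <- 3 / psi
  } else {
    if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 3) {
      stop("'m' must be a scalar >= 3", call. = FALSE)
    }
    if (is.null(psi)) psi <- 3 / m
  }
  structure(list(name = tolower(name), m = m, psi = psi),
            class = "particle_shape")
}

#' @export
print.particle_shape <- function(x, ...) {
  cat(sprintf("<particle_shape> %s: m = %g, psi = %.4g\n", x$name, x$m, x$psi))
  invisible(x)
}

#' Nanofluid mixture of a base fluid and suspended nanoparticles
#'
#' @param base Base-fluid [material_props()] (default blood).
#' @param particle Particle [material_props()] or a species name understood
#'   by [get_material()].
#' @param phi Particle volume fraction.  Physically meaningful dilute
#'   suspensions have `phi` in \[0, 0.1\]; values up to 1 are accepted for
#'   endpoint/identity checks.
#' @param shape A [particle_shape()] or shape name (default `"sphere"`).
#'
#' @return An object of class `nanofluid_mixture`.
#' @export
#' @examples
#' nanofluid_mixture(particle = "gold", phi = 0.04, shape = "platelet")
nanofluid_mixture <- function(base = get_material("blood"), particle, phi,
                              shape = "sphere") {
  if (is.character(particle)) particle <- get_material(particle)
  if (is.character(shape)) shape <- particle_shape(shape)
  stopifnot(inherits(base, "material_props"),
            inherits(particle, "material_props"),
            inherits(shape, "particle_shape"))
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) ||
      phi < 0 || phi > 1) {
    stop("'phi' must be a scalar volume fraction in [0, 1]", call. = FALSE)
  }
  structure(list(base = base, particle = particle, phi = phi, shape = shape),
            class = "nanofluid_mixture")
}

#' @export
print.nanofluid_mixture <- function(x, ...) {
  cat(sprintf("<nanofluid_mixture> %s + %s (%s), phi = %g\n",
              x$base$name, x$particle$name, x$shape$name, x$phi))
  invisible(x)
}

#' Effective density of a nanofluid
#'
#' Volume-weighted mixture rule `(1 - phi) rho_b + phi rho_s`.
#'
#' @param mix A [nanofluid_mixture()].
#' @return Density in kg/m^3.
#' @export
#' @examples
#' mixture_density(nanofluid_mixture(particle = "gold", phi = 0.04))
mixture_density <- function(mix) {
  stopifnot(inherits(mix, "nanofluid_mixture"))
  (1 - mix$phi) * mix$base$rho + mix$phi * mix$particle$rho
}

#' Effective volumetric heat capacity of a nanofluid
#'
#' Volume-weighted mixture rule
#' `(1 - phi) (rho cp)_b + phi (rho cp)_s`.
#'
#' @inheritParams mixture_density
#' @return Volumetric heat capacity in J/(m^3 K).
#' @export
mixture_heat_capacity <- function(mix) {
  stopifnot(inherits(mix, "nanofluid_mixture"))
  (1 - mix$phi) * mix$base$rho * mix$base$cp +
    mix$phi * mix$particle$rho * mix$particle$cp
}

#' Hamilton-Crosser effective thermal conductivity
#'
#' Effective conductivity of a dilute particle suspension with empirical
#' shape factor `m`:
#' `k_nf = k_b (k_s + (m-1) k_b - phi (m-1)(k_b - k_s)) /
#'         (k_s + (m-1) k_b + phi (k_b - k_s))`.
#' Reduces to the base-fluid conductivity at `phi = 0` and for
#' `k_s = k_b`, and is increasing in both `phi` and `m` when `k_s > k_b`.
#'
#' @inheritParams mixture_density
#' @return Conductivity in W/(m K).
#' @export
#' @examples
#' hamilton_crosser_k(nanofluid_mixture(particle = "gold", phi = 0.04))
hamilton_crosser_k <- function(mix) {
  stopifnot(inherits(mix, "nanofluid_mixture"))
  kb <- mix$base$k
  ks <- mix$particle$k
  m <- mix$shape$m
  phi <- mix$phi
  den <- ks + (m - 1) * kb + phi * (kb - ks)
  if (abs(den) < 1e-300) {
    stop("degenerate Hamilton-Crosser denominator (k_s + (m-1) k_b + phi (k_b - k_s) = 0)",
         call. = FALSE)
  }
  kb * (ks + (m - 1) * kb - phi * (m - 1) * (kb - ks)) / den
}

#' All effective properties and property ratios of a mixture
#'
#' @inheritParams mixture_density
#' @return A list with `rho` (kg/m^3), `rho_cp` (J/(m^3 K)), `k` (W/(m K)),
#'   and the dimensionless ratios to the base fluid `r_cp` and `r_k` that
#'   enter the dimensionless bioheat coefficients.
#' @export
mixture_properties <- function(mix) {
  stopifnot(inherits(mix, "nanofluid_mixture"))
  rho_cp <- mixture_heat_capacity(mix)
  k <- hamilton_crosser_k(mix)
  list(rho = mixture_density(mix),
       rho_cp = rho_cp,
       k = k,
       r_cp = rho_cp / (mix$base$rho * mix$base$cp),
       r_k = k / mix$base$k)
}
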