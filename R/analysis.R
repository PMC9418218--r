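# Post-processing: wall Nusselt numbers, heat-transfer-enhancement tables
# and parameter sweeps of the temperature field.

# Published wall Nusselt numbers and enhancement percentages for the
# species comparison (platelet shape) and the shape comparison (gold
# particles), as functions of the volume fraction.  These printed values
# are inputs to the enhancement arithmetic; the package does not claim to
# reproduce the absolute Nu column (the parameter set behind the 20.88
# baseline is not recoverable).
.published_species <- data.frame(
  particle = rep(c("gold", "swcnt", "mwcnt", "fe3o4"), each = 5),
  phi = rep(c(0, 0.01, 0.02, 0.03, 0.04), times = 4),
  Nu = c(20.88, 21.731, 22.585, 23.443, 24.307,
         20.88, 21.596, 22.317, 23.043, 23.776,
         20.88, 21.585, 22.294, 23.009, 23.730,
         20.88, 21.307, 21.736, 22.167, 22.602),
  pct = c(0, 4.075, 8.165, 12.274, 16.412,
          0, 3.429, 6.882, 10.359, 13.869,
          0, 3.376, 6.772, 10.196, 13.649,
          0, 2.045, 4.099, 6.163, 8.247),
  stringsAsFactors = FALSE
)
.published_shapes <- data.frame(
  shape = rep(c("platelet", "cylinder", "blade", "brick"), each = 5),
  phi = rep(c(0, 0.01, 0.02, 0.03, 0.04), times = 4),
  Nu = c(20.88, 21.731, 22.585, 23.443, 24.307,
         20.88, 21.499, 22.123, 22.752, 23.387,
         20.88, 21.415, 21.954, 22.498, 23.047,
         20.88, 21.311, 21.745, 22.185, 22.629),
  pct = c(0, 4.075, 8.165, 12.274, 16.412,
          0, 2.964, 5.953, 8.965, 12.006,
          0, 2.562, 5.143, 7.749, 10.378,
          0, 2.064, 4.142, 6.250, 8.376),
  stringsAsFactors = FALSE
)

#' Published Nusselt-number comparison tables
#'
#' The reference wall Nusselt numbers (`Nu`) and their printed enhancement
#' percentages (`pct`) against the particle-free baseline, for the
#' nanoparticle-species comparison and the particle-shape comparison.
#'
#' @param which `"species"` or `"shapes"`.
#' @return A data frame with columns `particle`/`shape`, `phi`, `Nu`, `pct`.
#' @export
#' @examples
#' published_nusselt("species")
published_nusselt <- function(which = c("species", "shapes")) {
  which <- match.arg(which)
  if (which == "species") .published_species else .published_shapes
}

#' Percentage heat-transfer enhancement
#'
#' `100 (Nu - Nu_base) / Nu_base`, truncated (toward zero) at `digits`
#' decimals.  Truncation, not rounding, is the printing convention of the
#' reference tables: it reproduces every published percentage cell from the
#' published Nusselt cells, which rounding does not.  A round-to-9-decimals
#' guard precedes truncation so that values that are exact in decimal
#' arithmetic (e.g. 6.25) are not knocked down by binary representation.
#'
#' @param nu_base Baseline Nusselt number (non-zero).
#' @param nu Nusselt number(s) to compare (vectorised).
#' @param digits Decimals kept after truncation (default 3).
#'
#' @return Numeric vector of truncated percentages.
#' @export
#' @examples
#' enhancement_percent(20.88, 24.307)  # 16.412
enhancement_percent <- function(nu_base, nu, digits = 3) {
  stopifnot(is.numeric(nu_base), length(nu_base) == 1L, is.numeric(nu))
  if (nu_base == 0) stop("zero baseline Nusselt number", call. = FALSE)
  pct <- 100 * (nu - nu_base) / nu_base
  trunc(round(pct, 9) * 10^digits) / 10^digits
}

#' Wall Nusselt number of the bioheat model
#'
#' `Nu = -(k_nf / k_b)(1 + 4R/3) d theta / dy` evaluated at the configured
#' wall and time, with the temperature gradient obtained by numerically
#' inverting the analytic transform-domain derivative
#' ([laplace_solution_dy()]) — no finite differencing at the boundary.
#'
#' The reference tables' absolute Nu scale is not reproducible (their
#' parameter set is unpublished), so this definition is the package's own;
#' only relative enhancements should be compared across configurations.
#'
#' @param params A [therapy_params()].
#' @param mix Optional [nanofluid_mixture()] (`NULL` = pure blood).
#' @param coeff Optional [pde_coefficients()] override; defaults to
#'   [assemble_coefficients()] of `params` and `mix`.
#' @param t_eval Evaluation time (> 0, default 1).
#' @param wall Wall position, 0 (default) or 1.
#' @param settings An [inversion_settings()].
#'
#' @return The Nusselt number (scalar).
#' @export
nusselt <- function(params, mix = NULL, coeff = NULL, t_eval = 1, wall = 0,
                    settings = inversion_settings()) {
  stopifnot(inherits(params, "therapy_params"), t_eval > 0,
            wall %in% c(0, 1))
  if (is.null(coeff)) coeff <- assemble_coefficients(params, mix)
  r_k <- if (is.null(mix)) 1 else mixture_properties(mix)$r_k
  G <- function(q) laplace_solution_dy(wall, q, coeff, params)
  grad <- switch(settings$method,
                 durbin = suppressWarnings(
                   durbin_invert(G, t_eval, settings, t_max = t_eval)),
                 zakian = zakian_invert(G, t_eval, settings))
  -r_k * (1 + 4 * params$R / 3) * grad
}

#' Model-computed Nusselt/enhancement table
#'
#' Computes the wall Nusselt number over a volume-fraction grid for one or
#' several particle species (at a fixed shape) or shapes (at a fixed
#' species), together with the enhancement percentage against the phi = 0
#' baseline.
#'
#' @param params A [therapy_params()].
#' @param phis Volume fractions (first entry should be 0 for the baseline;
#'   if absent, 0 is prepended).
#' @param particles Character vector of species names.
#' @param shapes Character vector of shape names (recycled against
#'   `particles` if length 1, and vice versa).
#' @param t_eval,wall,settings Passed to [nusselt()].
#'
#' @return A data frame of `NusseltRecord` rows: `particle`, `shape`, `phi`,
#'   `Nu`, `enhancement_pct`.
#' @export
nusselt_table <- function(params, phis = c(0, 0.01, 0.02, 0.03, 0.04),
                          particles = "gold", shapes = "platelet",
                          t_eval = 1, wall = 0,
                          settings = inversion_settings()) {
  if (!0 %in% phis) phis <- c(0, phis)
  combos <- data.frame(particle = particles, shape = shapes,
                       stringsAsFactors = FALSE)  # recycles
  out <- list()
  for (i in seq_len(nrow(combos))) {
    nu <- vapply(phis, function(phi) {
      mix <- if (phi > 0) {
        nanofluid_mixture(particle = combos$particle[i], phi = phi,
                          shape = combos$shape[i])
      } else NULL
      nusselt(params, mix, t_eval = t_eval, wall = wall, settings = settings)
    }, numeric(1))
    nu0 <- nu[phis == 0][1]
    out[[i]] <- data.frame(particle = combos$particle[i],
                           shape = combos$shape[i], phi = phis, Nu = nu,
                           enhancement_pct = enhancement_percent(nu0, nu),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Recompute enhancement percentages of a published table
#'
#' Applies [enhancement_percent()] to the `Nu` column of a
#' [published_nusselt()]-shaped table, per group, against its `phi = 0`
#' baseline.
#'
#' @param tab Data frame with columns `phi`, `Nu` and one grouping column
#'   (`particle` or `shape`).
#' @return `tab` with an extra column `pct_recomputed`.
#' @export
recompute_enhancement <- function(tab) {
  grp_col <- intersect(c("particle", "shape"), names(tab))[1]
  stopifnot(!is.na(grp_col), all(c("phi", "Nu") %in% names(tab)))
  parts <- split(tab, tab[[grp_col]])
  parts <- lapply(parts, function(d) {
    nu0 <- d$Nu[d$phi == 0][1]
    d$pct_recomputed <- enhancement_percent(nu0, d$Nu)
    d
  })
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  res[order(match(res[[grp_col]], unique(tab[[grp_col]])), res$phi), ]
}

#' Temperature-profile parameter sweep
#'
#' Re-solves the model for each value of one swept parameter, all other
#' inputs held at the base configuration, and returns tidy long-format
#' records.  Sweepable parameters: `phi`, `shape`, `particle`, `alpha`,
#' `t`, `R`, `lambda`, `beta`, `gamma`.
#'
#' @param param Parameter name (string).
#' @param values Vector of values (numeric, or character for
#'   `shape`/`particle`).
#' @param config Run configuration (see [default_config()]); resolved with
#'   defaults if partial.
#'
#' @return Data frame with columns `param`, `value`, `y`, `t`, `theta`.
#' @export
#' @examples
#' \donttest{
#' sw <- sweep_parameter("R", c(0, 0.5, 1),
#'                       default_config(inversion = list(durbin_terms = 4000)))
#' }
sweep_parameter <- function(param, values, config = default_config()) {
  ok <- c("phi", "shape", "particle", "alpha", "t", "R", "lambda", "beta",
          "gamma")
  if (!param %in% ok) {
    stop(sprintf("unknown sweep parameter '%s'; one of: %s", param,
                 paste(ok, collapse = ", ")), call. = FALSE)
  }
  config <- resolve_config(config)
  out <- list()
  for (v in values) {
    cfg <- config
    if (param %in% c("alpha", "R", "lambda", "beta", "gamma")) {
      cfg$params[[param]] <- as.numeric(v)
    } else if (param %in% c("phi", "shape", "particle")) {
      cfg$mixture[[param]] <- if (param == "phi") as.numeric(v) else
        as.character(v)
    } else if (param == "t") {
      cfg$grids$t_values <- as.numeric(v)
    }
    fld <- simulate_field(cfg)
    d <- as.data.frame(fld)
    d$method <- NULL
    d <- cbind(param = param, value = if (is.numeric(v)) v else
      as.character(v), d)
    out[[length(out) + 1L]] <- d
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
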