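test_that("Zakian inversion reproduces analytic pairs", {
  s <- inversion_settings()
  expect_equal(zakian_invert(function(q) 1 / q, 1.7, s), 1,
               tolerance = 1e-6)
  expect_equal(zakian_invert(function(q) 1 / q^2, 2, s), 2,
               tolerance = 1e-5)
  expect_equal(zakian_invert(function(q) 1 / (q + 1), 1, s), exp(-1),
               tolerance = 1e-5)
  expect_error(zakian_invert(function(q) 1 / q, -1, s), "t > 0")
})

test_that("Durbin inversion reproduces analytic pairs", {
  s <- quick_settings()
  t <- c(0.3, 1, 1.9)
  expect_equal(durbin_invert(function(q) 1 / q, t, s), rep(1, 3),
               tolerance = 1e-4)
  # fractional pair 1/q^(alpha+1) <-> t^alpha / Gamma(alpha+1), alpha = 0.5
  expect_equal(suppressWarnings(
    durbin_invert(function(q) 1 / q^1.5, 1, s, t_max = 2)),
    1 / gamma(1.5), tolerance = 1e-4)
  # oscillatory pair
  expect_equal(suppressWarnings(
    durbin_invert(function(q) 1 / (q^2 + 1), pi / 2, s, t_max = 2)),
    1, tolerance = 1e-4)
  expect_error(durbin_invert(function(q) 1 / q, c(1, 3), s, t_max = 2),
               "t_max")
})

test_that("Durbin truncation error decreases as the term count grows", {
  # raw partial sums (initial-value subtraction off) expose the 1/k tail
  t <- c(0.3, 1, 1.9)
  for (p in list(list(F = function(q) 1 / q, f = rep(1, 3)),
                 list(F = function(q) 1 / (q + 1), f = exp(-t)))) {
    errs <- vapply(c(250, 500, 1000, 2000), function(N) {
      s <- inversion_settings(durbin_terms = N, durbin_subtract_f0 = FALSE)
      max(abs(suppressWarnings(durbin_invert(p$F, t, s)) - p$f))
    }, numeric(1))
    # monotone up to noise: each doubling may not increase the error
    expect_true(all(diff(errs) < errs[-length(errs)] * 0.05))
    expect_lt(errs[4], errs[1] / 2)
  }
})

test_that("initial-value subtraction removes the slowly converging tail", {
  s_off <- inversion_settings(durbin_terms = 2000,
                              durbin_subtract_f0 = FALSE)
  s_on <- inversion_settings(durbin_terms = 2000)
  e_off <- max(abs(suppressWarnings(
    durbin_invert(function(q) 1 / (q + 1), 1, s_off, t_max = 2)) - exp(-1)))
  e_on <- max(abs(suppressWarnings(
    durbin_invert(function(q) 1 / (q + 1), 1, s_on, t_max = 2)) - exp(-1)))
  expect_lt(e_on, e_off / 10)
})

test_that("validation suite covers both methods at documented tolerances", {
  suite <- suppressWarnings(inversion_validation_suite(quick_settings(20000)))
  expect_gte(nrow(suite), 6)
  expect_true(any(grepl("Gamma", suite$pair)))  # fractional pair present
  expect_true(all(suite$err_durbin <= 1e-4))
  expect_true(all(suite$err_zakian[suite$smooth] <= 1e-5))
  # branch-cut pairs: Zakian documented envelope is ~1e-2
  expect_true(all(suite$err_zakian <= 1e-2))
})

test_that("settings are validated", {
  expect_error(inversion_settings(durbin_terms = 5), "durbin_terms")
  bad <- zakian_constants()
  bad$alpha[1] <- -1 + 1i
  expect_error(inversion_settings(zakian_constants = bad), "positive real")
})

test_that("field inversion writes the initial condition and boundaries", {
  p <- therapy_params(alpha = 0.8)
  co <- assemble_coefficients(p, gold_mix(0.02))
  fld <- laplace_field(co, p)
  tf <- suppressWarnings(
    invert_field(fld, c(0, 0.5, 1), c(0, 0.5, 1), quick_settings()))
  expect_s3_class(tf, "temperature_field")
  expect_equal(tf$values[, 1], rep(p$theta_init, 3))  # t = 0 column
  expect_equal(tf$values[1, -1], rep(p$theta_left, 2), tolerance = 1e-6)
  expect_equal(tf$values[3, -1], rep(p$theta_right, 2), tolerance = 1e-6)
  expect_match(tf$method, "durbin")
  d <- as.data.frame(tf)
  expect_named(d, c("y", "t", "theta", "method"))
  expect_equal(nrow(d), 9)
})

test_that("Durbin and Zakian agree on the bioheat solution at early times", {
  # Zakian's rational approximation degrades once transients have decayed,
  # so the cross-check window is t in [0.05, 0.5]; Durbin (the accurate
  # reference, cf. the finite-difference oracle) anchors the comparison.
  p8 <- therapy_params(alpha = 0.7)
  co <- assemble_coefficients(p8, gold_mix(0.02))
  ts <- c(0.05, 0.1, 0.3, 0.5)
  for (al in c(0.7, 1)) {
    p <- therapy_params(alpha = al)
    for (y in c(0.25, 0.5, 0.75)) {
      Fy <- function(q) laplace_solution(y, q, co, p)
      dv <- suppressWarnings(durbin_invert(Fy, ts, inversion_settings(),
                                           t_max = max(ts)))
      zv <- zakian_invert(Fy, ts, inversion_settings())
      expect_lt(max(abs(dv - zv)), 0.06)
    }
  }
})
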