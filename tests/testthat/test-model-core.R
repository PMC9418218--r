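test_that("coefficient assembly matches the adopted property-ratio reading", {
  # no particles, no radiation: unit diffusivity
  co <- assemble_coefficients(therapy_params(R = 0))
  expect_equal(co$D, 1)
  # lambda = beta = 0 collapses c and s to gamma
  co2 <- assemble_coefficients(therapy_params(gamma = 0.7, lambda = 0,
                                              beta = 0))
  expect_equal(co2$c, 0.7)
  expect_equal(co2$s, 0.7)
  # hand-evaluated ratios for a gold-platelet mixture
  p <- therapy_params(R = 0.5, gamma = 1, lambda = 1, beta = 1)
  co3 <- assemble_coefficients(p, gold_mix(0.04))
  r_cp <- (0.96 * 1050 * 3617 + 0.04 * 19300 * 129) / (1050 * 3617)
  r_k <- hc_formula(0.52, 318, 0.04, 5.7) / 0.52
  expect_equal(co3$D, r_k / r_cp * (1 + 2 / 3))
  expect_equal(co3$c, 1 - 1 / r_cp)
  expect_equal(co3$s, 1 + 1 / r_cp)
})

test_that("particular transform solution evaluates and cancels correctly", {
  p <- therapy_params(alpha = 0.5)
  co <- pde_coefficients(1, 1, 2)
  expect_equal(laplace_particular(1 + 0i, co, p),
               (37 * 1 + 2) / (1 * (1 + 1)) + 0i)  # 19.5
  # s = c * theta_init: equilibrium cancellation to theta_init/q for all q
  pe <- therapy_params(alpha = 0.73, theta_init = 5, theta_left = 5,
                       theta_right = 5)
  coe <- pde_coefficients(1.3, 2, 10)
  q <- complex(real = seq(0.1, 50, length.out = 20),
               imaginary = seq(-40, 40, length.out = 20))
  expect_equal(laplace_particular(q, coe, pe), 5 / q, tolerance = 1e-14)
  expect_error(laplace_particular(-1 + 0i, co, p), "Re\\(q\\)")
})

test_that("transform-domain boundary identities hold to machine precision", {
  p <- therapy_params(alpha = 0.8)
  co <- assemble_coefficients(p, gold_mix(0.02))
  # contour-like grid of frequencies
  q <- complex(real = 1.5, imaginary = seq(0, 400, length.out = 81))
  q[1] <- 1.5 + 0i
  for (al in c(0.6, 1)) {
    pa <- therapy_params(alpha = al)
    expect_lt(max(Mod(laplace_solution(0, q, co, pa) - pa$theta_left / q) /
                    Mod(pa$theta_left / q)), 1e-12)
    expect_lt(max(Mod(laplace_solution(1, q, co, pa) - pa$theta_right / q) /
                    Mod(pa$theta_right / q)), 1e-12)
  }
})

test_that("equilibrium transform is flat in y", {
  pe <- therapy_params(gamma = 1, lambda = 0, beta = 0, theta_init = 1,
                       theta_left = 1, theta_right = 1)
  coe <- assemble_coefficients(pe)  # c = s = 1, so s = c * theta_init
  q <- complex(real = 2, imaginary = c(0, 1, 10, 100))
  for (y in c(0.2, 0.5, 0.9)) {
    expect_equal(laplace_solution(y, q, coe, pe), 1 / q, tolerance = 1e-13)
  }
})

test_that("transform solution satisfies the transform-domain ODE", {
  # D F'' - (q^alpha + c) F + theta_init q^(alpha-1) + s/q = 0;
  # discrete residual with a central second difference vanishes as h -> 0
  p <- therapy_params(alpha = 0.8)
  co <- assemble_coefficients(p, gold_mix(0.02))
  q <- 2 + 3i
  qa <- q^p$alpha
  res <- vapply(c(1e-2, 5e-3, 2.5e-3), function(h) {
    y <- 0.4
    F0 <- laplace_solution(y, q, co, p)
    d2 <- (laplace_solution(y + h, q, co, p) - 2 * F0 +
             laplace_solution(y - h, q, co, p)) / h^2
    Mod(co$D * d2 - (qa + co$c) * F0 + p$theta_init * q^(p$alpha - 1) +
          co$s / q)
  }, numeric(1))
  expect_lt(res[3], 1e-4)
  # second-order decay (ratio ~ 4 per halving, generous band)
  expect_gt(res[1] / res[2], 3)
  expect_gt(res[2] / res[3], 3)
})

test_that("derivative transform is consistent with a finite difference", {
  p <- therapy_params(alpha = 0.7)
  co <- assemble_coefficients(p)
  q <- complex(real = 1.5, imaginary = c(0.5, 5, 50))
  h <- 1e-6
  for (y in c(0.3, 0.7)) {
    fd <- (laplace_solution(y + h, q, co, p) -
             laplace_solution(y - h, q, co, p)) / (2 * h)
    expect_equal(laplace_solution_dy(y, q, co, p), fd, tolerance = 1e-6)
  }
})

test_that("overflow-safe evaluation survives extreme frequencies", {
  p <- therapy_params(alpha = 1)
  co <- assemble_coefficients(p)
  q <- 1e6 + 1e6i  # |mu| ~ 1000: naive cosh/sinh would overflow
  v <- laplace_solution(0.5, q, co, p)
  expect_true(is.finite(Re(v)) && is.finite(Im(v)))
  expect_equal(laplace_solution(0, q, co, p), p$theta_left / q)
})

test_that("steady state interpolates boundaries and known closed forms", {
  p01 <- therapy_params(boundary_mode = "physical")
  # D=1, c=1, s=0: sinh(y)/sinh(1)
  co <- pde_coefficients(1, 1, 0)
  expect_equal(steady_state(c(0, 1), co, p01), c(0, 1))
  expect_equal(steady_state(0.5, co, p01), 0.44340944, tolerance = 1e-7)
  expect_equal(steady_state(0.5, co, p01), sinh(0.5) / sinh(1))
  # constant equilibrium s/c
  pc <- therapy_params(theta_left = 3, theta_right = 3)
  expect_equal(steady_state(seq(0, 1, 0.1), pde_coefficients(2, 1, 3), pc),
               rep(3, 11))
  # c = 0: quadratic profile y + s y(1-y)/(2D)
  co0 <- pde_coefficients(2, 0, 4)
  y <- seq(0, 1, 0.25)
  expect_equal(steady_state(y, co0, p01), y + y * (1 - y))
  # c < 0 trigonometric branch still pins the boundaries
  con <- pde_coefficients(1, -2, 0.5)
  expect_equal(steady_state(c(0, 1), con, p01), c(0, 1))
})

test_that("printed and physical boundary modes differ by the affine map", {
  # identical (D, c_eff...) dynamics up to theta -> (theta - 37)/8 requires
  # matching sources; check the pure-diffusion case lambda = beta = gamma = 0
  pp <- therapy_params(gamma = 0, lambda = 0, beta = 0)
  ph <- therapy_params(gamma = 0, lambda = 0, beta = 0,
                       boundary_mode = "physical")
  co <- assemble_coefficients(pp)
  q <- complex(real = 2, imaginary = c(0, 3, 30))
  for (y in c(0.25, 0.75)) {
    a <- laplace_solution(y, q, co, pp)
    b <- laplace_solution(y, q, assemble_coefficients(ph), ph)
    expect_equal((a - 37 / q) / 8, b, tolerance = 1e-12)
  }
})

test_that("parameter validation enforces the model's ranges", {
  expect_error(therapy_params(alpha = 0), "alpha")
  expect_error(therapy_params(alpha = 1.2), "alpha")
  expect_error(therapy_params(R = -0.5), "R")
  expect_error(pde_coefficients(-1, 0, 0), "positive")
})
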