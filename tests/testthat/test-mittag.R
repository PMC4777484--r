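test_that("Mittag-Leffler identities hold to high accuracy", {
  # E_eta(0) = 1 for any order
  for (eta in c(0.2, 0.5, 0.77, 1)) expect_identical(mittagLeffler(eta, 0), 1)
  # E_1(z) = exp(z)
  z <- seq(-50, 0, by = 2.5)
  expect_equal(mittagLeffler(1, z), exp(z), tolerance = 1e-14)
  # E_1/2(-x) = exp(x^2) erfc(x) = erfcx(x), across both evaluation routes
  x <- c(0.1, 0.5, 1, 1.9, 2.5, 5, 10, 20)   # pracma::erfcx overflows beyond
  expect_equal(mittagLeffler(0.5, -x), pracma::erfcx(x), tolerance = 1e-10)
})

test_that("series and spectral-integral routes agree across the handover", {
  # arguments straddling the series/integral boundary, all orders
  for (eta in c(0.25, 0.4, 0.6, 0.85, 0.95)) {
    lim <- frachh:::ml_series_limit(eta)
    x <- lim * c(0.8, 0.99, 1.01, 1.5)
    a <- frachh:::ml_series(eta, -x[x <= lim])
    b <- vapply(x, function(xx) frachh:::ml_integral(eta, xx), numeric(1))
    # the certified series may spend up to ~4 digits on cancellation
    expect_equal(a, b[x <= lim], tolerance = 1e-7)
  }
})

test_that("relaxation kernel is positive, decreasing, and asymptotically
           algebraic", {
  x <- 10^seq(-2, 3, by = 0.25)
  for (eta in c(0.3, 0.7)) {
    E <- mittagLeffler(eta, -x)
    expect_true(all(E > 0))
    expect_true(all(diff(E) < 0))
  }
  # far tail: E_eta(-x) ~ 1/(x Gamma(1-eta))
  for (eta in c(0.3, 0.6)) {
    expect_equal(mittagLeffler(eta, -1e4), 1 / (1e4 * gamma(1 - eta)),
                 tolerance = 1e-3)
  }
})

test_that("dense-grid (spline) evaluation matches pointwise evaluation", {
  t <- seq(0.001, 90, by = 0.001)
  x0 <- hhSteadyState(0)[["n"]]
  dense <- analyticGateResponse(30, 0.4, x0, t, "n")
  pick <- seq(1, length(t), by = 7000)
  sparse <- vapply(t[pick], function(tt)
    analyticGateResponse(30, 0.4, x0, tt, "n"), numeric(1))
  expect_equal(dense[pick], sparse, tolerance = 1e-8)
})

test_that("analytic gate relaxation has the right endpoints and classic limit", {
  x0 <- 0.1
  expect_equal(analyticGateResponse(30, 0.5, x0, 0, "n"), x0,
               tolerance = 1e-12)
  # eta = 1: classic exponential relaxation
  tn <- hhTau(-65)[["n"]]
  ninf <- hhSteadyState(-65)[["n"]]
  expect_equal(analyticGateResponse(-65, 1, 0, tn, "n"), ninf * (1 - exp(-1)),
               tolerance = 1e-12)
  # long-time limit is the classic steady state for any eta
  expect_equal(analyticGateResponse(30, 0.5, x0, 1e7, "n"),
               hhSteadyState(30)[["n"]], tolerance = 1e-3)
  expect_error(mittagLeffler(0, -1), "eta")
})

test_that("evaluation stays accurate as the order approaches 1", {
  # reference values from a 30-digit arbitrary-precision summation of the
  # defining series (where double-precision summation is hopeless)
  ref <- rbind(c(0.0606064044787216, 0.00393827782618126, 0.000634739708096874),
               c(0.0534518675061996, 0.00134786380608321, 0.000209576499006008),
               c(0.0501561991948912, 0.000175848345908712, 2.08629724638406e-5))
  etas <- c(0.97, 0.99, 0.999)
  xs <- c(3, 10, 50)
  for (i in seq_along(etas))
    expect_equal(mittagLeffler(etas[i], -xs), unname(ref[i, ]),
                 tolerance = 1e-10)
})
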