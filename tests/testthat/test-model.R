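theta <- defaultParameters("epithelial")

test_that("the input signal is 1 before the delay, I at the delay, 1 at infinity", {
  expect_equal(inputSignal(c(-10, 0, 0.99), I = 5.3, tau = 1, d = 0.1),
               c(1, 1, 1))
  expect_equal(inputSignal(1, I = 5.3, tau = 1, d = 0.1), 5.3)
  expect_equal(inputSignal(1e7, I = 5.3, tau = 1, d = 0.1), 1, tolerance = 1e-12)
  # decay halves the excess every log(2)/d minutes
  expect_equal(inputSignal(1 + log(2) / 0.1, 5.3, 1, 0.1), 1 + 4.3 / 2)
})

test_that("unmeasured steady state matches the linear-case closed form", {
  v <- parameterValues(theta)
  ss <- unmeasuredSteadyState(theta)
  expect_equal(ss[["xP0"]], (v[["kP"]] / v[["gammaP"]])^(1 / v[["hP"]]))
  # hR = 1 closed form: xR0 = a RT / (gammaR + a), a = kR xP0^gc1
  a <- v[["kR"]] * ss[["xP0"]]^v[["gc1"]]
  expect_equal(ss[["xR0"]], a * v[["RT"]] / (v[["gammaR"]] + a),
               tolerance = 1e-10)
  # defining-equation residual
  resid <- a * (v[["RT"]] - ss[["xR0"]]) - v[["gammaR"]] * ss[["xR0"]]^v[["hR"]]
  expect_lt(abs(resid), 1e-10 * a * v[["RT"]])
  # monotonicity in kP
  up <- theta
  up["kP"] <- 2 * up["kP"]
  expect_gt(unmeasuredSteadyState(up)[["xP0"]], ss[["xP0"]])
})

test_that("the rate closure makes every baseline an exact steady state", {
  cells <- generateCellPopulation(smallConfig(n = 25), seed = 7)
  cells <- deriveCellRates(theta, cells)
  g <- cellRates(cells)
  expect_true(all(g > 0))
  # right-hand side of each measured ODE vanishes at baseline, u = 1
  v <- parameterValues(theta)
  ss <- unmeasuredSteadyState(theta)
  T <- cellTotals(cells)
  x0 <- cellBaseline(cells)
  rhs <- cbind(
    v[["k1"]] * ss[["xR0"]]^v[["g1"]] * (T[, 1] - x0[, 1]) - g[, 1] * x0[, 1]^v[["h1"]],
    v[["k2"]] * x0[, 1]^v[["g2"]] * (T[, 2] - x0[, 2]) - g[, 2] * x0[, 2]^v[["h2"]],
    v[["k3"]] * x0[, 2]^v[["g3"]] * (T[, 3] - x0[, 3]) - g[, 3] * x0[, 3]^v[["h3"]],
    v[["k4"]] * ss[["xP0"]]^v[["g4"]] * (T[, 4] - x0[, 4]) - g[, 4] * x0[, 4]^v[["h4"]],
    (v[["k5"]] * x0[, 4]^v[["g5"]] + v[["k12"]] * x0[, 3]^v[["g12"]]) *
      (T[, 5] - x0[, 5]) - g[, 5] * x0[, 5]^v[["h5"]],
    (v[["k6"]] * x0[, 3]^v[["g6"]] + v[["k13"]] * x0[, 4]^v[["g13"]]) *
      (T[, 6] - x0[, 6]) - g[, 6] * x0[, 6]^v[["h6"]])
  expect_lt(max(abs(rhs)), 1e-10)
})

test_that("doubling a baseline rescales the closure per the formula", {
  v <- parameterValues(theta)
  cells <- generateCellPopulation(smallConfig(n = 10), seed = 1)
  base2 <- cellBaseline(cells)
  base2[, "pMEK"] <- 2 * base2[, "pMEK"]
  doubled <- CellPopulation(cellTotals(cells), base2)
  g1 <- cellRates(deriveCellRates(theta, cells))[, "pMEK"]
  g2 <- cellRates(deriveCellRates(theta, doubled))[, "pMEK"]
  m0 <- cellBaseline(cells)[, "pMEK"]
  T1 <- cellTotals(cells)[, "pMEK"]
  # h1 = 1: gamma scales as (T - 2 m0) / (2 m0) relative to (T - m0) / m0
  expect_equal(g2 / g1, ((T1 - 2 * m0) / (2 * m0)) / ((T1 - m0) / m0),
               tolerance = 1e-12)
})

test_that("with baseline inputs every trajectory stays at its baseline", {
  th0 <- theta
  th0["I1"] <- 1
  th0["I2"] <- 1
  cells <- generateCellPopulation(smallConfig(n = 40), seed = 3)
  res <- simulateEnsemble(th0, cells, times = c(0, 5, 20, 50))
  rel <- sweep(res@states, c(1, 2), cellBaseline(cells), "/") - 1
  expect_lt(max(abs(rel)), 5e-5)
})

test_that("an ensemble of one cell equals the single-cell simulation", {
  cells <- generateCellPopulation(smallConfig(n = 12), seed = 5)
  cells <- deriveCellRates(theta, cells)
  full <- simulateEnsemble(theta, cells, times = c(5, 15))
  one <- simulateEnsemble(theta, cells[3], times = c(5, 15))
  expect_equal(one@states[1, , ], full@states[3, , ], tolerance = 1e-12)
})

test_that("phospho stays within (0, total) and relaxes back to baseline", {
  cells <- generateCellPopulation(smallConfig(n = 30), seed = 9)
  res <- simulateEnsemble(theta, cells, times = c(1, 5, 15, 50, 400))
  tot <- cellTotals(cells)
  for (k in seq_along(res@times)) {
    st <- res@states[, , k]
    expect_true(all(st >= 0))
    expect_true(all(st <= tot * (1 + 1e-6)))
  }
  # decaying input: by t = 400 min everything is within 1% of baseline
  rel <- res@states[, , 5] / cellBaseline(cells) - 1
  expect_lt(max(abs(rel)), 0.01)
})

test_that("the solver agrees with an independent stiff integrator", {
  skip_if_not_installed("deSolve")
  v <- parameterValues(theta)
  cells <- generateCellPopulation(smallConfig(n = 10), seed = 2)
  cells <- deriveCellRates(theta, cells)
  ss <- unmeasuredSteadyState(theta)
  times <- c(0, 3, 8, 20, 50)
  res <- simulateEnsemble(theta, cells, times, rtol = 1e-8)
  u <- function(t, I, tau, d) ifelse(t < tau, 1, 1 + (I - 1) * exp(-d * (t - tau)))
  deriv <- function(t, x, p) {
    with(as.list(c(x, v)), {
      u1 <- u(t, I1, tau1, d1)
      u2 <- u(t, I2, tau2, d2)
      list(c(
        kR * u1^gR * XP^gc1 * (RT - XR) - gammaR * XR^hR,
        kP * u2^gP - gammaP * XP^hP,
        k1 * XR^g1 * (p$T[1] - M) - p$g[1] * M^h1,
        k2 * M^g2 * (p$T[2] - E) - p$g[2] * E^h2,
        k3 * E^g3 * (p$T[3] - R) - p$g[3] * R^h3,
        k4 * XP^g4 * (p$T[4] - A) - p$g[4] * A^h4,
        (k5 * A^g5 + k12 * R^g12) * (p$T[5] - G) - p$g[5] * G^h5,
        (k6 * R^g6 + k13 * A^g13) * (p$T[6] - S) - p$g[6] * S^h6))
    })
  }
  for (i in c(1, 6)) {
    p <- list(T = cellTotals(cells)[i, ], g = cellRates(cells)[i, ])
    x0 <- c(ss[["xR0"]], ss[["xP0"]], cellBaseline(cells)[i, ])
    names(x0) <- c("XR", "XP", "M", "E", "R", "A", "G", "S")
    sol <- deSolve::lsoda(x0, times, deriv, p, rtol = 1e-10, atol = 1e-10)
    ref <- t(sol[, c("M", "E", "R", "A", "G", "S")])
    expect_lt(max(abs(res@states[i, , ] - ref) / (abs(ref) + 1e-6)), 1e-4)
  }
})

test_that("halving solver tolerances leaves reported states unchanged to 1e-4", {
  cells <- generateCellPopulation(smallConfig(n = 15), seed = 4)
  cells <- deriveCellRates(theta, cells)
  a <- simulateEnsemble(theta, cells, times = c(5, 20), rtol = 1e-6)
  b <- simulateEnsemble(theta, cells, times = c(5, 20), rtol = 5e-7)
  expect_lt(max(abs(a@states - b@states) / (abs(b@states) + 1e-6)), 1e-4)
})

test_that("extreme kinetic-order perturbations still integrate (stiff fallback)", {
  hard <- theta
  hard["g2"] <- parameterValues(theta)[["g2"]] * 8  # 2^3 on the grid
  cells <- generateCellPopulation(smallConfig(n = 10), seed = 6)
  res <- simulateEnsemble(hard, cells, times = c(5, 50))
  expect_length(res@failed, 0)
  expect_true(all(is.finite(res@states)))
  # near saturation the dense-output interpolant may overshoot the
  # capacity by a whisker; a 1e-3 relative band is the honest contract here
  for (k in 1:2) {
    expect_true(all(res@states[, , k] <= cellTotals(cells) * (1 + 1e-3)))
  }
})
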