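# Surrogate cost surfaces make the contracts exact and fast; the real
# ensemble-cost grids are exercised in the acceptance suite.

quadCost <- function(center, weights) {
  force(center)
  force(weights)
  function(v) 1 + sum(weights * (log2(v) - log2(center))^2)
}

test_that("the sensitivity grid has 45 offsets and an exact zero anchor column", {
  v <- parameterValues(defaultParameters("epithelial"))
  w <- setNames(rep(0.01, 38), names(v))
  costfn <- quadCost(v, w)
  g <- sensitivityGrid(defaultParameters("epithelial"), costfn)
  vals <- sensitivityValues(g)
  expect_equal(dim(vals), c(38, 45))
  expect_equal(length(defaultSensitivityOffsets()), (3 - (-8)) / 0.25 + 1)
  expect_true(all(vals[, "0"] == 0))
  expect_true(all(is.finite(vals)))
  # entry equals the percent increase computed by hand
  vv <- v
  vv[["I1"]] <- v[["I1"]] * 2
  expect_equal(vals["I1", "1"], 100 * (costfn(vv) - costfn(v)) / costfn(v))
})

test_that("a parameter with no cost influence yields a flat zero row", {
  v <- parameterValues(defaultParameters("epithelial"))
  w <- setNames(rep(1, 38), names(v))
  w["tau2"] <- 0  # disconnected parameter
  g <- sensitivityGrid(defaultParameters("epithelial"), quadCost(v, w))
  vals <- sensitivityValues(g)
  expect_true(all(vals["tau2", ] == 0))
  expect_true(all(vals["I1", colnames(vals) != "0"] > 0))
})

test_that("grid entries are percent increases relative to the anchor cost", {
  v <- parameterValues(defaultParameters("epithelial"))
  w <- setNames(rep(0.5, 38), names(v))
  costfn <- quadCost(v, w)
  g <- sensitivityGrid(defaultParameters("epithelial"), costfn)
  vv <- v
  vv[["k1"]] <- v[["k1"]] * 2^-2
  expect_equal(sensitivityValues(g)["k1", "-2"],
               100 * (costfn(vv) - costfn(v)) / costfn(v))
})

test_that("the paired grids share the epithelial anchor values", {
  gt <- groundTruthPresets()
  vE <- parameterValues(gt$theta_epithelial)
  vM <- parameterValues(gt$theta_mesenchymal)
  costE <- quadCost(vE, setNames(rep(0.2, 38), names(vE)))
  costM <- quadCost(vM, setNames(rep(0.2, 38), names(vM)))
  pair <- sensitivityGridPair(gt$theta_epithelial, gt$theta_mesenchymal,
                              costE, costM)
  # epithelial grid: zero column exactly zero
  expect_true(all(sensitivityValues(pair$epithelial)[, "0"] == 0))
  # mesenchymal grid at delta = 0 substitutes the epithelial value: for the
  # differing parameters this costs something
  m0 <- sensitivityValues(pair$mesenchymal)[, "0"]
  expect_gt(m0[["I1"]], 0)
  expect_equal(unname(m0[["k1"]]), 0)
})

test_that("reconciling identical sets is a no-op with zero differences", {
  v <- parameterValues(defaultParameters("epithelial"))
  costfn <- quadCost(v, setNames(rep(1, 38), names(v)))
  res <- reconcileParameters(defaultParameters("epithelial"),
                             defaultParameters("epithelial"),
                             costfn, costfn)
  expect_true(all(reconciledDifferences(res) == 0))
  expect_equal(res@costE, costfn(v))
  expect_equal(nrow(diffReport(res)), 0)
})

test_that("reconciliation merges free parameters and respects certificates", {
  gt <- groundTruthPresets()
  vE <- parameterValues(gt$theta_epithelial)
  vM <- parameterValues(gt$theta_mesenchymal)
  # cost surfaces that pin only the four truly differing parameters
  w <- setNames(rep(0, 38), names(vE))
  w[c("I1", "I2", "h5", "k13")] <- 50
  costE <- quadCost(vE, w)
  costM <- quadCost(vM, w)
  res <- reconcileParameters(gt$theta_epithelial, gt$theta_mesenchymal,
                             costE, costM, slack = 0.01)
  # certificates within the slack
  expect_lte(res@costE, res@boundE)
  expect_lte(res@costM, res@boundM)
  # the pinned parameters stay different, everything else was already equal
  rep <- diffReport(res, tol_log2 = 0.1)
  expect_setequal(rep$parameter, c("I1", "I2", "h5", "k13"))
  expect_equal(rep$class[rep$parameter == "I1"], "input")
  expect_equal(rep$class[rep$parameter == "h5"], "kinetic")
  # differing count never increases
  before <- sum(abs(log2(vE) - log2(vM)) > 1e-12)
  expect_lte(sum(abs(reconciledDifferences(res)) > 1e-12), before)
})

test_that("reconciliation closes mergeable gaps under a permissive cost", {
  gt <- groundTruthPresets()
  vE <- parameterValues(gt$theta_epithelial)
  vM <- parameterValues(gt$theta_mesenchymal)
  # flat cost surfaces: everything can merge
  flat <- function(v) 1
  res <- reconcileParameters(gt$theta_epithelial, gt$theta_mesenchymal,
                             flat, flat)
  expect_true(all(abs(reconciledDifferences(res)) <= 1e-12))
  # audit trail: the L1 objective never increases across accepted merges
  aud <- res@audit
  expect_true(all(aud$merged))
})

test_that("phase-1 merges walk parameters in ascending difference order", {
  gt <- groundTruthPresets()
  res <- reconcileParameters(gt$theta_epithelial, gt$theta_mesenchymal,
                             function(v) 1, function(v) 1)
  aud <- res@audit
  expect_false(is.unsorted(aud$log2diff_before))
})

test_that("infeasible inputs raise an error", {
  expect_error(reconcileParameters(defaultParameters("epithelial"),
                                   defaultParameters("mesenchymal"),
                                   function(v) Inf, function(v) 1),
               "finite")
})

test_that("diffReport tolerances behave as documented", {
  gt <- groundTruthPresets()
  res <- reconcileParameters(gt$theta_epithelial, gt$theta_mesenchymal,
                             function(v) {
                               # forbid any change at all
                               if (!isTRUE(all.equal(
                                 v, parameterValues(gt$theta_epithelial)))) Inf
                               else 1
                             },
                             function(v) {
                               if (!isTRUE(all.equal(
                                 v, parameterValues(gt$theta_mesenchymal)))) Inf
                               else 1
                             },
                             polish_iters = 0)
  d <- reconciledDifferences(res)
  # one parameter differing by > 1 log2 unit with tol 0.1: reported
  expect_true("I2" %in% diffReport(res, 0.1)$parameter)
  # tol 0 lists all non-identical parameters
  expect_equal(nrow(diffReport(res, 0)), sum(abs(d) > 0))
  # report is sorted by descending magnitude
  rep <- diffReport(res, 0)
  expect_false(is.unsorted(rev(abs(rep$log2_difference))))
})
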