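test_that("MMD^2 matches the double-loop kernel-sum oracle", {
  set.seed(1)
  for (trial in 1:25) {
    n <- sample(5:20, 1)
    m <- sample(5:20, 1)
    d <- sample(1:4, 1)
    A <- matrix(rnorm(n * d), n, d)
    B <- matrix(rnorm(m * d, mean = 0.5), m, d)
    s <- runif(1, 0.5, 3)
    expect_equal(mmd2(A, B, s, "biased"), oracleMMD2(A, B, s, TRUE),
                 tolerance = 1e-12)
    expect_equal(mmd2(A, B, s, "unbiased"), oracleMMD2(A, B, s, FALSE),
                 tolerance = 1e-12)
  }
})

test_that("MMD^2 limits: identical samples give 0, separated clouds give 2", {
  set.seed(2)
  A <- matrix(rnorm(60), 20, 3)
  expect_equal(mmd2(A, A, 1, "biased"), 0, tolerance = 1e-12)
  expect_gte(mmd2(A, A, 1, "biased"), 0)
  # tight clouds (width << sigma) separated far beyond the length-scale:
  # self-terms ~1, cross-term ~0, so biased MMD^2 -> 2
  tight <- matrix(rnorm(60, sd = 1e-4), 20, 3)
  expect_equal(mmd2(tight, tight + 1e4, 1, "biased"), 2, tolerance = 1e-6)
  expect_error(mmd2(A, matrix(0, 5, 2), 1), "dimension")
  expect_error(mmd2(A[1, , drop = FALSE], A, 1), "2 points")
})

test_that("the median-heuristic bandwidth behaves as specified", {
  two <- rbind(c(0, 0), c(3, 0))
  expect_equal(medianHeuristicBandwidth(two), 3)
  set.seed(3)
  X <- matrix(rnorm(200), 100, 2)
  expect_equal(medianHeuristicBandwidth(rbind(X, X), cap = 1e5),
               medianHeuristicBandwidth(rbind(X, X), cap = 1e5))
  # capped subsample is deterministic under the seed
  big <- matrix(rnorm(6000), 3000, 2)
  expect_equal(medianHeuristicBandwidth(big, cap = 500, seed = 9),
               medianHeuristicBandwidth(big, cap = 500, seed = 9))
  expect_error(medianHeuristicBandwidth(matrix(1, 5, 2)), "identical")
})

test_that("the ensemble cost weights time points as specified", {
  gt <- groundTruthPresets()
  cfg <- smallConfig(n = 40, noise_cv = 0.05)
  d <- generateTimecourse(gt$theta_epithelial, cfg, time_grid = c(0, 5, 15),
                          seed = 10, n_replicates = 1, control_times = 0)
  cells <- baselineCells(d)
  v <- parameterValues(gt$theta_epithelial)
  full <- makeCostFunction(d, cells)
  only5 <- makeCostFunction(d, cells,
                            costSpec(time_weights = c(1, 0)))
  only15 <- makeCostFunction(d, cells,
                             costSpec(time_weights = c(0, 1)))
  F <- full(v)
  expect_gte(F, 0)
  expect_equal(only5(v) + only15(v), F, tolerance = 1e-10)
  # single-timepoint weight equals that time point's MMD^2 directly
  bw <- attr(full, "bandwidth")
  cd <- SummarizedExperiment::colData(d)
  data5 <- log2(snapshotMatrix(
    d[, cd$condition == "stimulated" & cd$time == 5], measuredSpecies()) + 1)
  sim <- simulateEnsemble(gt$theta_epithelial, cells, times = c(5, 15))
  sim5 <- log2(ensembleStates(sim, 5) + 1)
  expect_equal(only5(v), mmd2(sim5, data5, bw, "biased"), tolerance = 1e-8)
})

test_that("cost at the generating parameters undercuts log2-unit perturbations", {
  gt <- groundTruthPresets()
  cfg <- smallConfig(n = 150)
  d <- generateTimecourse(gt$theta_epithelial, cfg,
                          time_grid = c(0, 3, 8, 15, 30), seed = 12,
                          n_replicates = 2, control_times = 0)
  cells <- baselineCells(d)
  set.seed(1)
  cells <- cells[sample(length(cells), 120)]
  costfn <- makeCostFunction(d, cells)
  v <- parameterValues(gt$theta_epithelial)
  F0 <- costfn(v)
  for (delta in c(-1, 1)) {
    vv <- v
    vv[["I1"]] <- v[["I1"]] * 2^delta
    expect_gt(costfn(vv), F0)
  }
})

test_that("global search honors its selection contract", {
  # cheap surrogate: separable quadratic in log space
  target <- log10(c(a = 2, b = 30))
  costfn <- function(v) sum((log10(v[c("a", "b")]) - target)^2)
  ranges <- list(a = c(0.1, 100), b = c(0.1, 1000))
  gs <- globalSearch(costfn, ranges, n_samples = 400, n_keep = 25, seed = 4)
  expect_length(gs$thetas, 25)
  expect_false(is.unsorted(gs$costs))
  # every survivor beats every discarded draw
  all <- globalSearch(costfn, ranges, n_samples = 400, n_keep = 400, seed = 4)
  expect_equal(gs$costs, all$costs[1:25])
  expect_lte(max(gs$costs), min(all$costs[26:400]))
  # determinism
  gs2 <- globalSearch(costfn, ranges, n_samples = 400, n_keep = 25, seed = 4)
  expect_identical(gs$thetas, gs2$thetas)
  expect_error(globalSearch(function(v) Inf, ranges, 10, 2, 1),
               "revise the ranges")
})

test_that("local refinement converges on a convex surrogate", {
  target <- log10(c(k1 = 0.02, k2 = 5))
  costfn <- function(v) 1 + sum((log10(v[c("k1", "k2")]) - target)^2)
  start <- c(k1 = 0.5, k2 = 0.1)
  fit <- localRefine(costfn, start, round_iters = 200, improve_frac = 1e-6,
                     max_rounds = 20)
  got <- fittedParameters(fit)[c("k1", "k2")]
  expect_equal(log10(got), target, tolerance = 1e-3, ignore_attr = TRUE)
  # trace costs along the accepted path are non-increasing
  expect_true(all(diff(fitTrace(fit)$cost) <= 0))
  # improve_frac = Inf: exactly one simplex round
  one <- localRefine(costfn, start, round_iters = 50, improve_frac = Inf)
  expect_equal(nrow(fitTrace(one)), 2)
})

test_that("localRefine only returns a ParameterSet for full inventories", {
  # with the full 38-parameter template the result is a valid ParameterSet
  v <- parameterValues(defaultParameters("epithelial"))
  costfn <- function(x) sum((log10(x) - log10(v))^2)
  fit <- localRefine(costfn, v * 1.3, round_iters = 30, improve_frac = Inf)
  expect_s4_class(fittedParameters(fit), "ParameterSet")
})
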