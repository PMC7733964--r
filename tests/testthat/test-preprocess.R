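test_that("the dead-cell filter keeps exactly the cells at or below threshold", {
  ex <- rbind(pMEK = c(1, 2, 3), cPARP = c(0, 20, 21))
  s <- toySnapshot(ex)
  out <- filterDead(s)
  expect_equal(ncol(out), 2)
  expect_equal(unname(SummarizedExperiment::assay(out, "exprs")["cPARP", ]),
               c(0, 20))
  # infinite threshold is the identity
  expect_equal(ncol(filterDead(s, threshold = Inf)), 3)
  # all cells dead: empty snapshot plus warning
  expect_warning(empty <- filterDead(s, threshold = -1), "all cells removed")
  expect_equal(ncol(empty), 0)
  # missing channel errors by name
  expect_error(filterDead(s, channel = "cPARP2"), "cPARP2")
})

test_that("phenotype gating retains the right subpopulations", {
  cfgE <- smallConfig("epithelial", n = 400)
  cfgM <- smallConfig("mesenchymal", n = 400)
  popE <- generateCellPopulation(cfgE, seed = 1)
  popM <- generateCellPopulation(cfgM, seed = 2)
  mk <- function(pop, label) {
    toySnapshot(t(cbind(cellBaseline(pop), cellMarkers(pop))))
  }
  sE <- mk(popE)
  sM <- mk(popM)
  gate <- defaultGate("epithelial")
  # well-separated modes: >= 95% of epithelial cells pass their own gate
  expect_gte(ncol(gatePhenotype(sE, gate)), 0.95 * ncol(sE))
  # and <= 5% of a pure mesenchymal population passes the epithelial gate
  expect_lte(ncol(gatePhenotype(sM, gate)), 0.05 * ncol(sM))
  # trivial gate retains everyone
  open <- gateSpec("Ecad", 1e-12, "Vim", Inf)
  expect_equal(ncol(gatePhenotype(sE, open)), ncol(sE))
  # gate label is applied
  lab <- gatePhenotype(sE, gate, label = "epithelial")
  expect_true(all(snapshotPhenotypes(lab) == "epithelial"))
  expect_error(gatePhenotype(sE, gateSpec("nope", 1, "Vim", 1)), "nope")
})

test_that("filtering and gating commute (both are row predicates)", {
  pop <- generateCellPopulation(smallConfig(n = 300, dead_fraction = 0.2),
                                seed = 3)
  s <- toySnapshot(t(cbind(cellBaseline(pop), cellMarkers(pop))))
  gate <- defaultGate("epithelial")
  a <- gatePhenotype(filterDead(s), gate)
  b <- filterDead(gatePhenotype(s, gate))
  expect_identical(SummarizedExperiment::assay(a, "exprs"),
                   SummarizedExperiment::assay(b, "exprs"))
})

test_that("phospho/total scaling enforces the ratio constraint", {
  n <- 200
  set.seed(1)
  tot <- matrix(rlnorm(n * 6, log(100), 0.3), n, 6,
                dimnames = list(NULL, totalChannels()))
  ph <- tot * matrix(runif(n * 6, 0.05, 0.9), n, 6)
  colnames(ph) <- measuredSpecies()
  s <- toySnapshot(t(cbind(ph, tot)))
  # already consistent: factors are all exactly 1
  out <- scalePhosphoToTotal(s)
  expect_equal(unname(out$factors), rep(1, 6))
  # one channel uniformly 2x its total: factor 0.5
  ph2 <- ph
  ph2[, "pMEK"] <- 2 * tot[, "tMEK"]
  s2 <- toySnapshot(t(cbind(ph2, tot)))
  out2 <- scalePhosphoToTotal(s2)
  expect_equal(unname(out2$factors[["pMEK"]]), 0.5, tolerance = 1e-12)
  # postcondition: per-cell ratio <= 1 everywhere
  m <- SummarizedExperiment::assay(out2$data, "exprs")
  for (p in measuredSpecies()) {
    tn <- SummarizedExperiment::rowData(out2$data)[p, "partner"]
    expect_true(all(m[p, ] <= m[tn, ]))
  }
  # idempotence: a second application changes nothing
  out3 <- scalePhosphoToTotal(out2$data)
  expect_true(all(abs(out3$factors - 1) < 1e-12))
  # an all-zero total channel is an error
  tot0 <- tot
  tot0[, "tMEK"] <- 0
  expect_error(scalePhosphoToTotal(toySnapshot(t(cbind(ph, tot0)))),
               "entirely zero")
})

test_that("subsampling allocates proportionally across replicates", {
  d <- toySnapshot(matrix(seq_len(6000), nrow = 1,
                          dimnames = list("pMEK", NULL)),
                   time = 0,
                   replicate = rep(1:3, times = c(1000, 2000, 3000)))
  out <- subsampleAcrossReplicates(d, 600, seed = 1)
  tab <- table(snapshotReplicates(out))
  expect_equal(as.numeric(tab), c(100, 200, 300))
  # determinism
  out2 <- subsampleAcrossReplicates(d, 600, seed = 1)
  expect_identical(SummarizedExperiment::assay(out, "exprs"),
                   SummarizedExperiment::assay(out2, "exprs"))
  # n = everything: identity up to order
  all6k <- subsampleAcrossReplicates(d, 6000, seed = 1)
  expect_equal(ncol(all6k), 6000)
  # n larger than available: take all, warn
  expect_warning(more <- subsampleAcrossReplicates(d, 7000, seed = 1),
                 "taking all")
  expect_equal(ncol(more), 6000)
})

test_that("log transforms apply their closed forms", {
  s <- toySnapshot(matrix(c(0, exp(1) - 1, 3), 1,
                          dimnames = list("pMEK", NULL)))
  l1 <- SummarizedExperiment::assay(logTransform(s, "log1p"), "exprs")
  expect_equal(unname(l1[1, ]), c(0, 1, log1p(3)))
  l2 <- SummarizedExperiment::assay(logTransform(s, "log2"), "exprs")
  expect_equal(unname(l2[1, 3]), 2)
  # configurable offset
  l2b <- SummarizedExperiment::assay(logTransform(s, "log2", offset = 5),
                                     "exprs")
  expect_equal(unname(l2b[1, 3]), 3)
})

test_that("baseline pooling collects pre-stimulus cells only", {
  gt <- groundTruthPresets()
  d <- generateTimecourse(gt$theta_epithelial, smallConfig(n = 25),
                          time_grid = c(-5, 0, 5), seed = 2,
                          n_replicates = 2, control_times = 0)
  cells <- baselineCells(d)
  # 2 replicates x 2 pre-stimulus times x 25 cells
  expect_equal(length(cells), 100)
  expect_true(all(cellBaseline(cells) < cellTotals(cells)))
  expect_error(baselineCells(d[, snapshotTimes(d) > 0]), "no pre-stimulation")
})
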