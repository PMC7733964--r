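## Synthetic snapshot generation with known ground truth.
##
## The generator emulates the statistical structure the downstream analysis
## assumes: correlated lognormal cell-to-cell variation in total protein,
## baseline phospho levels as noisy fractions of totals, bimodal phenotype
## markers, a counts-valued viability channel, destructive sampling (a fresh
## population at every snapshot), ground-truth kinetics from the mechanistic
## model itself, and multiplicative lognormal measurement noise.

#' The standard sampling time grid
#'
#' Sampling times in minutes relative to EGF stimulation; the three
#' non-positive times are pre-stimulus baselines.
#'
#' @return Numeric vector of 12 times.
#' @export
defaultTimeGrid <- function() c(-10, -5, 0, 1, 3, 5, 8, 12, 15, 20, 30, 50)

#' Phenotype configuration for the synthetic generator
#'
#' All study conditions of the generator live here, not in code: snapshot
#' size, total-protein means and lognormal variability, the shared pairwise
#' correlation of totals, baseline phospho fractions, the bimodal
#' E-cadherin/vimentin modes, the dead-cell fraction and the measurement
#' noise CV.
#'
#' @param label "epithelial" or "mesenchymal".
#' @param n_cells_per_snapshot Cells per snapshot (>= 10; default 1000).
#' @param total_means Named positive means of the six total-protein
#'   channels (arbitrary intensity units).
#' @param total_cv Lognormal coefficient of variation of totals.
#' @param total_correlation Shared pairwise correlation of log-totals, in
#'   [0, 1).
#' @param baseline_phospho_fraction Named baseline phospho/total fractions
#'   in (0, 1) per measured species.
#' @param baseline_jitter_cv Lognormal CV of the per-cell jitter multiplying
#'   the baseline fraction.
#' @param ecad_vim_modes c(high, low) location parameters of the bimodal
#'   phenotype markers; epithelial populations put E-cadherin at the high
#'   mode and vimentin at the low mode, mesenchymal the reverse.
#' @param marker_sdlog Lognormal sdlog of the phenotype markers.
#' @param dead_fraction Fraction of dead/apoptotic cells (cleaved PARP
#'   above 20 counts), in [0, 1).
#' @param noise_cv Multiplicative lognormal measurement-noise CV.
#' @return A validated list of class "PhenotypeConfig".
#' @export
#' @examples
#' cfg <- phenotypeConfig("epithelial", n_cells_per_snapshot = 100)
phenotypeConfig <- function(label = c("epithelial", "mesenchymal"),
                            n_cells_per_snapshot = 1000,
                            total_means = c(tMEK = 150, tERK = 300, tRSK = 80,
                                            tAKT = 500, tGSK3B = 120,
                                            tS6 = 200),
                            total_cv = 0.25,
                            total_correlation = 0.5,
                            baseline_phospho_fraction = c(pMEK = 0.20,
                                                          ppERK = 0.10,
                                                          pRSK = 0.15,
                                                          pAKT = 0.15,
                                                          pGSK3B = 0.30,
                                                          pS6 = 0.15),
                            baseline_jitter_cv = 0.2,
                            ecad_vim_modes = c(high = 150, low = 4),
                            marker_sdlog = 0.4,
                            dead_fraction = 0.05,
                            noise_cv = 0.15) {
  label <- match.arg(label)
  if (n_cells_per_snapshot < 10) stop("n_cells_per_snapshot must be >= 10")
  if (any(total_means <= 0)) stop("total_means must be positive")
  if (total_cv < 0 || baseline_jitter_cv < 0 || noise_cv < 0) {
    stop("coefficients of variation must be non-negative")
  }
  if (total_correlation < 0 || total_correlation >= 1) {
    stop("total_correlation must be in [0, 1)")
  }
  if (any(baseline_phospho_fraction <= 0 | baseline_phospho_fraction >= 1)) {
    stop("baseline_phospho_fraction values must lie in (0, 1)")
  }
  if (dead_fraction < 0 || dead_fraction >= 1) {
    stop("dead_fraction must be in [0, 1)")
  }
  if (any(ecad_vim_modes <= 0)) stop("ecad_vim_modes must be positive")
  structure(list(label = label,
                 n_cells_per_snapshot = as.integer(n_cells_per_snapshot),
                 total_means = total_means[totalChannels()],
                 total_cv = total_cv,
                 total_correlation = total_correlation,
                 baseline_phospho_fraction =
                   baseline_phospho_fraction[measuredSpecies()],
                 baseline_jitter_cv = baseline_jitter_cv,
                 ecad_vim_modes = ecad_vim_modes,
                 marker_sdlog = marker_sdlog,
                 dead_fraction = dead_fraction,
                 noise_cv = noise_cv),
            class = "PhenotypeConfig")
}

## stable per-stage/per-snapshot seed derivation from a master seed
deriveSeed <- function(master, k) {
  as.integer((as.double(master) + as.double(k) * 9973) %% 2147483647)
}

#' Generate one cell population
#'
#' Draws per-cell totals from a correlated multivariate lognormal (the
#' shared pairwise correlation acts on the log scale through a common
#' factor), baseline phospho as fraction x total x lognormal jitter clamped
#' into \code{(eps*T, (1-eps)*T)} with \code{eps = 1e-6}, phenotype markers
#' from the configured bimodal modes, and a cleaved-PARP counts channel in
#' which \code{dead_fraction} of cells exceed 20 counts.
#'
#' @param config A \code{\link{phenotypeConfig}}.
#' @param seed Integer seed; the same seed reproduces the population
#'   exactly.
#' @return A \linkS4class{CellPopulation} (markers: Ecad, Vim, cPARP).
#' @export
generateCellPopulation <- function(config, seed) {
  stopifnot(inherits(config, "PhenotypeConfig"))
  set.seed(seed)
  n <- config$n_cells_per_snapshot
  sp <- measuredSpecies()

  sdlog <- sqrt(log(1 + config$total_cv^2))
  rho <- config$total_correlation
  z0 <- rnorm(n)
  z <- sqrt(rho) * matrix(z0, n, 6) + sqrt(1 - rho) * matrix(rnorm(n * 6), n, 6)
  totals <- sweep(exp(sdlog * z - sdlog^2 / 2), 2, config$total_means, "*")
  colnames(totals) <- sp

  sj <- sqrt(log(1 + config$baseline_jitter_cv^2))
  jitter <- matrix(exp(sj * rnorm(n * 6) - sj^2 / 2), n, 6)
  base <- sweep(totals, 2, config$baseline_phospho_fraction, "*") * jitter
  eps <- 1e-6
  base <- pmin(pmax(base, eps * totals), (1 - eps) * totals)
  colnames(base) <- sp

  hi <- config$ecad_vim_modes[["high"]]
  lo <- config$ecad_vim_modes[["low"]]
  if (config$label == "epithelial") {
    ecad <- rlnorm(n, log(hi), config$marker_sdlog)
    vim <- rlnorm(n, log(lo), config$marker_sdlog)
  } else {
    ecad <- rlnorm(n, log(lo), config$marker_sdlog)
    vim <- rlnorm(n, log(hi), config$marker_sdlog)
  }
  dead <- rbinom(n, 1, config$dead_fraction)
  cparp <- ifelse(dead == 1, 21 + rpois(n, 30), pmin(rpois(n, 2), 20))
  markers <- cbind(Ecad = ecad, Vim = vim, cPARP = as.numeric(cparp))
  CellPopulation(totals, base, markers = markers)
}

## multiplicative lognormal measurement noise, unit mean
applyNoise <- function(x, cv) {
  if (cv == 0) return(x)
  s <- sqrt(log(1 + cv^2))
  x * exp(s * rnorm(length(x)) - s^2 / 2)
}

#' Generate a synthetic snapshot time course
#'
#' For every snapshot time and replicate an independent cell population is
#' generated (destructive sampling: cell identity never persists across
#' time points), each cell's trajectory is simulated with the mechanistic
#' model from its own baseline steady state, the state at the snapshot time
#' is recorded, and multiplicative lognormal measurement noise is applied.
#' Unstimulated-control snapshots, with the input held at baseline so cells
#' remain at steady state, are emitted for four of the time points.
#'
#' @param truth Ground-truth \linkS4class{ParameterSet}.
#' @param config A \code{\link{phenotypeConfig}}.
#' @param time_grid Sorted sampling times containing at least one
#'   pre-stimulus point (t <= 0).
#' @param seed Master seed; snapshot seeds are derived from it.
#' @param n_replicates Number of independent replicates (default 3).
#' @param control_times Times at which unstimulated controls are emitted.
#' @return A \linkS4class{SnapshotSet} with 15 channels.
#' @export
generateTimecourse <- function(truth, config, time_grid = defaultTimeGrid(),
                               seed = 1L, n_replicates = 3,
                               control_times = c(0, 5, 15, 50)) {
  stopifnot(inherits(config, "PhenotypeConfig"))
  if (is.unsorted(time_grid)) stop("time_grid must be sorted")
  if (!any(time_grid <= 0)) {
    stop("time_grid must contain at least one pre-stimulus point (t <= 0)")
  }
  plan <- rbind(
    expand.grid(time = time_grid, replicate = seq_len(n_replicates),
                condition = "stimulated", stringsAsFactors = FALSE),
    expand.grid(time = control_times, replicate = seq_len(n_replicates),
                condition = "control", stringsAsFactors = FALSE))

  blocks <- vector("list", nrow(plan))
  for (k in seq_len(nrow(plan))) {
    t_k <- plan$time[k]
    pop <- generateCellPopulation(config, deriveSeed(seed, k))
    if (plan$condition[k] == "control" || t_k <= 0) {
      phospho <- cellBaseline(pop)  # input at baseline: cells at steady state
    } else {
      res <- tryCatch(
        simulateEnsemble(truth, pop, times = t_k),
        error = function(e) stop("snapshot (t = ", t_k, ", replicate ",
                                 plan$replicate[k], ", ", config$label,
                                 "): ", conditionMessage(e), call. = FALSE))
      phospho <- ensembleStates(res, t_k)
    }
    set.seed(deriveSeed(seed, k + 500000L))
    mk <- cellMarkers(pop)
    tot <- cellTotals(pop)
    colnames(tot) <- totalChannels()
    intensities <- cbind(phospho, tot, mk[, c("Ecad", "Vim"), drop = FALSE])
    noisy <- apply(intensities, 2, applyNoise, cv = config$noise_cv)
    blocks[[k]] <- list(exprs = cbind(noisy, cPARP = mk[, "cPARP"]),
                        meta = plan[k, ])
  }
  exprs <- t(do.call(rbind, lapply(blocks, `[[`, "exprs")))
  meta <- do.call(rbind, lapply(blocks, function(b) {
    b$meta[rep(1, nrow(b$exprs)), ]
  }))
  SnapshotSet(exprs,
              time = meta$time, replicate = meta$replicate,
              condition = meta$condition, phenotype = config$label)
}
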