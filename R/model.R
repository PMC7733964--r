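## Mechanistic model: input signal, steady-state closure, ensemble simulation.

#' Aggregated pathway input signal
#'
#' Each pathway's unmodeled upstream (receptor binding, adaptor recruitment)
#' is aggregated into a single input: the signal sits at its pre-stimulus
#' steady-state value 1 until the delay \code{tau}, jumps to the magnitude
#' \code{I} and decays exponentially back towards 1 at rate \code{d}.
#'
#' @param t Time(s) in minutes relative to stimulation.
#' @param I Input magnitude (\code{I = 1} means no stimulation).
#' @param tau Delay in minutes (>= 0).
#' @param d Decay rate per minute (>= 0).
#' @return Input level(s), vectorised over \code{t}.
#' @export
#' @examples
#' inputSignal(c(-5, 0.5, 2, 1e6), I = 5.3, tau = 1, d = 0.1)
inputSignal <- function(t, I, tau, d) {
  stopifnot(I > 0, tau >= 0, d >= 0)
  ifelse(t < tau, 1, 1 + (I - 1) * exp(-d * (t - tau)))
}

#' Steady state of the unmeasured modifier species
#'
#' At baseline input (u = 1) the PI3K modifier settles at
#' \eqn{x_{P0} = (k_P/\gamma_P)^{1/h_P}} in closed form; the pRAF modifier
#' solves \eqn{k_R x_{P0}^{g_{c1}} (R_T - x) = \gamma_R x^{h_R}} on
#' \eqn{(0, R_T)}, which always brackets a unique root for positive
#' parameters, found here to relative tolerance 1e-12.
#'
#' @param theta A \linkS4class{ParameterSet}.
#' @return Named numeric c(xR0, xP0).
#' @export
unmeasuredSteadyState <- function(theta) {
  v <- parameterValues(theta)
  xP0 <- (v[["kP"]] / v[["gammaP"]])^(1 / v[["hP"]])
  a <- v[["kR"]] * xP0^v[["gc1"]]
  RT <- v[["RT"]]
  fn <- function(x) a * (RT - x) - v[["gammaR"]] * x^v[["hR"]]
  if (!is.finite(a) || fn(RT * 1e-12) <= 0) {
    stop("no pRAF steady state in (0, RT) for this parameter set")
  }
  if (fn(RT * (1 - 1e-12)) >= 0) {
    # root hugs the capacity; first-order asymptotics in gammaR/a
    xR0 <- RT - v[["gammaR"]] * RT^v[["hR"]] / a
    if (!is.finite(xR0) || xR0 <= 0 || xR0 >= RT) {
      stop("no pRAF steady state in (0, RT) for this parameter set")
    }
    return(c(xR0 = xR0, xP0 = xP0))
  }
  r <- uniroot(fn, lower = RT * 1e-12, upper = RT * (1 - 1e-12),
               tol = 1e-12 * RT)
  c(xR0 = r$root, xP0 = xP0)
}

#' Derive cell-specific deactivation rates (DISCO closure)
#'
#' Sets each cell's six deactivation rates \eqn{\gamma_{i,c}} so that the
#' cell's measured baseline is an exact steady state of its ODEs under
#' baseline input, e.g.
#' \eqn{\gamma_{MEK,c} = k_1 x_{R0}^{g_1} (T_{MEK,c} - m_{0,c}) / m_{0,c}^{h_1}},
#' with the two-branch species (pGSK3B, pS6) using their summed production
#' terms.  Cell-to-cell variation in unmeasured components is thereby
#' absorbed into this rate subset while activation rates stay at the
#' population level.
#'
#' @param theta A \linkS4class{ParameterSet}.
#' @param cells A \linkS4class{CellPopulation}; baselines are clamped into
#'   \code{(eps*T, (1-eps)*T)} with \code{eps = 1e-6} first (a warning is
#'   given if any cell actually sits at the clamp bounds).
#' @return The \code{CellPopulation} with the \code{gamma} slot filled.
#' @export
deriveCellRates <- function(theta, cells) {
  ss <- unmeasuredSteadyState(theta)
  tot <- cellTotals(cells)
  eps <- 1e-6
  base <- cellBaseline(cells)
  lo <- eps * tot
  hi <- (1 - eps) * tot
  nclamp <- sum(base < lo | base > hi)
  if (nclamp > 0) {
    warning(nclamp, " baseline value(s) clamped to the interior of (0, total)")
    base <- pmin(pmax(base, lo), hi)
  }
  g <- cpp_derive_gamma(parameterValues(theta)[modelParameterNames()],
                        ss[["xR0"]], ss[["xP0"]], tot, base)
  dimnames(g) <- dimnames(tot)
  CellPopulation(tot, base, gamma = g, markers = cellMarkers(cells))
}

#' Simulate a single-cell ensemble
#'
#' Integrates the unified model for a population of cells: the two shared
#' unmeasured species are integrated once at the population level, then each
#' cell's six measured phospho ODEs are integrated from its own baseline
#' with its own derived deactivation rates.  Integration uses an adaptive
#' embedded Runge-Kutta scheme with an L-stable implicit fallback per
#' species, relative tolerance \code{rtol} and absolute tolerance
#' \code{1e-9 * T} per species.
#'
#' @param theta A \linkS4class{ParameterSet}.
#' @param cells A \linkS4class{CellPopulation} with derived rates (see
#'   \code{\link{deriveCellRates}}); underived populations are closed
#'   automatically.
#' @param times Output times in minutes; times <= 0 report the baseline.
#' @param rtol Relative tolerance (default 1e-6).
#' @param failTol Maximum tolerated fraction of failed cells (default 0.05);
#'   more failures abort with a diagnostic.
#' @return An \linkS4class{EnsembleResult}.
#' @export
#' @examples
#' theta <- defaultParameters("epithelial")
#' cells <- generateCellPopulation(phenotypeConfig("epithelial",
#'                                                 n_cells_per_snapshot = 20),
#'                                 seed = 1)
#' res <- simulateEnsemble(theta, cells, times = c(0, 5, 15))
simulateEnsemble <- function(theta, cells, times, rtol = 1e-6,
                             failTol = 0.05) {
  if (nrow(cellRates(cells)) == 0) cells <- deriveCellRates(theta, cells)
  ss <- unmeasuredSteadyState(theta)
  out <- cpp_simulate_ensemble(parameterValues(theta)[modelParameterNames()],
                               ss[["xR0"]], ss[["xP0"]],
                               cellTotals(cells), cellBaseline(cells),
                               cellRates(cells), as.numeric(times), rtol)
  failed <- as.integer(out$failed)
  if (length(failed) > failTol * length(cells)) {
    stop(sprintf(paste0("ensemble simulation failed for %d of %d cells ",
                        "(first failure: cell %d); parameter set rejected"),
                 length(failed), length(cells), failed[1]))
  }
  states <- out$states
  dimnames(states) <- list(NULL, measuredSpecies(), NULL)
  shared <- out$shared
  colnames(shared) <- c("pRAF", "PI3K")
  new("EnsembleResult", states = states, shared = shared,
      times = as.numeric(times), failed = failed)
}
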