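#' @import methods
#' @importFrom stats approx cor cov dist hclust lm.fit median optim
#'   quantile rbinom rlnorm rnorm runif rpois sd setNames uniroot var
#' @importFrom utils head read.csv write.csv
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SummarizedExperiment assay assay<- assayNames colData colData<-
#'   rowData
#' @importFrom S4Vectors DataFrame
#' @useDynLib discofit, .registration = TRUE
NULL

## ---- canonical naming ------------------------------------------------------

#' Names of the population-level model parameters
#'
#' The unified power-law model of the EGF-driven ERK and AKT pathways carries
#' exactly 38 population-level parameters: two aggregated inputs (magnitude,
#' delay, decay each), the two unmeasured modifier blocks (pRAF with a finite
#' capacity, PI3K without), and activation rate / kinetic-order triples for
#' the six measured phosphoproteins, with two-branch production for pGSK3B
#' (AKT and RSK arms) and pS6 (RSK and AKT arms).
#'
#' @return Character vector of length 38, in canonical order.
#' @export
#' @examples
#' length(modelParameterNames())
modelParameterNames <- function() {
  c("I1", "tau1", "d1", "I2", "tau2", "d2",
    "kR", "gR", "gc1", "hR", "gammaR", "RT",
    "kP", "gP", "hP", "gammaP",
    "k1", "g1", "h1",
    "k2", "g2", "h2",
    "k3", "g3", "h3",
    "k4", "g4", "h4",
    "k5", "g5", "k12", "g12", "h5",
    "k6", "g6", "k13", "g13", "h6")
}

#' Names of the measured phosphoprotein species
#'
#' @return Character vector of the six measured species, pathway order.
#' @export
measuredSpecies <- function() {
  c("pMEK", "ppERK", "pRSK", "pAKT", "pGSK3B", "pS6")
}

#' Names of the matching total-protein channels
#'
#' @return Character vector of the six total-protein channels.
#' @export
totalChannels <- function() {
  c("tMEK", "tERK", "tRSK", "tAKT", "tGSK3B", "tS6")
}

## ---- ParameterSet ----------------------------------------------------------

#' ParameterSet: the 38 population-level kinetic parameters
#'
#' Named numeric container for the unified model's population parameters.
#' Validity enforces completeness (all 38 canonical names, no extras) and
#' strict positivity; recommended ranges for kinetic orders live in
#' \code{\link{defaultSearchRanges}}, not in the class, so that sensitivity
#' grids may scale any parameter by up to 2^3.
#'
#' @slot values Named numeric vector of length 38.
#' @export
setClass("ParameterSet", representation(values = "numeric"))

setValidity("ParameterSet", function(object) {
  v <- object@values
  want <- modelParameterNames()
  if (length(v) != length(want)) {
    return(sprintf("expected %d parameters, got %d", length(want), length(v)))
  }
  if (!identical(sort(names(v)), sort(want))) {
    missing <- setdiff(want, names(v))
    extra <- setdiff(names(v), want)
    return(paste0("parameter names do not match the canonical inventory",
                  if (length(missing)) paste0("; missing: ",
                                              paste(missing, collapse = ", ")),
                  if (length(extra)) paste0("; unknown: ",
                                            paste(extra, collapse = ", "))))
  }
  if (any(!is.finite(v)) || any(v <= 0)) {
    bad <- names(v)[!is.finite(v) | v <= 0]
    return(paste0("parameters must be finite and strictly positive: ",
                  paste(bad, collapse = ", ")))
  }
  TRUE
})

#' Construct a ParameterSet
#'
#' @param values Named numeric vector covering all 38 canonical parameter
#'   names (any order).
#' @return A \linkS4class{ParameterSet}.
#' @export
#' @examples
#' theta <- ParameterSet(parameterValues(defaultParameters("epithelial")))
ParameterSet <- function(values) {
  want <- modelParameterNames()
  if (!all(want %in% names(values))) {
    stop(sprintf("expected %d named parameters; missing: %s", length(want),
                 paste(setdiff(want, names(values)), collapse = ", ")))
  }
  new("ParameterSet", values = values[want])
}

#' Named numeric vector of a ParameterSet's values
#'
#' @param object A \linkS4class{ParameterSet}.
#' @return Named numeric vector of length 38.
#' @export
parameterValues <- function(object) object@values

#' @export
setMethod("length", "ParameterSet", function(x) length(x@values))

#' @param i Parameter name(s) or index.
#' @rdname ParameterSet-class
#' @export
setMethod("[", "ParameterSet", function(x, i) unname(x@values[i]))

#' @param value Replacement value(s), strictly positive.
#' @rdname ParameterSet-class
#' @export
setMethod("[<-", "ParameterSet", function(x, i, value) {
  x@values[i] <- value
  validObject(x)
  x
})

setMethod("show", "ParameterSet", function(object) {
  cat("ParameterSet with", length(object@values), "population parameters\n")
  print(signif(object@values, 4))
})

## ---- CellPopulation --------------------------------------------------------

#' CellPopulation: per-cell totals, baselines and derived deactivation rates
#'
#' Measured per-cell state used to initialise the single-cell ensemble:
#' total protein levels and baseline (pre-stimulus) phospho levels for the
#' six measured species, plus the cell-specific deactivation rates
#' \eqn{\gamma_{i,c}} once derived by \code{\link{deriveCellRates}} (empty
#' matrix beforehand).  Phenotype marker and viability channels are carried
#' along when the population comes from the synthetic generator.
#'
#' @slot totals Numeric matrix, cells x 6 measured species (columns named as
#'   \code{measuredSpecies()}).
#' @slot baseline Numeric matrix, same shape; baseline phospho levels,
#'   interior to \code{(0, totals)}.
#' @slot gamma Numeric matrix, same shape once derived, otherwise 0-row.
#' @slot markers Numeric matrix, cells x extra channels (Ecad, Vim, cPARP)
#'   or 0-column.
#' @export
setClass("CellPopulation",
         representation(totals = "matrix", baseline = "matrix",
                        gamma = "matrix", markers = "matrix"))

setValidity("CellPopulation", function(object) {
  sp <- measuredSpecies()
  if (!identical(colnames(object@totals), sp) ||
      !identical(colnames(object@baseline), sp)) {
    return("totals and baseline must have the six measured species as columns")
  }
  if (nrow(object@totals) != nrow(object@baseline)) {
    return("totals and baseline must have one row per cell")
  }
  if (any(object@totals <= 0)) return("totals must be strictly positive")
  if (any(object@baseline <= 0) || any(object@baseline >= object@totals)) {
    return("baseline phospho must lie strictly inside (0, total) per cell")
  }
  if (nrow(object@gamma) > 0) {
    if (!identical(dim(object@gamma), dim(object@totals))) {
      return("gamma, when derived, must match the totals matrix shape")
    }
    if (any(object@gamma <= 0)) return("derived gamma must be positive")
  }
  TRUE
})

#' Construct a CellPopulation
#'
#' @param totals,baseline Cells x 6 matrices (columns \code{measuredSpecies()}).
#' @param gamma Optional derived deactivation-rate matrix.
#' @param markers Optional matrix of additional per-cell channels.
#' @return A \linkS4class{CellPopulation}.
#' @export
CellPopulation <- function(totals, baseline, gamma = NULL, markers = NULL) {
  if (is.null(gamma)) {
    gamma <- matrix(numeric(0), nrow = 0, ncol = 6,
                    dimnames = list(NULL, measuredSpecies()))
  }
  if (is.null(markers)) markers <- matrix(numeric(0), nrow = nrow(totals), ncol = 0)
  new("CellPopulation", totals = totals, baseline = baseline,
      gamma = gamma, markers = markers)
}

#' @rdname CellPopulation-class
#' @param x A \code{CellPopulation}.
#' @export
setMethod("length", "CellPopulation", function(x) nrow(x@totals))

#' Accessors for CellPopulation slots
#'
#' @param object A \linkS4class{CellPopulation}.
#' @return The corresponding per-cell matrix.
#' @export
cellTotals <- function(object) object@totals

#' @rdname cellTotals
#' @export
cellBaseline <- function(object) object@baseline

#' @rdname cellTotals
#' @export
cellRates <- function(object) object@gamma

#' @rdname cellTotals
#' @export
cellMarkers <- function(object) object@markers

setMethod("show", "CellPopulation", function(object) {
  cat("CellPopulation:", nrow(object@totals), "cells,",
      ncol(object@totals), "measured species;",
      if (nrow(object@gamma)) "gamma derived\n" else "gamma not derived\n")
})

#' Subset a CellPopulation by cell index
#'
#' @param x A \linkS4class{CellPopulation}.
#' @param i Cell indices.
#' @return A \code{CellPopulation} with the selected cells.
#' @export
setMethod("[", "CellPopulation", function(x, i) {
  g <- if (nrow(x@gamma)) x@gamma[i, , drop = FALSE] else x@gamma
  new("CellPopulation", totals = x@totals[i, , drop = FALSE],
      baseline = x@baseline[i, , drop = FALSE], gamma = g,
      markers = x@markers[i, , drop = FALSE])
})

## ---- SnapshotSet -----------------------------------------------------------

#' SnapshotSet: single-cell snapshots across time, replicate and condition
#'
#' A \linkS4class{SingleCellExperiment} whose columns are cells and whose
#' rows are channels.  Column metadata records the snapshot structure
#' (\code{time} in minutes relative to stimulation, \code{replicate},
#' \code{condition} = stimulated/control, \code{phenotype}); row metadata
#' records each channel's \code{role} (phospho, total, marker, viability)
#' and, for phospho channels, the matching total-protein \code{partner}.
#' Because sampling is destructive, cells in different snapshots are always
#' distinct individuals.
#'
#' @export
setClass("SnapshotSet", contains = "SingleCellExperiment")

setValidity("SnapshotSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  need <- c("time", "replicate", "condition", "phenotype")
  if (!all(need %in% colnames(cd))) {
    return(paste0("colData must contain: ", paste(need, collapse = ", ")))
  }
  if (!"exprs" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'exprs' is required")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("role", "partner") %in% colnames(rd))) {
    return("rowData must contain 'role' and 'partner'")
  }
  if (anyDuplicated(rownames(object))) return("channel names must be unique")
  if (any(SummarizedExperiment::assay(object, "exprs") < 0)) {
    return("intensities must be non-negative")
  }
  if (!all(cd$condition %in% c("stimulated", "control"))) {
    return("condition must be 'stimulated' or 'control'")
  }
  TRUE
})

#' Construct a SnapshotSet
#'
#' @param exprs Channels x cells matrix of non-negative intensities with
#'   unique rownames.
#' @param time,replicate,condition,phenotype Per-cell annotations (recycled).
#' @param panel Optional data.frame with columns \code{role} and
#'   \code{partner}, one row per channel; inferred from the standard panel
#'   naming when omitted.
#' @return A \linkS4class{SnapshotSet}.
#' @export
SnapshotSet <- function(exprs, time, replicate = 1L,
                        condition = "stimulated", phenotype = "ungated",
                        panel = NULL) {
  n <- ncol(exprs)
  if (is.null(panel)) panel <- standardPanel(rownames(exprs))
  cd <- S4Vectors::DataFrame(time = rep(as.numeric(time), length.out = n),
                             replicate = rep(as.integer(replicate), length.out = n),
                             condition = rep(condition, length.out = n),
                             phenotype = rep(phenotype, length.out = n))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(exprs = exprs), colData = cd,
    rowData = S4Vectors::DataFrame(panel))
  new("SnapshotSet", sce)
}

#' Standard channel panel description
#'
#' Maps channel names to their roles (phospho, total, marker, viability) and
#' phospho channels to their total-protein partners, following the 15-channel
#' panel the synthetic generator emits.
#'
#' @param channels Character vector of channel names.
#' @return data.frame with columns \code{role} and \code{partner}.
#' @export
standardPanel <- function(channels) {
  role <- rep("marker", length(channels))
  partner <- rep(NA_character_, length(channels))
  ph <- measuredSpecies()
  tot <- totalChannels()
  role[channels %in% ph] <- "phospho"
  role[channels %in% tot] <- "total"
  role[channels == "cPARP"] <- "viability"
  idx <- match(ph, channels)
  present <- !is.na(idx)
  partner[idx[present]] <- tot[present]
  data.frame(role = role, partner = partner, row.names = channels)
}

#' Snapshot annotation accessors
#'
#' @param object A \linkS4class{SnapshotSet}.
#' @return Per-cell annotation vector.
#' @export
snapshotTimes <- function(object) SummarizedExperiment::colData(object)$time

#' @rdname snapshotTimes
#' @export
snapshotReplicates <- function(object) {
  SummarizedExperiment::colData(object)$replicate
}

#' @rdname snapshotTimes
#' @export
snapshotConditions <- function(object) {
  SummarizedExperiment::colData(object)$condition
}

#' @rdname snapshotTimes
#' @export
snapshotPhenotypes <- function(object) {
  SummarizedExperiment::colData(object)$phenotype
}

#' Extract the intensity matrix of a SnapshotSet
#'
#' @param object A \linkS4class{SnapshotSet}.
#' @param channels Optional channel subset.
#' @return Cells x channels numeric matrix (transposed from the assay).
#' @export
snapshotMatrix <- function(object, channels = NULL) {
  m <- SummarizedExperiment::assay(object, "exprs")
  if (!is.null(channels)) {
    missing <- setdiff(channels, rownames(m))
    if (length(missing)) {
      stop("channel(s) not present: ", paste(missing, collapse = ", "))
    }
    m <- m[channels, , drop = FALSE]
  }
  t(m)
}

setMethod("show", "SnapshotSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("SnapshotSet:", ncol(object), "cells x", nrow(object), "channels\n")
  cat("  times:", paste(sort(unique(cd$time)), collapse = ", "), "min\n")
  cat("  replicates:", paste(sort(unique(cd$replicate)), collapse = ", "),
      " conditions:", paste(unique(cd$condition), collapse = ", "),
      " phenotypes:", paste(unique(cd$phenotype), collapse = ", "), "\n")
})

## ---- PartialCorrNetwork ----------------------------------------------------

#' PartialCorrNetwork: full-order partial-correlation network
#'
#' Symmetric matrix of full-order partial correlations \eqn{\rho_{XY\cdot Z}}
#' between the analysis channels, its Fisher z-transform, and the edge set
#' called at a magnitude threshold.
#'
#' @slot variables Channel names.
#' @slot rho Symmetric partial-correlation matrix, unit diagonal.
#' @slot z Fisher z-transform of \code{rho}, off-diagonal.
#' @slot edges data.frame (var1, var2, rho, z, passes_threshold).
#' @slot threshold Edge-calling threshold on |rho|.
#' @slot replicateSD Optional across-replicate SD matrix.
#' @export
setClass("PartialCorrNetwork",
         representation(variables = "character", rho = "matrix", z = "matrix",
                        edges = "data.frame", threshold = "numeric",
                        replicateSD = "matrix"))

setValidity("PartialCorrNetwork", function(object) {
  r <- object@rho
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-8))) {
    return("rho must be symmetric")
  }
  if (max(abs(diag(r) - 1)) > 1e-12) return("rho must have unit diagonal")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) return("rho entries must be in [-1, 1]")
  TRUE
})

#' Accessors for PartialCorrNetwork objects
#'
#' @param object A \linkS4class{PartialCorrNetwork}.
#' @return \code{networkEdges}: the edge table restricted to pairs passing
#'   the threshold; \code{networkRho} / \code{networkZ}: the full matrices.
#' @export
networkEdges <- function(object) {
  object@edges[object@edges$passes_threshold, c("var1", "var2", "rho", "z")]
}

#' @rdname networkEdges
#' @export
networkRho <- function(object) object@rho

#' @rdname networkEdges
#' @export
networkZ <- function(object) object@z

setMethod("show", "PartialCorrNetwork", function(object) {
  cat("PartialCorrNetwork on", length(object@variables), "variables,",
      sum(object@edges$passes_threshold), "edges at |rho| >=",
      object@threshold, "\n")
})

## ---- EnsembleResult --------------------------------------------------------

#' EnsembleResult: simulated single-cell trajectories
#'
#' @slot states 3-d array cells x species x times of the six measured
#'   phospho species.
#' @slot shared Matrix times x 2 of the shared unmeasured species
#'   (pRAF, PI3K).
#' @slot times Output time grid (minutes).
#' @slot failed Indices of cells whose integration failed (excluded).
#' @export
setClass("EnsembleResult",
         representation(states = "array", shared = "matrix",
                        times = "numeric", failed = "integer"))

#' Extract ensemble states at one output time
#'
#' @param object An \linkS4class{EnsembleResult}.
#' @param time Requested output time (must be on the grid).
#' @return Cells x species matrix.
#' @export
ensembleStates <- function(object, time) {
  k <- match(time, object@times)
  if (is.na(k)) stop("time not on the output grid")
  object@states[, , k, drop = TRUE]
}

setMethod("show", "EnsembleResult", function(object) {
  cat("EnsembleResult:", dim(object@states)[1], "cells x",
      dim(object@states)[2], "species x", length(object@times), "times;",
      length(object@failed), "failed\n")
})

## ---- Fit / sensitivity / reconciliation results ---------------------------

#' FitResult: outcome of distribution-matching parameter estimation
#'
#' @slot theta Best parameter set: a \linkS4class{ParameterSet} when the
#'   search covered the full model inventory, otherwise the named numeric
#'   vector that was optimised (the local search is generic over cost
#'   surfaces).
#' @slot cost Final cost value.
#' @slot trace data.frame (stage, iteration, cost) along the search.
#' @slot seed Master seed used.
#' @slot settings List snapshot of the search settings.
#' @export
setClass("FitResult",
         representation(theta = "ANY", cost = "numeric",
                        trace = "data.frame", seed = "integer",
                        settings = "list"))

#' Accessors for FitResult objects
#'
#' @param object A \linkS4class{FitResult}.
#' @return The fitted \linkS4class{ParameterSet}, the final cost, or the
#'   search trace respectively.
#' @export
fittedParameters <- function(object) object@theta

#' @rdname fittedParameters
#' @export
fitCost <- function(object) object@cost

#' @rdname fittedParameters
#' @export
fitTrace <- function(object) object@trace

setMethod("show", "FitResult", function(object) {
  cat("FitResult: cost", signif(object@cost, 6), "after",
      nrow(object@trace), "recorded evaluations (seed", object@seed, ")\n")
})

#' SensitivityGrid: percent cost increase over a log2 perturbation grid
#'
#' @slot values Matrix parameters x offsets of percent cost increases
#'   100 * (F(theta_j * 2^delta) - F0) / F0.
#' @slot offsets Log2 offsets (columns).
#' @slot anchor The anchor \linkS4class{ParameterSet}.
#' @slot baseCost Cost at the anchor under the grid's own cost function.
#' @export
setClass("SensitivityGrid",
         representation(values = "matrix", offsets = "numeric",
                        anchor = "ParameterSet", baseCost = "numeric"))

setMethod("show", "SensitivityGrid", function(object) {
  cat("SensitivityGrid:", nrow(object@values), "parameters x",
      ncol(object@values), "log2 offsets in [",
      min(object@offsets), ",", max(object@offsets), "]\n")
})

#' Percent-increase matrix of a sensitivity grid
#'
#' @param object A \linkS4class{SensitivityGrid}.
#' @return Parameters x offsets matrix of percent cost increases.
#' @export
sensitivityValues <- function(object) object@values

#' ReconciliationResult: near-identical parameter pair across phenotypes
#'
#' @slot thetaE,thetaM Reconciled parameter sets.
#' @slot log2diff Named per-parameter log2 differences (E minus M).
#' @slot costE,costM Cost certificates at the reconciled sets.
#' @slot boundE,boundM Cost bounds (fitted costs) the certificates respect.
#' @slot slack Relative slack allowed on the bounds.
#' @slot audit data.frame trail of phase-1 merge decisions.
#' @export
setClass("ReconciliationResult",
         representation(thetaE = "ParameterSet", thetaM = "ParameterSet",
                        log2diff = "numeric", costE = "numeric",
                        costM = "numeric", boundE = "numeric",
                        boundM = "numeric", slack = "numeric",
                        audit = "data.frame"))

setMethod("show", "ReconciliationResult", function(object) {
  nd <- sum(abs(object@log2diff) > 1e-12)
  cat("ReconciliationResult:", nd, "parameters still differ;",
      "costs", signif(object@costE, 5), "/", signif(object@costM, 5),
      "within (1 +", object@slack, ") x bounds\n")
})

#' Per-parameter log2 differences of a reconciled pair
#'
#' @param object A \linkS4class{ReconciliationResult}.
#' @return Named numeric vector of log2 differences (epithelial minus
#'   mesenchymal).
#' @export
reconciledDifferences <- function(object) object@log2diff
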