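## Grid-based parameter sensitivity and cross-phenotype reconciliation.

#' Default sensitivity offsets
#'
#' Log2 fold-changes in increments of 0.25 over [-8, 3]: 45 offsets.
#'
#' @return Numeric vector of 45 log2 offsets.
#' @export
defaultSensitivityOffsets <- function() seq(-8, 3, by = 0.25)

#' Grid-based parameter sensitivity
#'
#' For each population parameter j and each log2 offset delta, evaluates
#' the cost with \eqn{\theta_j} replaced by \eqn{\theta_j 2^\delta} (all
#' other parameters at the anchor) and reports the percent increase in
#' cost, \eqn{100 (F - F_0)/F_0}.  The delta = 0 column is exactly zero by
#' construction; simulation failures are recorded as infinite entries.
#'
#' @param anchor Anchor \linkS4class{ParameterSet} (typically the
#'   epithelial best fit).
#' @param costfn Cost function for the anchor's own phenotype.
#' @param offsets Log2 offsets (default \code{\link{defaultSensitivityOffsets}}).
#' @return A \linkS4class{SensitivityGrid}.
#' @export
sensitivityGrid <- function(anchor, costfn,
                            offsets = defaultSensitivityOffsets()) {
  v <- thetaVec(anchor)
  F0 <- costfn(v)
  if (!is.finite(F0) || F0 <= 0) stop("cost at the anchor must be finite and positive")
  vals <- matrix(NA_real_, length(v), length(offsets),
                 dimnames = list(names(v), as.character(offsets)))
  for (j in seq_along(v)) {
    for (k in seq_along(offsets)) {
      if (offsets[k] == 0) {
        vals[j, k] <- 0
        next
      }
      vj <- v
      vj[j] <- v[j] * 2^offsets[k]
      vals[j, k] <- 100 * (costfn(vj) - F0) / F0
    }
  }
  new("SensitivityGrid", values = vals, offsets = offsets,
      anchor = if (is(anchor, "ParameterSet")) anchor else ParameterSet(v),
      baseCost = F0)
}

#' Paired sensitivity grids for the two phenotypes
#'
#' Both grids scan the same absolute parameter values, anchored at the
#' epithelial best fit: the epithelial grid perturbs the epithelial set
#' under the epithelial cost (its delta = 0 column is identically zero);
#' the mesenchymal grid substitutes \eqn{\theta^{E*}_j 2^\delta} into the
#' mesenchymal best fit under the mesenchymal cost, so its baseline column
#' shows the cost of forcing the epithelial value on the mesenchymal
#' model.
#'
#' @param anchorE Epithelial best-fit \linkS4class{ParameterSet}.
#' @param thetaM Mesenchymal best-fit \linkS4class{ParameterSet}.
#' @param costE,costM Phenotype cost functions.
#' @param offsets Log2 offsets.
#' @return List with elements \code{epithelial} and \code{mesenchymal}
#'   (\linkS4class{SensitivityGrid} each).
#' @export
sensitivityGridPair <- function(anchorE, thetaM, costE, costM,
                                offsets = defaultSensitivityOffsets()) {
  gE <- sensitivityGrid(anchorE, costE, offsets)
  vE <- thetaVec(anchorE)
  vM <- thetaVec(thetaM)
  FM0 <- costM(vM)
  if (!is.finite(FM0) || FM0 <= 0) stop("mesenchymal anchor cost must be finite")
  vals <- matrix(NA_real_, length(vM), length(offsets),
                 dimnames = list(names(vM), as.character(offsets)))
  for (j in seq_along(vM)) {
    for (k in seq_along(offsets)) {
      vj <- vM
      vj[j] <- vE[j] * 2^offsets[k]
      vals[j, k] <- 100 * (costM(vj) - FM0) / FM0
    }
  }
  gM <- new("SensitivityGrid", values = vals, offsets = offsets,
            anchor = if (is(thetaM, "ParameterSet")) thetaM else ParameterSet(vM),
            baseCost = FM0)
  list(epithelial = gE, mesenchymal = gM)
}

#' Reconcile two fitted parameter sets across phenotypes
#'
#' Finds a pair of near-identical parameter sets by minimising the total
#' log2 difference subject to neither phenotype's cost exceeding its
#' fitted bound (times 1 + slack).  Phase 1 greedily merges parameters in
#' ascending order of |log2 difference|, line-searching 11 candidate
#' common values on the log-scale segment between the two fitted values
#' (midpoint outward) and accepting the first that keeps both cost
#' certificates within bounds.  Phase 2 polishes the remaining differing
#' parameters jointly by simplex search under a penalty of 1e6 per unit
#' constraint violation; certificates are recomputed with penalties off
#' and phase 2 is discarded if they violate the bounds.
#'
#' @param thetaE,thetaM Fitted \linkS4class{ParameterSet}s with finite
#'   costs.
#' @param costE,costM Phenotype cost functions.
#' @param slack Relative slack on the cost bounds (default 0.01, the
#'   99-percent-fitness reading; 0 enforces the strict constraints).
#' @param n_candidates Candidate points per phase-1 line search.
#' @param polish_iters Simplex iterations in phase 2.
#' @return A \linkS4class{ReconciliationResult}.
#' @export
reconcileParameters <- function(thetaE, thetaM, costE, costM, slack = 0.01,
                                n_candidates = 11, polish_iters = 200) {
  vE <- thetaVec(thetaE)
  vM <- thetaVec(thetaM)
  FE0 <- costE(vE)
  FM0 <- costM(vM)
  if (!is.finite(FE0) || !is.finite(FM0)) {
    stop("costs at the input parameter sets must be finite")
  }
  boundE <- FE0 * (1 + slack)
  boundM <- FM0 * (1 + slack)

  diffs <- abs(log2(vE) - log2(vM))
  audit <- data.frame(parameter = character(0), log2diff_before = numeric(0),
                      merged = logical(0), value = numeric(0),
                      costE = numeric(0), costM = numeric(0))
  ts <- seq(0, 1, length.out = n_candidates)
  ts <- ts[order(abs(ts - 0.5))]
  curE <- vE
  curM <- vM
  cE <- FE0
  cM <- FM0
  for (j in names(sort(diffs))) {
    if (abs(log2(curE[[j]]) - log2(curM[[j]])) <= 1e-12) {
      audit <- rbind(audit, data.frame(parameter = j, log2diff_before = 0,
                                       merged = TRUE, value = curE[[j]],
                                       costE = cE, costM = cM))
      next
    }
    merged <- FALSE
    for (t in ts) {
      val <- 2^((1 - t) * log2(vE[[j]]) + t * log2(vM[[j]]))
      tryE <- curE; tryE[[j]] <- val
      tryM <- curM; tryM[[j]] <- val
      fE <- costE(tryE)
      if (!is.finite(fE) || fE > boundE) next
      fM <- costM(tryM)
      if (!is.finite(fM) || fM > boundM) next
      curE <- tryE; curM <- tryM; cE <- fE; cM <- fM
      audit <- rbind(audit, data.frame(parameter = j,
                                       log2diff_before = diffs[[j]],
                                       merged = TRUE, value = val,
                                       costE = fE, costM = fM))
      merged <- TRUE
      break
    }
    if (!merged) {
      audit <- rbind(audit, data.frame(parameter = j,
                                       log2diff_before = diffs[[j]],
                                       merged = FALSE, value = NA_real_,
                                       costE = cE, costM = cM))
    }
  }

  J <- names(curE)[abs(log2(curE) - log2(curM)) > 1e-12]
  if (length(J) > 0 && polish_iters > 0) {
    obj <- function(x) {
      k <- length(J)
      pE <- curE; pM <- curM
      pE[J] <- 2^x[seq_len(k)]
      pM[J] <- 2^x[k + seq_len(k)]
      fE <- costE(pE)
      fM <- costM(pM)
      pen <- 1e6 * (max(0, fE - boundE) + max(0, fM - boundM))
      if (!is.finite(pen)) pen <- 1e12
      sum(abs(x[seq_len(k)] - x[k + seq_len(k)])) + pen
    }
    x0 <- c(log2(curE[J]), log2(curM[J]))
    res <- optim(x0, obj, method = "Nelder-Mead",
                 control = list(maxit = polish_iters))
    k <- length(J)
    polE <- curE; polM <- curM
    polE[J] <- 2^res$par[seq_len(k)]
    polM[J] <- 2^res$par[k + seq_len(k)]
    fE <- costE(polE)
    fM <- costM(polM)
    okBounds <- is.finite(fE) && is.finite(fM) && fE <= boundE && fM <= boundM
    okObjective <- sum(abs(log2(polE) - log2(polM))) <
      sum(abs(log2(curE) - log2(curM)))
    if (okBounds && okObjective) {
      curE <- polE; curM <- polM; cE <- fE; cM <- fM
    }
  }

  new("ReconciliationResult",
      thetaE = ParameterSet(curE), thetaM = ParameterSet(curM),
      log2diff = log2(curE) - log2(curM),
      costE = cE, costM = cM, boundE = boundE, boundM = boundM,
      slack = slack, audit = audit)
}

#' Report the parameters still differing after reconciliation
#'
#' @param res A \linkS4class{ReconciliationResult}.
#' @param tol_log2 Difference tolerance in log2 units (default 0.1).
#' @return data.frame (parameter, log2_difference, class) sorted by
#'   descending |log2 difference|; class marks input-associated parameters
#'   (magnitude, delay, decay) versus kinetic ones.
#' @export
diffReport <- function(res, tol_log2 = 0.1) {
  d <- reconciledDifferences(res)
  keep <- abs(d) > tol_log2
  d <- d[keep]
  ord <- order(abs(d), decreasing = TRUE)
  inputPars <- c("I1", "tau1", "d1", "I2", "tau2", "d2")
  data.frame(parameter = names(d)[ord],
             log2_difference = unname(d[ord]),
             class = ifelse(names(d)[ord] %in% inputPars, "input", "kinetic"),
             row.names = NULL)
}
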