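## Full-order partial-correlation network inference.

#' Partial correlation of two variables given a conditioning set
#'
#' The partial correlation \eqn{\rho_{XY\cdot Z}} is the Pearson
#' correlation of the residuals from least-squares regressions (with
#' intercept) of x and of y on the conditioning variables Z.
#'
#' @param x,y Numeric vectors of equal length.
#' @param Z Optional numeric matrix of conditioning variables (columns);
#'   empty or NULL gives the plain Pearson correlation.
#' @return Scalar partial correlation; NaN with a warning when a residual
#'   variance vanishes.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(500); y <- x + rnorm(500); w <- y + rnorm(500)
#' partialCorrelation(x, w, cbind(y))  # near 0: Markov chain
partialCorrelation <- function(x, y, Z = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(Z) || NCOL(Z) == 0 || length(Z) == 0) {
    ex <- x - mean(x)
    ey <- y - mean(y)
  } else {
    Z <- as.matrix(Z)
    stopifnot(nrow(Z) == n)
    if (n < ncol(Z) + 3) stop("need at least |Z| + 3 observations")
    X <- cbind(1, Z)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      warning("rank-deficient conditioning set; dependent columns dropped")
      X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
      qrX <- qr(X)
    }
    ex <- qr.resid(qrX, x)
    ey <- qr.resid(qrX, y)
  }
  vx <- sum(ex^2)
  vy <- sum(ey^2)
  # residuals that vanish to rounding leave the correlation undefined
  tolx <- 1e-12 * sum((x - mean(x))^2)
  toly <- 1e-12 * sum((y - mean(y))^2)
  if (vx <= max(tolx, 0) || vy <= max(toly, 0) || vx == 0 || vy == 0) {
    warning("zero residual variance; partial correlation undefined")
    return(NaN)
  }
  sum(ex * ey) / sqrt(vx * vy)
}

#' Fisher z-transform
#'
#' Variance-stabilising atanh transform of a correlation coefficient.
#'
#' @param rho Correlation value(s) with |rho| < 1.
#' @return atanh(rho).
#' @export
#' @examples
#' fisherZ(0.1)  # 0.100335...
fisherZ <- function(rho) {
  if (any(abs(rho) >= 1, na.rm = TRUE)) {
    stop("|rho| >= 1: Fisher z-transform is infinite")
  }
  atanh(rho)
}

#' Full-order partial-correlation network
#'
#' For every pair of analysis channels, computes the partial correlation
#' conditioning on all remaining channels in the list, assembles the
#' symmetric matrix, Fisher z-transforms it, and calls edges at a magnitude
#' threshold on rho (default 0.1).  Data are expected on the log(1 + x)
#' scale for intensity channels.
#'
#' @param x A \linkS4class{SnapshotSet} or a cells x channels numeric
#'   matrix.
#' @param variables Channels to analyse (default: the six phospho species
#'   when present, otherwise all columns).
#' @param threshold Edge-calling threshold on |rho| (default 0.1).
#' @return A \linkS4class{PartialCorrNetwork}.
#' @export
partialCorrelationMatrix <- function(x, variables = NULL, threshold = 0.1) {
  m <- if (is(x, "SnapshotSet")) {
    if (is.null(variables)) {
      variables <- intersect(measuredSpecies(), rownames(x))
    }
    snapshotMatrix(x, variables)
  } else {
    x <- as.matrix(x)
    if (is.null(variables)) variables <- colnames(x)
    x[, variables, drop = FALSE]
  }
  p <- length(variables)
  stopifnot(p >= 2)
  if (nrow(m) < p + 3) stop("need at least |variables| + 3 cells")
  rho <- diag(1, p)
  dimnames(rho) <- list(variables, variables)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      rho[i, j] <- rho[j, i] <-
        partialCorrelation(m[, i], m[, j], m[, -c(i, j), drop = FALSE])
    }
  }
  z <- matrix(NA_real_, p, p, dimnames = dimnames(rho))
  off <- row(rho) != col(rho)
  z[off] <- atanh(pmin(pmax(rho[off], -1 + 1e-15), 1 - 1e-15))
  pairs <- which(upper.tri(rho), arr.ind = TRUE)
  edges <- data.frame(var1 = variables[pairs[, 1]],
                      var2 = variables[pairs[, 2]],
                      rho = rho[pairs], z = z[pairs])
  edges$passes_threshold <- abs(edges$rho) >= threshold
  new("PartialCorrNetwork", variables = variables, rho = rho, z = z,
      edges = edges, threshold = threshold,
      replicateSD = matrix(numeric(0), 0, 0))
}

#' Per-timepoint partial-correlation dynamics of selected edges
#'
#' For each listed edge and each time point, computes the partial
#' correlation within each replicate's cells (conditioning on all remaining
#' analysis channels), plus the across-replicate mean and sample SD.
#'
#' @param d A \linkS4class{SnapshotSet} on the log(1 + x) scale.
#' @param edges data.frame or 2-column matrix of (var1, var2) channel
#'   pairs.
#' @param variables Conditioning universe (default: the six phospho
#'   species).
#' @param condition Condition analysed (default "stimulated").
#' @return data.frame (var1, var2, time, replicate, rho) in long format
#'   with per-replicate values, plus rows with replicate NA holding the
#'   across-replicate mean and sd columns.
#' @export
edgeDynamics <- function(d, edges, variables = measuredSpecies(),
                         condition = "stimulated") {
  edges <- as.data.frame(edges)
  colnames(edges)[1:2] <- c("var1", "var2")
  cd <- SummarizedExperiment::colData(d)
  sel <- cd$condition == condition
  times <- sort(unique(cd$time[sel]))
  out <- list()
  for (tt in times) {
    reps <- sort(unique(cd$replicate[sel & cd$time == tt]))
    for (e in seq_len(nrow(edges))) {
      v1 <- edges$var1[e]
      v2 <- edges$var2[e]
      rhos <- vapply(reps, function(r) {
        m <- snapshotMatrix(d[, sel & cd$time == tt & cd$replicate == r],
                            variables)
        partialCorrelation(m[, v1], m[, v2],
                           m[, setdiff(variables, c(v1, v2)), drop = FALSE])
      }, numeric(1))
      out[[length(out) + 1]] <-
        data.frame(var1 = v1, var2 = v2, time = tt, replicate = reps,
                   rho = rhos, mean = mean(rhos),
                   sd = if (length(rhos) >= 2) sd(rhos) else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Display ordering of network variables by hierarchical clustering
#'
#' Leaf order of a single-linkage agglomerative dendrogram on Euclidean
#' distances between the variables' rows of the partial-correlation matrix.
#' Ties are broken deterministically by input order (stats::hclust).
#'
#' @param net A \linkS4class{PartialCorrNetwork}.
#' @return Character vector: the variables in display order.
#' @export
clusterOrder <- function(net) {
  v <- net@variables
  if (length(v) == 2) return(v)
  hc <- hclust(dist(net@rho, method = "euclidean"), method = "single")
  v[hc$order]
}

#' Simulate a linear-Gaussian signaling cascade
#'
#' Generates draws from a linear-Gaussian structural model with the
#' canonical chain structure pMEK -> ppERK -> pRSK -> pS6 plus an
#' independent pAKT -> pGSK3B arm.  Used to validate that full-order
#' partial correlation recovers exactly the chain edges.
#'
#' @param n Number of cells.
#' @param seed Integer seed.
#' @param beta Edge coefficient (default 1).
#' @param noise_sd Innovation SD (default 1).
#' @return List with \code{data} (n x 6 matrix, panel channel names) and
#'   \code{edges} (the ground-truth undirected edge pairs).
#' @export
simulateGaussianCascade <- function(n, seed = 1L, beta = 1, noise_sd = 1) {
  set.seed(seed)
  pMEK <- rnorm(n)
  ppERK <- beta * pMEK + rnorm(n, sd = noise_sd)
  pRSK <- beta * ppERK + rnorm(n, sd = noise_sd)
  pS6 <- beta * pRSK + rnorm(n, sd = noise_sd)
  pAKT <- rnorm(n)
  pGSK3B <- beta * pAKT + rnorm(n, sd = noise_sd)
  data <- cbind(pMEK = pMEK, ppERK = ppERK, pRSK = pRSK, pAKT = pAKT,
                pGSK3B = pGSK3B, pS6 = pS6)
  edges <- data.frame(var1 = c("pMEK", "ppERK", "pRSK", "pAKT"),
                      var2 = c("ppERK", "pRSK", "pS6", "pGSK3B"))
  list(data = data, edges = edges)
}

## canonical undirected edge key for set comparisons
edgeKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "~")
}
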