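# Shared fixtures built in code at test time.

smallConfig <- function(label = "epithelial", n = 60, ...) {
  phenotypeConfig(label, n_cells_per_snapshot = n, ...)
}

# tiny snapshot set: known intensities, hand-set annotations
toySnapshot <- function(exprs, time = 0, replicate = 1L,
                        condition = "stimulated", phenotype = "ungated") {
  SnapshotSet(exprs, time = time, replicate = replicate,
              condition = condition, phenotype = phenotype)
}

# brute-force partial correlation: independently coded residual regressions
oraclePartialCorrelation <- function(x, y, Z) {
  if (is.null(Z) || NCOL(Z) == 0) return(cor(x, y))
  fx <- lm(x ~ ., data = data.frame(x = x, Z))
  fy <- lm(y ~ ., data = data.frame(y = y, Z))
  cor(resid(fx), resid(fy))
}

# precision-matrix identity: rho_ij.rest = -p_ij / sqrt(p_ii p_jj)
oraclePrecisionPcor <- function(m) {
  p <- solve(cov(m))
  r <- -p / sqrt(diag(p) %o% diag(p))
  diag(r) <- 1
  dimnames(r) <- list(colnames(m), colnames(m))
  r
}

# double-loop Gaussian-kernel MMD^2
oracleMMD2 <- function(A, B, sigma, biased = TRUE) {
  k <- function(x, y) exp(-sum((x - y)^2) / (2 * sigma^2))
  km <- function(X, Y) {
    s <- 0
    for (i in seq_len(nrow(X))) for (j in seq_len(nrow(Y))) {
      s <- s + k(X[i, ], Y[j, ])
    }
    s / (nrow(X) * nrow(Y))
  }
  kmU <- function(X) {
    s <- 0
    for (i in seq_len(nrow(X))) for (j in seq_len(nrow(X))) {
      if (i != j) s <- s + k(X[i, ], X[j, ])
    }
    s / (nrow(X) * (nrow(X) - 1))
  }
  if (biased) km(A, A) + km(B, B) - 2 * km(A, B)
  else kmU(A) + kmU(B) - 2 * km(A, B)
}
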