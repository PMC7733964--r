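## Preprocessing: viability filtering, phenotype gating, phospho/total
## consistency scaling, subsampling and transforms.

#' Remove dead and apoptotic cells
#'
#' Retains exactly the cells at or below the cleaved-PARP threshold; cells
#' with more than \code{threshold} counts are removed as dead or apoptotic.
#'
#' @param s A \linkS4class{SnapshotSet}.
#' @param threshold Counts threshold (default 20).
#' @param channel Viability channel name (default "cPARP").
#' @return The filtered \code{SnapshotSet} (with a warning if empty).
#' @export
#' @examples
#' # cells with cPARP counts {0, 20, 21} -> the first two are retained
filterDead <- function(s, threshold = 20, channel = "cPARP") {
  if (!channel %in% rownames(s)) {
    stop("viability channel not present: ", channel)
  }
  keep <- SummarizedExperiment::assay(s, "exprs")[channel, ] <= threshold
  if (!any(keep)) warning("all cells removed by the dead-cell filter")
  s[, keep]
}

#' Gate specification
#'
#' @param marker_high,marker_low Channel names.
#' @param threshold_high,threshold_low Positive intensity thresholds.
#' @return A list of class "GateSpec".
#' @export
gateSpec <- function(marker_high, threshold_high, marker_low, threshold_low) {
  if (threshold_high <= 0 || threshold_low <= 0) {
    stop("gate thresholds must be positive")
  }
  structure(list(marker_high = marker_high, threshold_high = threshold_high,
                 marker_low = marker_low, threshold_low = threshold_low),
            class = "GateSpec")
}

#' Default phenotype gates
#'
#' Epithelial cells are gated E-cadherin-high / vimentin-low and
#' mesenchymal cells E-cadherin-low / vimentin-high.  The default cutoff
#' (25 intensity units on both markers) sits at the geometric midpoint of
#' the synthetic generator's bimodal marker modes; with real data the
#' cutoffs are chosen from the marker distributions and passed explicitly.
#'
#' @param phenotype "epithelial" or "mesenchymal".
#' @param cutoff Threshold applied to both markers.
#' @return A \code{\link{gateSpec}}.
#' @export
defaultGate <- function(phenotype = c("epithelial", "mesenchymal"),
                        cutoff = 25) {
  phenotype <- match.arg(phenotype)
  if (phenotype == "epithelial") {
    gateSpec("Ecad", cutoff, "Vim", cutoff)
  } else {
    gateSpec("Vim", cutoff, "Ecad", cutoff)
  }
}

#' Gate a phenotype subpopulation
#'
#' Retains cells with the high marker at or above its threshold and the low
#' marker strictly below its threshold, and sets the phenotype label.
#'
#' @param s A \linkS4class{SnapshotSet}.
#' @param gate A \code{\link{gateSpec}}.
#' @param label Phenotype label to assign (default: kept unchanged).
#' @return The gated \code{SnapshotSet}.
#' @export
gatePhenotype <- function(s, gate, label = NULL) {
  stopifnot(inherits(gate, "GateSpec"))
  m <- SummarizedExperiment::assay(s, "exprs")
  missing <- setdiff(c(gate$marker_high, gate$marker_low), rownames(m))
  if (length(missing)) {
    stop("gate channel(s) not present: ", paste(missing, collapse = ", "))
  }
  keep <- m[gate$marker_high, ] >= gate$threshold_high &
    m[gate$marker_low, ] < gate$threshold_low
  out <- s[, keep]
  if (!is.null(label)) {
    SummarizedExperiment::colData(out)$phenotype <- label
  }
  out
}

#' Scale phospho channels to respect their total-protein partners
#'
#' The total units of a protein must be at least the units of its
#' phosphorylated form.  Each phospho channel is multiplied by one global
#' factor (per channel, pooled over all cells of the set) chosen so that a
#' configured quantile of the per-cell phospho/total ratio is at most 1;
#' factors never exceed 1 (already-consistent data are left untouched).
#' Residual violating cells are clamped to \code{(1 - eps) * total}.
#'
#' @param d A \linkS4class{SnapshotSet} whose phospho channels declare
#'   total-channel partners in \code{rowData}.
#' @param ratio_quantile Quantile of the ratio forced to be <= 1
#'   (default 0.999).
#' @param eps Clamp margin (default 1e-6).
#' @return List with elements \code{data} (the scaled \code{SnapshotSet})
#'   and \code{factors} (named per-channel scale report).
#' @export
scalePhosphoToTotal <- function(d, ratio_quantile = 0.999, eps = 1e-6) {
  m <- SummarizedExperiment::assay(d, "exprs")
  rd <- SummarizedExperiment::rowData(d)
  ph <- rownames(d)[rd$role == "phospho"]
  factors <- setNames(rep(1, length(ph)), ph)
  for (p in ph) {
    tot <- rd[p, "partner"]
    if (is.na(tot) || !tot %in% rownames(m)) {
      stop("no total-channel partner declared for ", p)
    }
    if (all(m[tot, ] == 0)) stop("total channel entirely zero: ", tot)
    q <- quantile(m[p, ] / m[tot, ], ratio_quantile, names = FALSE)
    factors[p] <- min(1, 1 / q)
    m[p, ] <- m[p, ] * factors[p]
    m[p, ] <- pmin(m[p, ], (1 - eps) * m[tot, ])
  }
  SummarizedExperiment::assay(d, "exprs") <- m
  list(data = d, factors = factors)
}

#' Subsample cells across replicates
#'
#' For each time point (within condition and phenotype), draws \code{n}
#' cells without replacement from the cells pooled over replicates,
#' allocated to replicates proportionally to their cell counts (largest
#' remainder method).  Reproducible under \code{seed}.
#'
#' @param d A \linkS4class{SnapshotSet}.
#' @param n Cells per time point (>= 1).  If a group holds fewer cells,
#'   all are taken with a warning.
#' @param seed Integer seed.
#' @return The subsampled \code{SnapshotSet}.
#' @export
subsampleAcrossReplicates <- function(d, n, seed = 1L) {
  stopifnot(n >= 1)
  cd <- SummarizedExperiment::colData(d)
  grp <- interaction(cd$time, cd$condition, cd$phenotype, drop = TRUE)
  set.seed(seed)
  keep <- logical(ncol(d))
  for (g in levels(grp)) {
    idx <- which(grp == g)
    if (length(idx) <= n) {
      if (length(idx) < n) {
        warning("group ", g, " has only ", length(idx), " cells; taking all")
      }
      keep[idx] <- TRUE
      next
    }
    reps <- cd$replicate[idx]
    counts <- table(reps)
    exact <- n * as.numeric(counts) / length(idx)
    alloc <- floor(exact)
    rem <- n - sum(alloc)
    if (rem > 0) {
      extra <- order(exact - alloc, decreasing = TRUE)[seq_len(rem)]
      alloc[extra] <- alloc[extra] + 1
    }
    for (j in seq_along(counts)) {
      ridx <- idx[reps == names(counts)[j]]
      keep[sample(ridx, alloc[j])] <- TRUE
    }
  }
  d[, keep]
}

#' Log-transform snapshot intensities
#'
#' \code{log1p} applies the natural log(1 + x) used for partial-correlation
#' analysis; \code{log2} applies log2(x + offset) used for
#' distribution-matching fits and marginal displays.
#'
#' @param s A \linkS4class{SnapshotSet} with non-negative intensities.
#' @param kind "log1p" or "log2".
#' @param offset Offset for the log2 variant (default 1).
#' @return The transformed \code{SnapshotSet}.
#' @export
logTransform <- function(s, kind = c("log1p", "log2"), offset = 1) {
  kind <- match.arg(kind)
  m <- SummarizedExperiment::assay(s, "exprs")
  if (any(m < 0)) stop("negative intensities cannot be log-transformed")
  m <- if (kind == "log1p") log1p(m) else log2(m + offset)
  SummarizedExperiment::assay(s, "exprs") <- m
  s
}

#' Pool baseline cells for model initialisation
#'
#' Extracts the cells of the pre-stimulation snapshots (t <= 0, stimulated
#' condition) as a \linkS4class{CellPopulation}: measured totals and
#' baseline phospho levels per cell, baselines clamped into the interior of
#' (0, total).
#'
#' @param d A preprocessed \linkS4class{SnapshotSet}.
#' @param eps Clamp margin (default 1e-6).
#' @return A \linkS4class{CellPopulation}.
#' @export
baselineCells <- function(d, eps = 1e-6) {
  cd <- SummarizedExperiment::colData(d)
  sel <- cd$time <= 0 & cd$condition == "stimulated"
  if (!any(sel)) stop("no pre-stimulation snapshots (t <= 0) present")
  sub <- d[, sel]
  tot <- snapshotMatrix(sub, totalChannels())
  ph <- snapshotMatrix(sub, measuredSpecies())
  colnames(tot) <- measuredSpecies()
  ph <- pmin(pmax(ph, eps * tot), (1 - eps) * tot)
  CellPopulation(tot, ph)
}
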