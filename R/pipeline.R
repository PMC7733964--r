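## End-to-end orchestration of the analysis stages.

#' Analysis configuration
#'
#' Central configuration for \code{\link{runAnalysis}}; every stage reads
#' its settings from here so a run is fully described by (config, seed).
#'
#' @param time_grid Sampling times (minutes relative to stimulation).
#' @param n_cells_per_snapshot,n_replicates Synthetic generator scale.
#' @param dead_threshold Cleaved-PARP counts cutoff.
#' @param gate_cutoff Phenotype marker gate cutoff.
#' @param pcor_threshold Partial-correlation edge threshold.
#' @param subsample_n Cells per time point pooled across replicates.
#' @param budget Optimizer budget ("desk" or "full").
#' @param slack Reconciliation cost slack.
#' @param sensitivity_offsets Log2 grid offsets.
#' @param diff_tol_log2 Differing-parameter tolerance.
#' @param fit_settings Optional overrides of the budget's search settings
#'   (see \code{\link{fitBudget}}), e.g. for quick smoke runs.
#' @return Validated list of class "AnalysisConfig".
#' @export
analysisConfig <- function(time_grid = defaultTimeGrid(),
                           n_cells_per_snapshot = 1000,
                           n_replicates = 3,
                           dead_threshold = 20,
                           gate_cutoff = 25,
                           pcor_threshold = 0.1,
                           subsample_n = 500,
                           budget = "desk",
                           slack = 0.01,
                           sensitivity_offsets = defaultSensitivityOffsets(),
                           diff_tol_log2 = 0.1,
                           fit_settings = list()) {
  cfg <- list(time_grid = time_grid,
              n_cells_per_snapshot = n_cells_per_snapshot,
              n_replicates = n_replicates,
              dead_threshold = dead_threshold,
              gate_cutoff = gate_cutoff,
              pcor_threshold = pcor_threshold,
              subsample_n = subsample_n,
              budget = budget,
              slack = slack,
              sensitivity_offsets = sensitivity_offsets,
              diff_tol_log2 = diff_tol_log2,
              fit_settings = fit_settings)
  validateConfig(cfg)
  structure(cfg, class = "AnalysisConfig")
}

validateConfig <- function(cfg) {
  need <- c("time_grid", "n_cells_per_snapshot", "n_replicates",
            "dead_threshold", "gate_cutoff", "pcor_threshold", "subsample_n",
            "budget", "slack", "sensitivity_offsets", "diff_tol_log2")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("config is missing field(s): ", paste(missing, collapse = ", "))
  }
  if (!any(cfg$time_grid <= 0)) stop("config field time_grid needs a t <= 0 point")
  if (!cfg$budget %in% c("desk", "full")) {
    stop("config field budget must be 'desk' or 'full'")
  }
  if (cfg$slack < 0) stop("config field slack must be >= 0")
  invisible(TRUE)
}

## md5 of the serialized config (base tools only)
configHash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(cfg, file = f)
  unname(tools::md5sum(f))
}

#' Run the full analysis end to end
#'
#' Generates two-phenotype synthetic data from the ground-truth presets,
#' preprocesses them (dead-cell filter, gating, phospho/total scaling,
#' subsampling), infers partial-correlation networks, fits the mechanistic
#' model to each phenotype by distribution matching, computes the paired
#' sensitivity grids, reconciles the two fitted parameter sets, and
#' reports the remaining differing parameters.  When \code{outDir} is
#' given, every artifact family is written as plain text with a provenance
#' manifest (config hash + seed).
#'
#' @param config An \code{\link{analysisConfig}}.
#' @param seed Master seed; stage seeds are derived from it.
#' @param outDir Optional output directory.
#' @param verbose Log stage boundaries.
#' @return List with the per-stage results (data, networks, fits, grids,
#'   reconciliation, diff report).
#' @export
runAnalysis <- function(config = analysisConfig(), seed = 1L, outDir = NULL,
                        verbose = TRUE) {
  validateConfig(config)
  hash <- configHash(config)
  prov <- c(config_hash = hash, seed = as.character(seed))
  say <- function(...) if (verbose) message("[discofit] ", ...)
  gt <- groundTruthPresets()
  phenos <- c("epithelial", "mesenchymal")

  say("stage 1/6: synthetic data generation")
  raw <- lapply(phenos, function(ph) {
    cfg <- phenotypeConfig(ph, n_cells_per_snapshot = config$n_cells_per_snapshot)
    generateTimecourse(gt[[paste0("theta_", ph)]], cfg,
                       time_grid = config$time_grid,
                       seed = deriveSeed(seed, match(ph, phenos)),
                       n_replicates = config$n_replicates)
  })
  names(raw) <- phenos

  say("stage 2/6: preprocessing")
  prep <- lapply(phenos, function(ph) {
    d <- filterDead(raw[[ph]], threshold = config$dead_threshold)
    d <- gatePhenotype(d, defaultGate(ph, config$gate_cutoff), label = ph)
    d <- scalePhosphoToTotal(d)$data
    subsampleAcrossReplicates(d, config$subsample_n,
                              seed = deriveSeed(seed, 100 + match(ph, phenos)))
  })
  names(prep) <- phenos

  say("stage 3/6: partial-correlation network inference")
  networks <- lapply(prep, function(d) {
    partialCorrelationMatrix(logTransform(d, "log1p"),
                             threshold = config$pcor_threshold)
  })

  say("stage 4/6: distribution-matching fits (budget: ", config$budget, ")")
  fits <- lapply(phenos, function(ph) {
    fitPhenotype(prep[[ph]], budget = config$budget,
                 seed = deriveSeed(seed, 200 + match(ph, phenos)),
                 settings = if (is.null(config$fit_settings)) list()
                            else config$fit_settings)
  })
  names(fits) <- phenos

  say("stage 5/6: sensitivity grids")
  costs <- lapply(phenos, function(ph) {
    cells <- baselineCells(prep[[ph]])
    nmax <- min(length(cells), 150)
    set.seed(deriveSeed(seed, 300 + match(ph, phenos)))
    makeCostFunction(prep[[ph]], cells[sample(length(cells), nmax)])
  })
  names(costs) <- phenos
  grids <- sensitivityGridPair(fittedParameters(fits$epithelial),
                               fittedParameters(fits$mesenchymal),
                               costs$epithelial, costs$mesenchymal,
                               offsets = config$sensitivity_offsets)

  say("stage 6/6: reconciliation")
  recon <- reconcileParameters(fittedParameters(fits$epithelial),
                               fittedParameters(fits$mesenchymal),
                               costs$epithelial, costs$mesenchymal,
                               slack = config$slack)
  report <- diffReport(recon, tol_log2 = config$diff_tol_log2)

  out <- list(config = config, config_hash = hash, seed = seed, data = prep,
              networks = networks, fits = fits, grids = grids,
              reconciliation = recon, diff_report = report)
  if (!is.null(outDir)) writeArtifacts(out, outDir, prov)
  out
}

writeArtifacts <- function(res, outDir, prov) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (ph in names(res$data)) {
    writeSnapshotSet(res$data[[ph]], file.path(outDir, paste0("data_", ph)),
                     provenance = prov)
    net <- res$networks[[ph]]
    write.table(net@edges, file.path(outDir, paste0("edges_", ph, ".tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.csv(networkRho(net), file.path(outDir, paste0("pcor_", ph, ".csv")))
    writeLines(clusterOrder(net),
               file.path(outDir, paste0("order_", ph, ".txt")))
    writeParameterSet(fittedParameters(res$fits[[ph]]),
                      file.path(outDir, paste0("fit_", ph, ".txt")))
    write.csv(fitTrace(res$fits[[ph]]),
              file.path(outDir, paste0("trace_", ph, ".csv")),
              row.names = FALSE)
    write.csv(sensitivityValues(res$grids[[ph]]),
              file.path(outDir, paste0("sensitivity_", ph, ".csv")))
  }
  rec <- res$reconciliation
  recTab <- data.frame(parameter = modelParameterNames(),
                       epithelial = parameterValues(rec@thetaE),
                       mesenchymal = parameterValues(rec@thetaM),
                       log2_difference = rec@log2diff)
  write.csv(recTab, file.path(outDir, "reconciliation.csv"), row.names = FALSE)
  write.csv(res$diff_report, file.path(outDir, "diff_report.csv"),
            row.names = FALSE)
  write.dcf(data.frame(config_hash = prov[["config_hash"]],
                       seed = prov[["seed"]],
                       package_version = as.character(
                         utils::packageVersion("discofit"))),
            file.path(outDir, "PROVENANCE.dcf"))
  invisible(outDir)
}
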