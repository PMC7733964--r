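## Plain-text I/O: snapshot CSV + manifest layout, parameter tables.

#' Write a SnapshotSet as per-snapshot CSV files with a manifest
#'
#' One CSV per snapshot (rows = cells, columns = channels) plus a
#' \code{MANIFEST.dcf} (Debian-control structured key-value text) recording
#' time, replicate, condition, phenotype and provenance per file.
#'
#' @param d A \linkS4class{SnapshotSet}.
#' @param dir Output directory (created if needed).
#' @param provenance Optional named character vector written into every
#'   manifest block (e.g. config hash, seed).
#' @return Invisibly, the manifest data.frame.
#' @export
writeSnapshotSet <- function(d, dir, provenance = character(0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cd <- SummarizedExperiment::colData(d)
  key <- interaction(cd$time, cd$replicate, cd$condition, cd$phenotype,
                     drop = TRUE)
  rows <- list()
  for (g in levels(key)) {
    idx <- which(key == g)
    file <- sprintf("snapshot_t%s_r%d_%s_%s.csv",
                    gsub("-", "m", format(cd$time[idx[1]])),
                    cd$replicate[idx[1]], cd$condition[idx[1]],
                    cd$phenotype[idx[1]])
    write.csv(as.data.frame(snapshotMatrix(d[, idx])),
              file.path(dir, file), row.names = FALSE)
    rows[[g]] <- data.frame(file = file, time = cd$time[idx[1]],
                            replicate = cd$replicate[idx[1]],
                            condition = cd$condition[idx[1]],
                            phenotype = cd$phenotype[idx[1]],
                            n_cells = length(idx))
  }
  manifest <- do.call(rbind, rows)
  if (length(provenance)) {
    for (nm in names(provenance)) manifest[[nm]] <- provenance[[nm]]
  }
  write.dcf(manifest, file.path(dir, "MANIFEST.dcf"))
  invisible(manifest)
}

#' Read a SnapshotSet from the CSV + manifest layout
#'
#' @param dir Directory written by \code{\link{writeSnapshotSet}}.
#' @return A \linkS4class{SnapshotSet}.
#' @export
readSnapshotSet <- function(dir) {
  mf <- file.path(dir, "MANIFEST.dcf")
  if (!file.exists(mf)) stop("no MANIFEST.dcf in ", dir)
  manifest <- as.data.frame(read.dcf(mf), stringsAsFactors = FALSE)
  blocks <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- as.matrix(read.csv(file.path(dir, manifest$file[i]),
                            check.names = FALSE))
    list(exprs = m, time = as.numeric(manifest$time[i]),
         replicate = as.integer(manifest$replicate[i]),
         condition = manifest$condition[i],
         phenotype = manifest$phenotype[i])
  })
  exprs <- t(do.call(rbind, lapply(blocks, `[[`, "exprs")))
  n <- vapply(blocks, function(b) nrow(b$exprs), integer(1))
  SnapshotSet(exprs,
              time = rep(vapply(blocks, `[[`, numeric(1), "time"), n),
              replicate = rep(vapply(blocks, `[[`, integer(1), "replicate"), n),
              condition = rep(vapply(blocks, `[[`, character(1), "condition"), n),
              phenotype = rep(vapply(blocks, `[[`, character(1), "phenotype"), n))
}

#' Serialize a ParameterSet as flat structured text
#'
#' @param theta A \linkS4class{ParameterSet}.
#' @param file Output path ("name value" per line).
#' @return Invisibly, \code{file}.
#' @export
writeParameterSet <- function(theta, file) {
  v <- parameterValues(theta)
  writeLines(sprintf("%s %.17g", names(v), v), file)
  invisible(file)
}

#' @rdname writeParameterSet
#' @export
readParameterSet <- function(file) {
  tab <- read.table(file, col.names = c("name", "value"))
  ParameterSet(setNames(tab$value, tab$name))
}

#' Export ensemble trajectories as long-format CSV
#'
#' @param res An \linkS4class{EnsembleResult}.
#' @param file Output path (columns cell, time, species, value).
#' @return Invisibly, \code{file}.
#' @export
writeTrajectories <- function(res, file) {
  st <- res@states
  d <- dim(st)
  long <- data.frame(
    cell = rep(seq_len(d[1]), times = d[2] * d[3]),
    time = rep(res@times, each = d[1] * d[2]),
    species = rep(rep(measuredSpecies(), each = d[1]), times = d[3]),
    value = as.numeric(st))
  write.csv(long, file, row.names = FALSE)
  invisible(file)
}
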