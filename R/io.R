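# Tab-delimited readers/writers for all pipeline artifacts. Numbers are
# written with full double precision so files round-trip without loss.

.writeTsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' Read and write GPR-style spot tables
#'
#' Tab-delimited with columns Block, Row, Column, Probe_ID, F635_Mean (Cy5)
#' and F532_Mean (Cy3).
#'
#' @param spots spot data.frame (one sample).
#' @param path file path.
#' @return \code{readSpotTable} returns the spot data.frame.
#' @export
writeSpotTable <- function(spots, path) .writeTsv(spots, path)

#' @rdname writeSpotTable
#' @export
readSpotTable <- function(path) {
  df <- .readTsv(path)
  need <- c("Probe_ID", "F635_Mean", "F532_Mean")
  if (!all(need %in% colnames(df)))
    stop("spot table missing column(s): ",
         paste(setdiff(need, colnames(df)), collapse = ", "))
  df
}

#' Read and write the probe manifest
#' @param manifest data.frame probe_id, species, genus, family, order.
#' @param path file path.
#' @export
writeManifest <- function(manifest, path) .writeTsv(manifest, path)

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  df <- .readTsv(path)
  need <- c("probe_id", "species", "genus", "family", "order")
  if (!all(need %in% colnames(df)))
    stop("manifest missing column(s): ",
         paste(setdiff(need, colnames(df)), collapse = ", "))
  df
}

#' Read and write sample metadata
#' @param metadata data.frame with sample_id, group and cytokine columns.
#' @param path file path.
#' @export
writeMetadata <- function(metadata, path) .writeTsv(metadata, path)

#' @rdname writeMetadata
#' @export
readMetadata <- function(path) .readTsv(path)

#' Read and write qPCR Ct tables
#' @param ct data.frame sample_id, target, ct, censored.
#' @param path file path.
#' @export
writeCtTable <- function(ct, path) .writeTsv(ct, path)

#' @rdname writeCtTable
#' @export
readCtTable <- function(path) {
  df <- .readTsv(path)
  df$censored <- as.logical(df$censored)
  df
}

#' Write a simulated cohort to disk
#'
#' Lays out \code{spots/<sample_id>.tsv}, \code{manifest.tsv},
#' \code{metadata.tsv} and \code{ct.tsv} under \code{dir}.
#'
#' @param sim a [SimulatedCohort-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(sim, dir) {
  stopifnot(is(sim, "SimulatedCohort"))
  dir.create(file.path(dir, "spots"), recursive = TRUE, showWarnings = FALSE)
  for (sid in names(sim@spotTables))
    writeSpotTable(sim@spotTables[[sid]],
                   file.path(dir, "spots", paste0(sid, ".tsv")))
  writeManifest(sim@manifest, file.path(dir, "manifest.tsv"))
  writeMetadata(sim@sampleMetadata, file.path(dir, "metadata.tsv"))
  writeCtTable(sim@ctTable, file.path(dir, "ct.tsv"))
  invisible(dir)
}

#' Read a directory of spot tables
#'
#' @param dir directory containing one TSV per sample; file names (minus
#'   extension) become sample ids.
#' @return named list of spot data.frames.
#' @export
readSpotTables <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files)) stop("no .tsv spot tables found in ", dir)
  out <- lapply(files, readSpotTable)
  names(out) <- sub("\\.tsv$", "", basename(files))
  out
}

#' Write and read an AbundanceExperiment as TSV
#'
#' Writes \code{abundance.tsv} and \code{detected.tsv} (samples in rows,
#' taxa in columns) plus \code{taxonomy.tsv} under \code{dir};
#' \code{readAbundance} reconstructs the object.
#'
#' @param x an [AbundanceExperiment-class].
#' @param dir directory.
#' @export
writeAbundance <- function(x, dir) {
  stopifnot(is(x, "AbundanceExperiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ab <- data.frame(sample_id = colnames(x), t(abundances(x)),
                   check.names = FALSE)
  de <- data.frame(sample_id = colnames(x), t(detectionCalls(x)),
                   check.names = FALSE)
  .writeTsv(ab, file.path(dir, "abundance.tsv"))
  .writeTsv(de, file.path(dir, "detected.tsv"))
  tx <- taxonomy(x)
  tx <- cbind(data.frame(taxon = rownames(x)), tx)
  .writeTsv(tx, file.path(dir, "taxonomy.tsv"))
  invisible(dir)
}

#' @rdname writeAbundance
#' @export
readAbundance <- function(dir) {
  ab <- .readTsv(file.path(dir, "abundance.tsv"))
  de <- .readTsv(file.path(dir, "detected.tsv"))
  tx <- .readTsv(file.path(dir, "taxonomy.tsv"))
  samples <- ab$sample_id
  m <- t(as.matrix(ab[, -1, drop = FALSE]))
  colnames(m) <- samples
  d <- t(as.matrix(de[, -1, drop = FALSE]) > 0)
  colnames(d) <- samples
  mode(d) <- "logical"
  rn <- tx$taxon
  taxdf <- tx[, setdiff(colnames(tx), "taxon"), drop = FALSE]
  rownames(m) <- rownames(d) <- rn
  AbundanceExperiment(m[rn, , drop = FALSE], d[rn, , drop = FALSE],
                      taxonomy = taxdf)
}
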