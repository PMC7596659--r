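#' Extract the relative-abundance matrix
#'
#' @param x an [AbundanceExperiment-class].
#' @return numeric matrix, taxa in rows and samples in columns.
#' @export
abundances <- function(x) {
  stopifnot(is(x, "AbundanceExperiment"))
  assay(x, "abundance")
}

#' Extract the logical detection-call matrix
#'
#' @param x an [AbundanceExperiment-class].
#' @return logical matrix parallel to [abundances()].
#' @export
detectionCalls <- function(x) {
  stopifnot(is(x, "AbundanceExperiment"))
  assay(x, "detected")
}

#' Extract the taxonomy table
#'
#' @param x an [AbundanceExperiment-class].
#' @return data.frame of lineage columns, one row per taxon.
#' @export
taxonomy <- function(x) {
  stopifnot(is(x, "AbundanceExperiment"))
  as.data.frame(rowData(x))
}

#' Extract per-sample group labels
#'
#' @param x an [AbundanceExperiment-class] whose \code{colData} has a
#'   \code{group} column, or a [SimulatedCohort-class].
#' @return factor of group labels.
#' @export
sampleGroups <- function(x) {
  if (is(x, "SimulatedCohort")) return(x@truth@groupAssignment)
  stopifnot(is(x, "AbundanceExperiment"))
  if (!"group" %in% colnames(colData(x)))
    stop("colData(x) has no 'group' column; attach metadata first")
  factor(colData(x)$group)
}

#' Attach sample metadata to an AbundanceExperiment
#'
#' Joins a metadata table (as produced by [renderMetadata()] or read with
#' [readMetadata()]) onto \code{colData} by \code{sample_id}.
#'
#' @param x an [AbundanceExperiment-class].
#' @param metadata data.frame with a \code{sample_id} column.
#' @return \code{x} with metadata columns merged into \code{colData}.
#' @export
attachMetadata <- function(x, metadata) {
  stopifnot(is(x, "AbundanceExperiment"), "sample_id" %in% colnames(metadata))
  idx <- match(colnames(x), metadata$sample_id)
  if (anyNA(idx))
    stop("metadata missing sample(s): ",
         paste(colnames(x)[is.na(idx)], collapse = ", "))
  md <- metadata[idx, setdiff(colnames(metadata), "sample_id"), drop = FALSE]
  colData(x) <- cbind(colData(x)[, setdiff(colnames(colData(x)), colnames(md)),
                                 drop = FALSE],
                      DataFrame(md, row.names = colnames(x)))
  x
}

#' Ground-truth accessors for a simulated cohort
#'
#' @param x a [SimulatedCohort-class].
#' @return \code{plantedDifferential}: data.frame of planted differential
#'   species with fold-changes; \code{plantedAbundance}: species-by-sample
#'   matrix of true per-sample relative abundances.
#' @export
plantedDifferential <- function(x) {
  stopifnot(is(x, "SimulatedCohort"))
  x@truth@differentialSpecies
}

#' @rdname plantedDifferential
#' @export
plantedAbundance <- function(x) {
  stopifnot(is(x, "SimulatedCohort"))
  x@truth@sampleAbundance
}
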