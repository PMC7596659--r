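#' @import methods
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData `colData<-`
#' @importFrom stats sd median setNames
NULL

#' AbundanceExperiment: species-by-sample relative abundances with detection calls
#'
#' Container for quantified phylogenetic-microarray data. Extends
#' \linkS4class{SummarizedExperiment} with two mandatory assays:
#' \describe{
#'   \item{\code{abundance}}{relative abundances in \code{[0, 1]}; each sample
#'     (column) sums to 1 over its positively detected taxa, or to 0 when no
#'     taxon was called positive on that array.}
#'   \item{\code{detected}}{logical detection calls from the two-pass
#'     intensity/ratio filter; non-detected taxa carry abundance exactly 0.}
#' }
#' \code{rowData} holds the taxonomy (species, genus, family, order) at the
#' current aggregation rank; \code{colData} holds sample metadata. Per-sample
#' detection reports (background, baseline ratio, per-species flags) are stored
#' in \code{metadata(x)$detection_reports}.
#'
#' @seealso [quantifyCohort()], [aggregateToRank()]
#' @export
setClass("AbundanceExperiment", contains = "SummarizedExperiment")

.validAbundanceExperiment <- function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("abundance", "detected") %in% an))
    return("assays must include 'abundance' and 'detected'")
  ab <- assay(object, "abundance")
  det <- assay(object, "detected")
  if (!is.numeric(ab) || any(ab < 0, na.rm = TRUE))
    msg <- c(msg, "'abundance' must be non-negative numeric")
  if (!is.logical(det))
    msg <- c(msg, "'detected' must be logical")
  if (is.numeric(ab) && is.logical(det)) {
    if (any(ab[!det] != 0))
      msg <- c(msg, "non-detected taxa must have abundance exactly 0")
    cs <- colSums(ab)
    bad <- abs(cs - 1) > 1e-9 & abs(cs) > 1e-9
    if (any(bad))
      msg <- c(msg, "each sample must sum to 1 over detected taxa (or 0)")
  }
  if (length(msg)) msg else TRUE
}
setValidity("AbundanceExperiment", .validAbundanceExperiment)

#' Construct an AbundanceExperiment
#'
#' @param abundance numeric matrix, taxa in rows, samples in columns.
#' @param detected logical matrix of the same shape (defaults to
#'   \code{abundance > 0}).
#' @param taxonomy data.frame of lineage columns, one row per taxon.
#' @param sampleData data.frame of per-sample covariates, one row per sample.
#' @param detectionReports optional list of per-sample detection report
#'   data.frames, stored in \code{metadata()}.
#' @return An [AbundanceExperiment-class] object.
#' @export
AbundanceExperiment <- function(abundance, detected = abundance > 0,
                                taxonomy = NULL, sampleData = NULL,
                                detectionReports = NULL) {
  stopifnot(is.matrix(abundance), all(dim(abundance) == dim(detected)))
  if (is.null(rownames(abundance)))
    rownames(abundance) <- sprintf("taxon%03d", seq_len(nrow(abundance)))
  if (is.null(colnames(abundance)))
    colnames(abundance) <- sprintf("S%03d", seq_len(ncol(abundance)))
  dimnames(detected) <- dimnames(abundance)
  rd <- if (is.null(taxonomy)) DataFrame(row.names = rownames(abundance))
        else DataFrame(taxonomy, row.names = rownames(abundance))
  cd <- if (is.null(sampleData)) DataFrame(row.names = colnames(abundance))
        else DataFrame(sampleData, row.names = colnames(abundance))
  se <- SummarizedExperiment(
    assays = list(abundance = abundance, detected = detected),
    rowData = rd, colData = cd)
  out <- new("AbundanceExperiment", se)
  if (!is.null(detectionReports)) metadata(out)$detection_reports <- detectionReports
  validObject(out)
  out
}

#' CommunityTruth: planted ground truth of a simulated gut community
#'
#' Holds the latent community a synthetic cohort is generated from: the
#' species pool, baseline composition, which species carry a group effect and
#' at what fold-change, the per-sample group assignment, and how serum
#' cytokines are coupled to species abundances.
#'
#' @slot speciesNames character vector of taxon labels.
#' @slot baseAbundance numeric, relative abundances summing to 1 (absent
#'   species are exactly 0).
#' @slot differentialSpecies data.frame with columns \code{species} and
#'   \code{fold_change} (strictly positive; >1 means enriched in ALL).
#' @slot groupAssignment factor of per-sample labels in \{ALL, NC\}.
#' @slot cytokineCoupling data.frame with columns \code{cytokine},
#'   \code{species}, \code{intercept}, \code{slope}, \code{noise_sd}.
#' @slot sampleAbundance species-by-sample matrix of realised per-sample true
#'   relative abundances (group fold-change and between-subject variation
#'   applied, columns re-normalised to 1); all rendered artifacts — spots,
#'   cytokines, Ct values — derive from this one realisation.
#' @export
setClass("CommunityTruth", representation(
  speciesNames = "character",
  baseAbundance = "numeric",
  differentialSpecies = "data.frame",
  groupAssignment = "factor",
  cytokineCoupling = "data.frame",
  sampleAbundance = "matrix"))

setValidity("CommunityTruth", function(object) {
  msg <- character()
  if (length(object@baseAbundance) != length(object@speciesNames))
    msg <- c(msg, "baseAbundance and speciesNames lengths differ")
  if (abs(sum(object@baseAbundance) - 1) > 1e-9)
    msg <- c(msg, "baseAbundance must sum to 1")
  if (any(object@baseAbundance < 0))
    msg <- c(msg, "baseAbundance must be non-negative")
  ds <- object@differentialSpecies
  if (nrow(ds)) {
    if (!all(ds$species %in% object@speciesNames))
      msg <- c(msg, "differential species must be in speciesNames")
    if (any(ds$fold_change <= 0))
      msg <- c(msg, "fold-changes must be strictly positive")
  }
  if (!all(levels(object@groupAssignment) %in% c("ALL", "NC")))
    msg <- c(msg, "groups must be ALL/NC")
  sa <- object@sampleAbundance
  if (nrow(sa) != length(object@speciesNames) ||
      ncol(sa) != length(object@groupAssignment))
    msg <- c(msg, "sampleAbundance must be species x samples")
  else if (any(abs(colSums(sa) - 1) > 1e-9))
    msg <- c(msg, "sampleAbundance columns must sum to 1")
  if (length(msg)) msg else TRUE
})

#' SimulatedCohort: a complete synthetic microarray study
#'
#' Bundle of all artifacts rendered from one [CommunityTruth-class]:
#' per-sample spot-level two-channel intensity tables, the probe manifest,
#' sample metadata with a cytokine panel, and a qPCR Ct table.
#'
#' @slot truth the [CommunityTruth-class] the cohort was rendered from.
#' @slot config the simulation configuration list (see [simulationConfig()]).
#' @slot spotTables named list of GPR-style spot data.frames, one per sample.
#' @slot manifest data.frame probe_id, species, genus, family, order.
#' @slot sampleMetadata data.frame with sample_id, group and cytokine columns.
#' @slot ctTable data.frame sample_id, target, ct, censored.
#' @export
setClass("SimulatedCohort", representation(
  truth = "CommunityTruth",
  config = "list",
  spotTables = "list",
  manifest = "data.frame",
  sampleMetadata = "data.frame",
  ctTable = "data.frame"))

setValidity("SimulatedCohort", function(object) {
  msg <- character()
  if (length(object@spotTables) != nrow(object@sampleMetadata))
    msg <- c(msg, "one spot table per metadata row required")
  if (!all(names(object@spotTables) == object@sampleMetadata$sample_id))
    msg <- c(msg, "spot table names must match metadata sample_id order")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulatedCohort", function(object) {
  cat("SimulatedCohort:", length(object@spotTables), "samples,",
      length(object@truth@speciesNames), "species\n")
  cat("  groups:", paste(sprintf("%s=%d", names(table(object@truth@groupAssignment)),
                                 table(object@truth@groupAssignment)), collapse = ", "), "\n")
  cat("  differential species:", nrow(object@truth@differentialSpecies), "\n")
  cat("  qPCR targets:", length(setdiff(unique(object@ctTable$target), "UNIVERSAL")), "\n")
})

setMethod("show", "CommunityTruth", function(object) {
  cat("CommunityTruth:", length(object@speciesNames), "species (",
      sum(object@baseAbundance > 0), "present ),",
      nrow(object@differentialSpecies), "differential\n")
})
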