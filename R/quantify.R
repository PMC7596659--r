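# Two-pass detection calling and relative-abundance quantification for
# two-channel (Cy5 test / Cy3 reference) phylogenetic arrays.
#
# Per array: (1) average the triplicate spots of each species in each
# channel; (2) background = mean Cy5 of the dimmest 30% of species; a species
# must exceed 5x background (first pass); (3) baseline ratio = mean of the
# lower half of the species Cy5/Cy3 ratios; a species' ratio must exceed 5x
# the baseline (second pass); (4) relative abundance = the positive species'
# ratio normalised to the sum over all positive species.

#' Average triplicate spots into per-species channel signals
#'
#' @param spots GPR-style spot data.frame for one sample (columns Probe_ID,
#'   F635_Mean, F532_Mean).
#' @param manifest probe manifest mapping probe_id to the taxonomy.
#' @return data.frame with one row per species: species, mean_cy5, mean_cy3,
#'   ratio (NA and \code{ratio_defined = FALSE} when the species' mean Cy3 is
#'   0), n_spots. Rows are ordered by species label.
#' @export
aggregateSpots <- function(spots, manifest) {
  if (any(spots$F635_Mean < 0) || any(spots$F532_Mean < 0))
    stop("negative spot intensities")
  sp <- manifest$species[match(spots$Probe_ID, manifest$probe_id)]
  if (anyNA(sp))
    stop("unmapped probe(s): ",
         paste(unique(spots$Probe_ID[is.na(sp)]), collapse = ", "))
  f <- factor(sp, levels = sort(unique(sp)))
  cy5 <- tapply(spots$F635_Mean, f, mean)
  cy3 <- tapply(spots$F532_Mean, f, mean)
  n <- as.integer(table(f))
  ratio <- ifelse(cy3 > 0, cy5 / cy3, NA_real_)
  data.frame(species = levels(f), mean_cy5 = as.numeric(cy5),
             mean_cy3 = as.numeric(cy3), ratio = as.numeric(ratio),
             ratio_defined = cy3 > 0, n_spots = n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Array background from the dimmest species
#'
#' Species are ranked ascending by mean Cy5 signal (ties broken by species
#' label for reproducibility) and the background is the arithmetic mean of
#' the lowest \code{floor(frac * S)} species (at least 1).
#'
#' @param signals output of [aggregateSpots()].
#' @param frac fraction of dimmest species used (default 0.30).
#' @return background intensity (scalar).
#' @export
estimateBackground <- function(signals, frac = 0.30) {
  S <- nrow(signals)
  if (S < 4) stop("insufficient data: need >= 4 species for background")
  ord <- order(signals$mean_cy5, signals$species)
  k <- max(1L, floor(frac * S))
  mean(signals$mean_cy5[ord[seq_len(k)]])
}

#' Baseline Cy5/Cy3 ratio from the lower half of the ratio ranking
#'
#' Defined ratios are ranked ascending (ties by species label) and the
#' baseline is the mean of the lowest \code{floor(S/2)}.
#'
#' @param signals output of [aggregateSpots()].
#' @return baseline ratio (scalar).
#' @export
estimateBaselineRatio <- function(signals) {
  ok <- signals[signals$ratio_defined, , drop = FALSE]
  if (nrow(ok) < 2) stop("insufficient data: need >= 2 defined ratios")
  ord <- order(ok$ratio, ok$species)
  k <- max(1L, floor(nrow(ok) / 2))
  mean(ok$ratio[ord[seq_len(k)]])
}

#' Two-pass positive detection calls
#'
#' A species is positive when its mean Cy5 is strictly greater than
#' \code{fold} times the background AND its Cy5/Cy3 ratio is strictly greater
#' than \code{fold} times the baseline ratio. Species with undefined ratios
#' never pass the second filter.
#'
#' @param signals output of [aggregateSpots()].
#' @param background scalar from [estimateBackground()].
#' @param baseline_ratio scalar from [estimateBaselineRatio()].
#' @param fold threshold multiplier (default 5).
#' @return \code{signals} with added columns background, baseline_ratio,
#'   pass_intensity, pass_ratio, positive.
#' @export
callDetection <- function(signals, background, baseline_ratio, fold = 5) {
  stopifnot(background > 0, baseline_ratio > 0)
  signals$background <- background
  signals$baseline_ratio <- baseline_ratio
  signals$pass_intensity <- signals$mean_cy5 > fold * background
  signals$pass_ratio <- signals$ratio_defined &
    !is.na(signals$ratio) & signals$ratio > fold * baseline_ratio
  signals$positive <- signals$pass_intensity & signals$pass_ratio
  signals
}

#' Ratio-normalised relative abundances for one array
#'
#' Positive species receive \code{ratio / sum(ratio over positives)}; all
#' other species receive exactly 0.
#'
#' @param calls output of [callDetection()].
#' @return named numeric vector of relative abundances over all species.
#' @export
normalizeAbundance <- function(calls) {
  ab <- stats::setNames(numeric(nrow(calls)), calls$species)
  pos <- calls$positive
  if (!any(pos)) {
    warning("no positive species on this array; returning all-zero row")
    return(ab)
  }
  ab[pos] <- calls$ratio[pos] / sum(calls$ratio[pos])
  ab
}

#' Quantify a full cohort of arrays
#'
#' Runs the per-array chain (spot aggregation, background and baseline
#' estimation, two-pass calling, ratio normalisation) independently for every
#' sample — each hybridisation carries its own reference mix — and assembles
#' the species-by-sample [AbundanceExperiment-class].
#'
#' @param spotTables named list of spot data.frames (names = sample ids).
#' @param manifest shared probe manifest.
#' @param fold detection threshold multiplier (default 5).
#' @param aggregate spot summary statistic, \code{"mean"} (default) or
#'   \code{"median"}.
#' @return an [AbundanceExperiment-class]; per-sample detection reports are
#'   kept in \code{metadata(x)$detection_reports}.
#' @export
quantifyCohort <- function(spotTables, manifest, fold = 5,
                           aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  ids <- names(spotTables)
  if (is.null(ids) || anyDuplicated(ids))
    stop("input error: spot tables must have unique sample-id names")
  reports <- lapply(spotTables, function(spots) {
    sig <- aggregateSpots(spots, manifest)
    if (aggregate == "median") {
      sp <- manifest$species[match(spots$Probe_ID, manifest$probe_id)]
      f <- factor(sp, levels = sig$species)
      sig$mean_cy5 <- as.numeric(tapply(spots$F635_Mean, f, stats::median))
      sig$mean_cy3 <- as.numeric(tapply(spots$F532_Mean, f, stats::median))
      sig$ratio <- ifelse(sig$mean_cy3 > 0, sig$mean_cy5 / sig$mean_cy3, NA_real_)
      sig$ratio_defined <- sig$mean_cy3 > 0
    }
    bg <- estimateBackground(sig)
    bl <- estimateBaselineRatio(sig)
    callDetection(sig, bg, bl, fold = fold)
  })
  species <- sort(unique(manifest$species))
  ab <- sapply(reports, function(r) {
    v <- suppressWarnings(normalizeAbundance(r))
    v[species]
  })
  det <- sapply(reports, function(r)
    stats::setNames(r$positive, r$species)[species])
  ab <- matrix(ab, nrow = length(species),
               dimnames = list(species, ids))
  det <- matrix(det, nrow = length(species),
                dimnames = list(species, ids))
  tax <- unique(manifest[, c("species", "genus", "family", "order")])
  tax <- tax[match(species, tax$species), ]
  AbundanceExperiment(ab, det,
                      taxonomy = tax[, c("genus", "family", "order")],
                      detectionReports = reports)
}

#' Aggregate an AbundanceExperiment to a higher taxonomic rank
#'
#' Abundances are summed within taxa of the requested rank (row sums are
#' preserved); an aggregated taxon is flagged detected when any member
#' species was positive. Aggregating to \code{"species"} is the identity.
#'
#' @param x an [AbundanceExperiment-class] at species level.
#' @param rank one of "species", "genus", "family", "order".
#' @return an [AbundanceExperiment-class] at the requested rank.
#' @export
aggregateToRank <- function(x, rank = c("species", "genus", "family", "order")) {
  rank <- match.arg(rank)
  if (rank == "species") return(x)
  tx <- taxonomy(x)
  if (!rank %in% colnames(tx))
    stop("input error: rank '", rank, "' not present in taxonomy")
  f <- factor(tx[[rank]])
  ab <- rowsum(abundances(x), f)
  det <- rowsum(detectionCalls(x) + 0, f) > 0
  keep <- switch(rank, genus = c("genus", "family", "order"),
                 family = c("family", "order"), order = "order")
  lin <- unique(tx[, keep, drop = FALSE])
  lin <- lin[match(levels(f), lin[[rank]]), setdiff(keep, rank), drop = FALSE]
  rownames(ab) <- rownames(det) <- levels(f)
  AbundanceExperiment(ab, det, taxonomy = lin,
                      sampleData = as.data.frame(colData(x)))
}
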