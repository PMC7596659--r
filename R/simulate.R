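#' Simulation configuration for a synthetic microarray cohort
#'
#' Collects every parameter of the synthetic-data generator. Defaults describe
#' a cohort shaped like a two-group paediatric case/control study profiled on
#' a species-level 16S phylogenetic array: 58 cases (ALL) and 23 controls
#' (NC), a species pool in which only part of the panel is present in the
#' community, log-normal abundances, triplicate spots with multiplicative
#' scanner noise, and a handful of species carrying a group fold-change.
#'
#' @param n_all,n_nc number of case (ALL) and control (NC) samples.
#' @param n_species size of the species panel on the array.
#' @param n_differential number of species carrying a group effect.
#' @param fold_range range the per-species fold-changes are drawn from
#'   (uniform); use \code{c(f, f)} for a fixed fold-change.
#' @param prop_present fraction of panel species actually present in the
#'   community; the rest have true abundance 0 and hybridise at background.
#' @param sigma_log log-sd of the log-normal base abundances across species.
#' @param sample_sigma log-sd of between-subject abundance variation.
#' @param triplicate_cv coefficient of variation of the multiplicative
#'   log-normal spot noise (0 = identical triplicates).
#' @param background_mean mean background fluorescence (intensity units).
#' @param signal_scale Cy5 intensity per unit relative abundance.
#' @param reference_channel_mean mean Cy3 intensity of the common reference
#'   pool (lights up every spot).
#' @param species_per_genus,genera_per_family,families_per_order nesting of
#'   the synthetic taxonomy.
#' @param cytokines cytokine panel names for the metadata table.
#' @param coupled_cytokine,coupling_slope,coupling_intercept,coupling_noise_sd
#'   linear coupling of one cytokine to the first differential species:
#'   \code{value = intercept + slope * abundance + N(0, noise_sd)}.
#' @param n_qpcr_targets number of differential species validated by qPCR.
#' @param ct_universal_mean mean universal-primer threshold cycle.
#' @param ct_noise_sd per-well Ct noise (cycles); wells are run in duplicate
#'   and averaged.
#' @param max_cycles cycle ceiling; censored (no-amplification) reactions are
#'   recorded at this value.
#' @param differential_species optional explicit species indices to carry the
#'   group effect (overrides random choice).
#' @param fold_changes optional explicit fold-changes, parallel to
#'   \code{differential_species}.
#' @param seed single integer seed threaded to every sub-generator.
#' @return a validated list of class \code{"chipbiome_config"}.
#' @export
simulationConfig <- function(n_all = 58, n_nc = 23,
                             n_species = 150, n_differential = 15,
                             fold_range = c(2, 8),
                             prop_present = 0.6,
                             sigma_log = 1, sample_sigma = 0.5,
                             triplicate_cv = 0.15,
                             background_mean = 500,
                             signal_scale = 2e6,
                             reference_channel_mean = 1000,
                             species_per_genus = 3,
                             genera_per_family = 3,
                             families_per_order = 3,
                             cytokines = c("IL-1B", "IL-2R", "IL-6",
                                           "IL-8", "IL-10", "TNF-a"),
                             coupled_cytokine = "IL-10",
                             coupling_slope = 1000,
                             coupling_intercept = 5,
                             coupling_noise_sd = 2,
                             n_qpcr_targets = 3,
                             ct_universal_mean = 15,
                             ct_noise_sd = 0.15,
                             max_cycles = 45,
                             differential_species = NULL,
                             fold_changes = NULL,
                             seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "chipbiome_config"
  .validateConfig(cfg)
  cfg
}

.validateConfig <- function(cfg) {
  with(cfg, {
    if (n_all < 1 || n_nc < 1 || n_species < 1)
      stop("configuration error: counts must be >= 1")
    if (n_differential > n_species)
      stop("configuration error: n_differential exceeds n_species")
    if (triplicate_cv < 0) stop("configuration error: triplicate_cv < 0")
    if (any(fold_range <= 0)) stop("configuration error: fold_range must be positive")
    if (prop_present <= 0 || prop_present > 1)
      stop("configuration error: prop_present must be in (0, 1]")
    if (!is.null(differential_species) &&
        (length(differential_species) != n_differential ||
         any(differential_species > n_species)))
      stop("configuration error: differential_species must index n_differential species")
    if (!coupled_cytokine %in% cytokines)
      stop("configuration error: unknown cytokine '", coupled_cytokine, "'")
  })
  invisible(TRUE)
}

# one global seed; fixed offsets give each sub-generator an independent,
# reproducible stream (kept < 2^31)
.stageSeed <- function(seed, offset) (as.integer(seed) + offset) %% .Machine$integer.max

#' Generate a latent community with planted group structure
#'
#' Draws the ground truth a synthetic cohort is rendered from: log-normal
#' base abundances over the present fraction of the species panel, a random
#' subset of comfortably abundant species assigned group fold-changes, group
#' labels, cytokine coupling, and the realised species-by-sample abundance
#' matrix (fold-change applied to ALL samples, between-subject log-normal
#' variation, columns re-normalised).
#'
#' @param config a [simulationConfig()].
#' @return a [CommunityTruth-class] object.
#' @export
generateCommunity <- function(config) {
  .validateConfig(config)
  set.seed(.stageSeed(config$seed, 0L))
  S <- config$n_species
  species <- sprintf("sp%03d", seq_len(S))
  n_present <- max(1L, round(config$prop_present * S))
  present <- sort(sample.int(S, n_present))
  base <- numeric(S)
  base[present] <- stats::rlnorm(n_present, meanlog = 0, sdlog = config$sigma_log)
  base <- base / sum(base)

  # differential species: drawn from the detectable part of the community
  # (above the lower quartile of present species) unless given explicitly
  if (!is.null(config$differential_species)) {
    diff_idx <- as.integer(config$differential_species)
  } else {
    eligible <- present[base[present] >= stats::quantile(base[present], 0.25)]
    if (length(eligible) < config$n_differential)
      eligible <- present
    diff_idx <- sort(sample(eligible, config$n_differential))
  }
  folds <- if (!is.null(config$fold_changes)) as.numeric(config$fold_changes)
           else stats::runif(config$n_differential,
                             config$fold_range[1], config$fold_range[2])
  diff_df <- data.frame(species = species[diff_idx], fold_change = folds,
                        stringsAsFactors = FALSE)

  groups <- factor(rep(c("ALL", "NC"), c(config$n_all, config$n_nc)),
                   levels = c("ALL", "NC"))
  sample_ids <- sprintf("S%03d", seq_along(groups))

  # realised per-sample composition: fold-change on ALL, subject-level
  # log-normal variation, re-normalised (compositional effect preserved)
  mult <- matrix(1, S, length(groups))
  mult[diff_idx, groups == "ALL"] <- folds
  subj <- matrix(stats::rlnorm(S * length(groups),
                               meanlog = -config$sample_sigma^2 / 2,
                               sdlog = config$sample_sigma),
                 S, length(groups))
  sa <- base * mult * subj
  sa <- sweep(sa, 2, colSums(sa), "/")
  dimnames(sa) <- list(species, sample_ids)

  coup <- data.frame(cytokine = config$cytokines,
                     species = NA_character_,
                     intercept = config$coupling_intercept,
                     slope = 0, noise_sd = config$coupling_noise_sd,
                     stringsAsFactors = FALSE)
  coup$species[coup$cytokine == config$coupled_cytokine] <- diff_df$species[1]
  coup$slope[coup$cytokine == config$coupled_cytokine] <- config$coupling_slope

  new("CommunityTruth", speciesNames = species, baseAbundance = base,
      differentialSpecies = diff_df, groupAssignment = groups,
      cytokineCoupling = coup, sampleAbundance = sa)
}

#' Build the synthetic probe manifest
#'
#' One probe per species, nested taxonomy built by grouping consecutive
#' species into genera, genera into families and families into orders.
#'
#' @param config a [simulationConfig()].
#' @return data.frame with columns probe_id, species, genus, family, order.
#' @export
buildManifest <- function(config) {
  S <- config$n_species
  g <- ceiling(seq_len(S) / config$species_per_genus)
  f <- ceiling(g / config$genera_per_family)
  o <- ceiling(f / config$families_per_order)
  data.frame(probe_id = sprintf("P%04d", seq_len(S)),
             species = sprintf("sp%03d", seq_len(S)),
             genus = sprintf("g%03d", g),
             family = sprintf("f%02d", f),
             order = sprintf("o%02d", o),
             stringsAsFactors = FALSE)
}

.lnormNoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))          # CV of a log-normal = sqrt(e^s2 - 1)
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean 1
}

#' Render spot-level two-channel intensity tables
#'
#' Each species' probe is printed in triplicate. Per spot,
#' \code{Cy5 = background_mean * noise + signal_scale * abundance * noise'}
#' and \code{Cy3 = reference_channel_mean * noise''}, with independent
#' multiplicative log-normal noise of CV \code{triplicate_cv} (unit mean).
#' Absent species therefore hybridise at background in the test channel while
#' the reference pool still lights up the spot.
#'
#' @param truth a [CommunityTruth-class].
#' @param config the matching [simulationConfig()].
#' @return named list of GPR-style data.frames (columns Block, Row, Column,
#'   Probe_ID, F635_Mean, F532_Mean), one per sample.
#' @export
renderSpotTables <- function(truth, config) {
  stopifnot(length(truth@speciesNames) == config$n_species)
  set.seed(.stageSeed(config$seed, 1L))
  manifest <- buildManifest(config)
  S <- config$n_species
  n_spot <- 3L * S
  layout <- data.frame(Block = 1L,
                       Row = rep(seq_len(S), each = 3L),
                       Column = rep(1:3, S),
                       Probe_ID = rep(manifest$probe_id, each = 3L),
                       stringsAsFactors = FALSE)
  lapply(stats::setNames(colnames(truth@sampleAbundance),
                         colnames(truth@sampleAbundance)), function(sid) {
    a <- rep(truth@sampleAbundance[, sid], each = 3L)
    cy5 <- config$background_mean * .lnormNoise(n_spot, config$triplicate_cv) +
      config$signal_scale * a * .lnormNoise(n_spot, config$triplicate_cv)
    cy3 <- config$reference_channel_mean * .lnormNoise(n_spot, config$triplicate_cv)
    cbind(layout, data.frame(F635_Mean = cy5, F532_Mean = cy3))
  })
}

#' Render sample metadata with a coupled cytokine panel
#'
#' Cytokine values follow \code{intercept + slope * abundance(coupled species)
#' + N(0, noise_sd)} per the truth's coupling table; uncoupled cytokines are
#' intercept plus noise.
#'
#' @param truth a [CommunityTruth-class].
#' @param config the matching [simulationConfig()].
#' @return data.frame with sample_id, group, and one column per cytokine.
#' @export
renderMetadata <- function(truth, config) {
  set.seed(.stageSeed(config$seed, 2L))
  coup <- truth@cytokineCoupling
  bad <- setdiff(coup$cytokine, config$cytokines)
  if (length(bad))
    stop("configuration error: unknown cytokine(s) ", paste(bad, collapse = ", "))
  n <- ncol(truth@sampleAbundance)
  md <- data.frame(sample_id = colnames(truth@sampleAbundance),
                   group = as.character(truth@groupAssignment),
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(coup))) {
    ab <- if (is.na(coup$species[i])) rep(0, n)
          else truth@sampleAbundance[coup$species[i], ]
    md[[coup$cytokine[i]]] <- coup$intercept[i] + coup$slope[i] * ab +
      stats::rnorm(n, 0, coup$noise_sd[i])
  }
  md
}

#' Render a qPCR threshold-cycle table
#'
#' For each target species and sample, the specific-primer Ct is constructed
#' as \code{ct_universal - log2(relative abundance)} plus per-well noise, so
#' that the delta-Ct quantification \code{2^(ct_universal - ct_specific) *
#' 10^4} recovers \code{10^4 *} the planted relative abundance exactly when
#' noise is 0. Wells are run in duplicate and the recorded Ct is their mean.
#' Zero-abundance targets do not amplify: Ct is censored at the cycle ceiling.
#'
#' @param truth a [CommunityTruth-class].
#' @param config the matching [simulationConfig()].
#' @param targets species labels to assay; default the first
#'   \code{n_qpcr_targets} planted differential species.
#' @return data.frame with sample_id, target (species or "UNIVERSAL"), ct,
#'   censored.
#' @export
renderCtTable <- function(truth, config, targets = NULL) {
  set.seed(.stageSeed(config$seed, 3L))
  if (is.null(targets)) {
    k <- min(config$n_qpcr_targets, nrow(truth@differentialSpecies))
    targets <- truth@differentialSpecies$species[seq_len(k)]
  }
  if (!all(targets %in% truth@speciesNames))
    stop("configuration error: qPCR target not in species list")
  samples <- colnames(truth@sampleAbundance)
  dupMean <- function(mu) mean(mu + stats::rnorm(2, 0, config$ct_noise_sd))
  rows <- lapply(samples, function(sid) {
    ct_u <- dupMean(config$ct_universal_mean)
    out <- data.frame(sample_id = sid, target = "UNIVERSAL",
                      ct = ct_u, censored = FALSE, stringsAsFactors = FALSE)
    for (tg in targets) {
      a <- truth@sampleAbundance[tg, sid]
      if (a <= 0) {
        out <- rbind(out, data.frame(sample_id = sid, target = tg,
                                     ct = config$max_cycles, censored = TRUE))
      } else {
        ct_s <- dupMean(ct_u - log2(a))
        cens <- ct_s >= config$max_cycles
        out <- rbind(out, data.frame(sample_id = sid, target = tg,
                                     ct = min(ct_s, config$max_cycles),
                                     censored = cens))
      }
    }
    out
  })
  do.call(rbind, rows)
}

#' Simulate a complete synthetic cohort
#'
#' Runs [generateCommunity()], [renderSpotTables()], [renderMetadata()] and
#' [renderCtTable()] under one threaded seed and bundles the artifacts.
#'
#' @param config a [simulationConfig()].
#' @return a [SimulatedCohort-class] object.
#' @examples
#' sim <- simulateCohort(simulationConfig(n_all = 6, n_nc = 4,
#'                                        n_species = 20, n_differential = 2))
#' sim
#' @export
simulateCohort <- function(config = simulationConfig()) {
  truth <- generateCommunity(config)
  new("SimulatedCohort",
      truth = truth, config = unclass(config),
      spotTables = renderSpotTables(truth, config),
      manifest = buildManifest(config),
      sampleMetadata = renderMetadata(truth, config),
      ctTable = renderCtTable(truth, config))
}
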