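# End-to-end orchestration: simulate -> quantify -> diversity ->
# differential -> classify -> validate, each stage reading only the declared
# file artifacts of its predecessors, with every output hashed into a run
# manifest for reproducibility.

#' Assemble a pipeline run configuration
#'
#' @param simulation a [simulationConfig()] (the cohort to generate, or the
#'   shape expected of provided input files).
#' @param fold detection threshold multiplier (default 5).
#' @param alpha screen significance level (default 0.05).
#' @param lda_threshold LEfSe score cutoff (default 2).
#' @param n_trees random-forest size (default 500).
#' @param n_permutations PERMANOVA permutations (default 999).
#' @param pseudo_count_total rescaling total for richness estimators.
#' @param stages character subset of
#'   \code{c("simulate","quantify","diversity","differential","classify","validate")}.
#' @param seed analysis-stage seed (NMDS, PERMANOVA, LEfSe bootstrap, forests).
#' @return a named list of class \code{"chipbiome_runconfig"}.
#' @export
runConfig <- function(simulation = simulationConfig(),
                      fold = 5, alpha = 0.05, lda_threshold = 2,
                      n_trees = 500, n_permutations = 999,
                      pseudo_count_total = 10000,
                      stages = c("simulate", "quantify", "diversity",
                                 "differential", "classify", "validate"),
                      seed = 42) {
  cfg <- as.list(environment())
  class(cfg) <- "chipbiome_runconfig"
  cfg
}

.stageFiles <- function(dir) list.files(dir, recursive = TRUE, full.names = TRUE)

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order under \code{out_dir},
#' each stage writing TSV artifacts into its own subdirectory and reading
#' only its predecessors' files. A JSON run manifest records parameters,
#' seeds and the MD5 hash of every artifact; a rerun with the same
#' configuration reproduces identical hashes for all deterministic stages.
#'
#' @param config a [runConfig()].
#' @param out_dir output directory.
#' @return the run manifest (list), invisibly; also written as
#'   \code{manifest.json}.
#' @export
runPipeline <- function(config = runConfig(), out_dir) {
  stopifnot(inherits(config, "chipbiome_runconfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  done <- character()
  t0 <- Sys.time()

  stage_dir <- function(s) {
    d <- file.path(out_dir, s)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
  }
  log_stage <- function(s, ...) message(sprintf("[%s] %s", s, paste0(...)))

  if ("simulate" %in% stages) {
    log_stage("simulate", "rendering synthetic cohort (seed ",
              config$simulation$seed, ")")
    sim <- simulateCohort(config$simulation)
    writeCohort(sim, stage_dir("simulate"))
    truth_df <- plantedDifferential(sim)
    .writeTsv(truth_df, file.path(stage_dir("simulate"), "planted_truth.tsv"))
    done <- c(done, "simulate")
  }

  sim_dir <- file.path(out_dir, "simulate")
  if ("quantify" %in% stages) {
    log_stage("quantify", "two-pass detection calling, fold = ", config$fold)
    spots <- readSpotTables(file.path(sim_dir, "spots"))
    manifest <- readManifest(file.path(sim_dir, "manifest.tsv"))
    ae <- quantifyCohort(spots, manifest, fold = config$fold)
    writeAbundance(ae, stage_dir("quantify"))
    reports <- metadata(ae)$detection_reports
    rep_df <- do.call(rbind, lapply(names(reports), function(s)
      cbind(sample_id = s, reports[[s]])))
    .writeTsv(rep_df, file.path(stage_dir("quantify"), "detection_report.tsv"))
    done <- c(done, "quantify")
  }

  read_ae <- function() {
    ae <- readAbundance(file.path(out_dir, "quantify"))
    md <- readMetadata(file.path(sim_dir, "metadata.tsv"))
    attachMetadata(ae, md)
  }

  if ("diversity" %in% stages) {
    log_stage("diversity", "alpha indices + Bray-Curtis ordination + PERMANOVA")
    ae <- read_ae()
    g <- sampleGroups(ae)
    d <- stage_dir("diversity")
    div <- alphaDiversity(ae, pseudo_count_total = config$pseudo_count_total)
    .writeTsv(div, file.path(d, "alpha_diversity.tsv"))
    .writeTsv(compareAlpha(div, g), file.path(d, "alpha_tests.tsv"))
    bc <- brayCurtis(ae)
    bcm <- as.matrix(bc)
    .writeTsv(cbind(data.frame(sample_id = rownames(bcm)), as.data.frame(bcm)),
              file.path(d, "bray_curtis.tsv"))
    pc <- pcoaOrdination(bc, k = 2)
    nm <- nmdsOrdination(bc, k = 2, seed = config$seed)
    .writeTsv(cbind(data.frame(sample_id = rownames(pc$coordinates), group = g),
                    as.data.frame(pc$coordinates)),
              file.path(d, "pcoa.tsv"))
    .writeTsv(cbind(data.frame(sample_id = colnames(ae), group = g,
                               stress = nm$stress),
                    as.data.frame(nm$coordinates)),
              file.path(d, "nmds.tsv"))
    pm <- permanovaTest(bc, g, n_permutations = config$n_permutations,
                        seed = config$seed)
    .writeTsv(as.data.frame(pm), file.path(d, "permanova.tsv"))
    done <- c(done, "diversity")
  }

  if ("differential" %in% stages) {
    log_stage("differential", "LEfSe cascade, alpha = ", config$alpha,
              ", LDA cutoff = ", config$lda_threshold)
    ae <- read_ae()
    g <- sampleGroups(ae)
    d <- stage_dir("differential")
    res <- lefse(ae, g, alpha = config$alpha,
                 lda_threshold = config$lda_threshold, seed = config$seed)
    .writeTsv(res, file.path(d, "lefse_species.tsv"))
    clad <- buildCladogramTable(ae, g, alpha = config$alpha,
                                lda_threshold = config$lda_threshold,
                                seed = config$seed)
    .writeTsv(clad, file.path(d, "cladogram_table.tsv"))
    done <- c(done, "differential")
  }

  if ("classify" %in% stages) {
    log_stage("classify", "LOOCV random forest, ", config$n_trees, " trees")
    ae <- read_ae()
    g <- sampleGroups(ae)
    d <- stage_dir("classify")
    cmp <- compareRanks(ae, g, n_trees = config$n_trees, seed = config$seed)
    .writeTsv(cmp$table, file.path(d, "rank_comparison.tsv"))
    sp <- cmp$reports$species
    .writeTsv(data.frame(sample_id = names(sp$scores), group = g,
                         score = sp$scores),
              file.path(d, "loocv_scores.tsv"))
    .writeTsv(sp$curve, file.path(d, "roc_points.tsv"))
    imp <- featureImportance(ae, g, n_trees = config$n_trees,
                             seed = config$seed)
    .writeTsv(imp$all, file.path(d, "importance.tsv"))
    jsonlite::write_json(list(auc = sp$auc, ci_low = sp$auc_ci_low,
                              ci_high = sp$auc_ci_high),
                         file.path(d, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    done <- c(done, "classify")
  }

  if ("validate" %in% stages) {
    log_stage("validate", "delta-Ct qPCR concordance + cytokine correlations")
    ae <- read_ae()
    g <- sampleGroups(ae)
    d <- stage_dir("validate")
    ct <- readCtTable(file.path(sim_dir, "ct.tsv"))
    .writeTsv(qpcrQuantify(ct), file.path(d, "qpcr_abundance.tsv"))
    .writeTsv(comparePlatforms(ae, ct, g), file.path(d, "platform_concordance.tsv"))
    md <- readMetadata(file.path(sim_dir, "metadata.tsv"))
    .writeTsv(spearmanMatrix(ae, md, group = "ALL"),
              file.path(d, "cytokine_correlations.tsv"))
    done <- c(done, "validate")
  }

  files <- .stageFiles(out_dir)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "chipbiome",
    stages_run = done,
    parameters = lapply(unclass(config)[setdiff(names(config), "stages")],
                        function(p) if (is.list(p)) unclass(p) else p),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    artifacts = lapply(stats::setNames(files, sub(paste0("^", out_dir, "/?"),
                                                  "", files)),
                       function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Summarise a pipeline run as a markdown report
#'
#' Walks the artifact tree of a completed [runPipeline()] run and writes one
#' markdown document mirroring a standard results narrative: beta-diversity
#' ordination, differential taxa, classifier performance, qPCR concordance
#' and cytokine correlations. Missing stages are marked absent. Regeneration
#' is idempotent.
#'
#' @param out_dir directory of a pipeline run.
#' @param file report path (default \code{report.md} inside \code{out_dir}).
#' @return the report path, invisibly.
#' @export
makeReport <- function(out_dir, file = file.path(out_dir, "report.md")) {
  L <- c("# chipbiome run report", "")
  tsv <- function(...) {
    p <- file.path(out_dir, ...)
    if (file.exists(p)) .readTsv(p) else NULL
  }
  md_table <- function(df, max_rows = 12) {
    df <- utils::head(df, max_rows)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, 4)
    c(paste("|", paste(colnames(df), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
      apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|")))
  }
  section <- function(title, df, note = NULL) {
    L <<- c(L, paste("##", title), "")
    if (is.null(df)) L <<- c(L, "_Section absent: stage not run._", "")
    else if (!nrow(df)) L <<- c(L, note %||% "_No rows._", "")
    else L <<- c(L, md_table(df), "")
  }
  section("Alpha diversity (group comparison)", tsv("diversity", "alpha_tests.tsv"))
  pm <- tsv("diversity", "permanova.tsv")
  if (!is.null(pm))
    L <- c(L, "## Beta diversity", "",
           sprintf("PERMANOVA on Bray-Curtis: pseudo-F = %.3f, p = %.4g (%d permutations).",
                   pm$pseudo_F, pm$p_value, pm$n_permutations), "")
  nm <- tsv("diversity", "nmds.tsv")
  if (!is.null(nm))
    L <- c(L, sprintf("NMDS stress: %.3f.", nm$stress[1]), "")
  section("Differential taxa (LEfSe)", tsv("differential", "lefse_species.tsv"),
          "No taxa passed the screen and effect-size filter.")
  section("Classifier (LOOCV random forest, by rank)",
          tsv("classify", "rank_comparison.tsv"))
  section("Top discriminant taxa", utils::head(tsv("classify", "importance.tsv"), 10))
  section("qPCR platform concordance", tsv("validate", "platform_concordance.tsv"))
  corr <- tsv("validate", "cytokine_correlations.tsv")
  if (!is.null(corr)) corr <- corr[!is.na(corr$p_value) & corr$p_value < 0.05, ]
  section("Significant species-cytokine correlations", corr,
          "No significant correlations.")
  writeLines(L, file)
  invisible(file)
}
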