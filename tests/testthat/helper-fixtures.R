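# Small fixtures built in code.

# Manifest for S species, one probe each, genera of `per_genus` species.
tiny_manifest <- function(S, per_genus = 2) {
  g <- ceiling(seq_len(S) / per_genus)
  data.frame(probe_id = sprintf("P%02d", seq_len(S)),
             species = sprintf("sp%02d", seq_len(S)),
             genus = sprintf("g%02d", g),
             family = sprintf("f%02d", ceiling(g / 2)),
             order = "o1", stringsAsFactors = FALSE)
}

# Spot table with per-species constant channel values (n_rep spots each).
spots_from_values <- function(manifest, cy5, cy3, n_rep = 3) {
  data.frame(Block = 1L,
             Row = rep(seq_len(nrow(manifest)), each = n_rep),
             Column = rep(seq_len(n_rep), nrow(manifest)),
             Probe_ID = rep(manifest$probe_id, each = n_rep),
             F635_Mean = rep(cy5, each = n_rep),
             F532_Mean = rep(cy3, each = n_rep),
             stringsAsFactors = FALSE)
}

# AbundanceExperiment from a samples-by-taxa value matrix (rows renormalised).
ae_from_matrix <- function(m, taxonomy = NULL, groups = NULL) {
  m <- m / rowSums(m)
  ab <- t(m)
  sd_df <- if (is.null(groups)) NULL else data.frame(group = groups)
  AbundanceExperiment(ab, ab > 0, taxonomy = taxonomy, sampleData = sd_df)
}

# Cohort whose species-level signal cancels exactly within one genus:
# sp01/sp02 (same genus) carry equal and opposite group effects, remaining
# taxa are pure noise, so genus sums are uninformative.
cancel_cohort <- function(n_all = 58, n_nc = 23, n_noise = 28, seed = 1) {
  set.seed(seed)
  n <- n_all + n_nc
  g <- factor(rep(c("ALL", "NC"), c(n_all, n_nc)), levels = c("ALL", "NC"))
  eff <- ifelse(g == "ALL", 0.02, -0.02)
  sp1 <- pmax(0.05 + eff + rnorm(n, 0, 0.004), 1e-6)
  sp2 <- pmax(0.05 - eff + rnorm(n, 0, 0.004), 1e-6)
  noise <- matrix(pmax(rnorm(n * n_noise, 0.03, 0.008), 1e-6), n)
  m <- cbind(sp1, sp2, noise)
  S <- n_noise + 2
  colnames(m) <- sprintf("sp%02d", seq_len(S))
  tax <- tiny_manifest(S)[, c("genus", "family", "order")]
  list(ae = ae_from_matrix(m, taxonomy = tax, groups = g), groups = g)
}

# Simulation config for the planted-signal study design used across tests:
# 150-species panel, 15 differential species at fold-change 4, triplicate
# CV 0.15, 58 vs 23 samples.
signal_config <- function(seed, ...) {
  simulationConfig(n_species = 150, n_differential = 15,
                   fold_range = c(4, 4), triplicate_cv = 0.15,
                   seed = seed, ...)
}

# Null config used for calibration runs: same cohort shape, no effect.
null_config <- function(seed, n_species = 50) {
  simulationConfig(n_species = n_species, n_differential = 0,
                   n_qpcr_targets = 0, seed = seed)
}
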