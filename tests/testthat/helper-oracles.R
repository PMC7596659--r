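# Independent brute-force oracles, written as plain-loop transcriptions so
# they share no code with the implementation they check.

# Per-array chain: triplicate means -> background (mean Cy5 of the dimmest
# 30% of species, floor, min 1) -> baseline ratio (mean of the lower half of
# defined ratios, floor) -> strict 5x/5x two-pass call -> ratio-normalised
# abundances.
oracle_quantify <- function(spots, manifest, fold = 5) {
  species <- sort(unique(manifest$species))
  S <- length(species)
  m5 <- m3 <- ratio <- rep(NA_real_, S)
  defined <- logical(S)
  for (i in seq_len(S)) {
    pr <- manifest$probe_id[manifest$species == species[i]]
    sel <- spots$Probe_ID %in% pr
    m5[i] <- sum(spots$F635_Mean[sel]) / sum(sel)
    m3[i] <- sum(spots$F532_Mean[sel]) / sum(sel)
    defined[i] <- m3[i] > 0
    if (defined[i]) ratio[i] <- m5[i] / m3[i]
  }
  ord <- order(m5, species)
  background <- mean(m5[ord[seq_len(max(1, floor(0.30 * S)))]])
  di <- which(defined)
  dord <- di[order(ratio[di], species[di])]
  baseline <- mean(ratio[dord[seq_len(max(1, floor(length(di) / 2)))]])
  pass1 <- m5 > fold * background
  pass2 <- defined & !is.na(ratio) & ratio > fold * baseline
  positive <- pass1 & pass2
  ab <- rep(0, S)
  if (any(positive)) ab[positive] <- ratio[positive] / sum(ratio[positive])
  list(species = species, mean_cy5 = m5, mean_cy3 = m3, ratio = ratio,
       background = background, baseline = baseline,
       pass_intensity = pass1, pass_ratio = pass2, positive = positive,
       abundance = ab)
}

# AUC as the exact pairwise concordance probability (ties count 1/2).
oracle_auc <- function(scores, labels, positive = "ALL") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Random small array instance: 4-12 species, 1-3 spots each, log-normal
# intensities, occasionally a species with all-zero Cy3.
random_instance <- function(seed) {
  set.seed(seed)
  S <- sample(4:12, 1)
  manifest <- data.frame(probe_id = sprintf("P%02d", seq_len(S)),
                         species = sprintf("sp%02d", seq_len(S)),
                         genus = sprintf("g%02d", ceiling(seq_len(S) / 2)),
                         family = sprintf("f%02d", ceiling(seq_len(S) / 4)),
                         order = "o1", stringsAsFactors = FALSE)
  nspot <- sample(1:3, S, replace = TRUE)
  spots <- data.frame(Probe_ID = rep(manifest$probe_id, nspot),
                      stringsAsFactors = FALSE)
  n <- nrow(spots)
  spots$F635_Mean <- rlnorm(n, log(500), 1.5)
  spots$F532_Mean <- rlnorm(n, log(300), 1)
  if (runif(1) < 0.3) {
    z <- sample(S, 1)
    spots$F532_Mean[spots$Probe_ID == manifest$probe_id[z]] <- 0
  }
  list(spots = spots, manifest = manifest)
}
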