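# The two-pass detection-calling and relative-abundance chain.

test_that("spot aggregation averages triplicates per channel", {
  mf <- tiny_manifest(4)
  sp <- spots_from_values(mf, cy5 = c(100, 200, 300, 400),
                          cy3 = c(50, 50, 50, 50))
  # perturb one species' spots to (100, 110, 120)
  sp$F635_Mean[sp$Probe_ID == "P01"] <- c(100, 110, 120)
  sig <- aggregateSpots(sp, mf)
  expect_equal(sig$mean_cy5[sig$species == "sp01"], 110)
  expect_equal(sig$ratio[sig$species == "sp01"], 2.2)

  # single surviving spot: that spot's values are used
  sp1 <- sp[!(sp$Probe_ID == "P02" & sp$Column > 1), ]
  sig1 <- aggregateSpots(sp1, mf)
  expect_equal(sig1$mean_cy5[sig1$species == "sp02"], 200)
  expect_equal(sig1$n_spots[sig1$species == "sp02"], 1L)

  # permuting spot order leaves the output unchanged
  expect_equal(aggregateSpots(sp[sample(nrow(sp)), ], mf), sig)

  # unmapped probes and negative intensities are rejected
  bad <- sp; bad$Probe_ID[1] <- "PXX"
  expect_error(aggregateSpots(bad, mf), "unmapped")
  neg <- sp; neg$F635_Mean[1] <- -1
  expect_error(aggregateSpots(neg, mf), "negative")
})

test_that("background is the mean Cy5 of the dimmest 30% of species", {
  mf <- tiny_manifest(10)
  sp <- spots_from_values(mf, cy5 = 1:10, cy3 = rep(1, 10))
  sig <- aggregateSpots(sp, mf)
  expect_equal(estimateBackground(sig), 2)          # floor(3) -> mean(1,2,3)

  # constant input: background equals the constant
  spc <- spots_from_values(mf, cy5 = rep(7, 10), cy3 = rep(1, 10))
  expect_equal(estimateBackground(aggregateSpots(spc, mf)), 7)

  # S = 4 -> floor(1.2) = 1 species used; cross-checked against the
  # rank-and-average oracle
  mf4 <- tiny_manifest(4)
  sp4 <- spots_from_values(mf4, cy5 = c(40, 10, 30, 20), cy3 = rep(1, 4))
  expect_equal(estimateBackground(aggregateSpots(sp4, mf4)), 10)
  expect_equal(estimateBackground(aggregateSpots(sp4, mf4)),
               oracle_quantify(sp4, mf4)$background)
  expect_error(estimateBackground(aggregateSpots(
    spots_from_values(tiny_manifest(3), cy5 = 1:3, cy3 = rep(1, 3)),
    tiny_manifest(3))), "insufficient")
})

test_that("baseline ratio is the mean of the lower half of the ratio ranking", {
  mf <- tiny_manifest(4)
  sp <- spots_from_values(mf, cy5 = c(1, 2, 3, 4), cy3 = rep(1, 4))
  expect_equal(estimateBaselineRatio(aggregateSpots(sp, mf)), 1.5)

  spc <- spots_from_values(mf, cy5 = rep(3, 4), cy3 = rep(1, 4))
  expect_equal(estimateBaselineRatio(aggregateSpots(spc, mf)), 3)

  # odd count: floor(5/2) = 2 lowest used; checked against the oracle
  mf5 <- tiny_manifest(5)
  sp5 <- spots_from_values(mf5, cy5 = c(5, 1, 4, 2, 3), cy3 = rep(1, 5))
  expect_equal(estimateBaselineRatio(aggregateSpots(sp5, mf5)), 1.5)
  expect_equal(estimateBaselineRatio(aggregateSpots(sp5, mf5)),
               oracle_quantify(sp5, mf5)$baseline)
})

test_that("species with zero Cy3 are excluded from ratios but not intensity", {
  mf <- tiny_manifest(5)
  sp <- spots_from_values(mf, cy5 = c(100, 20, 30, 40, 500),
                          cy3 = c(10, 10, 10, 10, 0))
  sig <- aggregateSpots(sp, mf)
  expect_false(sig$ratio_defined[sig$species == "sp05"])
  expect_true(is.na(sig$ratio[sig$species == "sp05"]))
  calls <- callDetection(sig, estimateBackground(sig),
                         estimateBaselineRatio(sig))
  expect_false(calls$positive[calls$species == "sp05"])
  expect_true(calls$pass_intensity[calls$species == "sp05"])
})

test_that("detection thresholds are strict inequalities in both passes", {
  mf <- tiny_manifest(4)
  sig <- aggregateSpots(spots_from_values(mf, cy5 = c(10, 20, 500, 600),
                                          cy3 = rep(10, 4)), mf)
  bg <- 10; bl <- 2
  eps <- 1e-9
  at5 <- sig
  at5$mean_cy5 <- c(50, 50 * (1 + eps), 500, 500)   # exactly 5x vs above
  at5$ratio <- c(10, 10, 10, 10 * (1 + eps))
  at5$ratio[3] <- 10                                 # exactly 5x baseline
  calls <- callDetection(at5, bg, bl, fold = 5)
  expect_false(calls$pass_intensity[1])              # == 5x background
  expect_true(calls$pass_intensity[2])               # 5x(1+eps)
  expect_false(calls$pass_ratio[3])                  # == 5x baseline
  expect_true(calls$positive[4])                     # both strict passes
  # high intensity but baseline-level ratio stays negative
  expect_false(calls$positive[3])
})

test_that("abundance normalisation spreads the positive ratios to sum 1", {
  mf <- tiny_manifest(4)
  sig <- aggregateSpots(spots_from_values(mf, cy5 = c(300, 100, 5, 4),
                                          cy3 = rep(100, 4)), mf)
  calls <- callDetection(sig, background = 1, baseline_ratio = 0.1)
  ab <- normalizeAbundance(calls)
  expect_equal(unname(ab[c("sp01", "sp02")]), c(0.75, 0.25))
  expect_equal(sum(ab), 1)

  one <- callDetection(sig, background = 1, baseline_ratio = 0.55)
  expect_equal(unname(normalizeAbundance(one)["sp01"]), 1)

  none <- callDetection(sig, background = 1e6, baseline_ratio = 1e6)
  expect_warning(ab0 <- normalizeAbundance(none), "no positive")
  expect_true(all(ab0 == 0))
})

test_that("cohort quantification is order-invariant and validates input", {
  cfg <- simulationConfig(n_all = 4, n_nc = 3, n_species = 12,
                          n_differential = 2, seed = 21)
  sim <- simulateCohort(cfg)
  ae <- quantifyCohort(sim@spotTables, sim@manifest)
  expect_equal(ncol(ae), 7)
  expect_true(all(abs(colSums(abundances(ae)) - 1) < 1e-9 |
                    colSums(abundances(ae)) == 0))

  perm <- sample(length(sim@spotTables))
  ae2 <- quantifyCohort(sim@spotTables[perm], sim@manifest)
  expect_equal(abundances(ae2), abundances(ae)[, colnames(ae2)])

  dup <- sim@spotTables; names(dup) <- rep(names(dup)[1], length(dup))
  expect_error(quantifyCohort(dup, sim@manifest), "unique")

  # infinite threshold: nothing is ever called
  suppressWarnings(ae_inf <- quantifyCohort(sim@spotTables, sim@manifest,
                                            fold = Inf))
  expect_true(all(abundances(ae_inf) == 0))
})

test_that("calls and abundances are invariant to joint channel rescaling", {
  for (s in 1:5) {
    inst <- random_instance(400 + s)
    ae1 <- quantifyCohort(list(A = inst$spots), inst$manifest)
    scaled <- inst$spots
    scaled$F635_Mean <- scaled$F635_Mean * 7.3
    scaled$F532_Mean <- scaled$F532_Mean * 7.3
    ae2 <- quantifyCohort(list(A = scaled), inst$manifest)
    expect_equal(abundances(ae1), abundances(ae2), tolerance = 1e-12)
    expect_identical(detectionCalls(ae1), detectionCalls(ae2))
  }
})

test_that("raising a species' Cy5 never turns its own positive call off", {
  for (s in 1:10) {
    inst <- random_instance(500 + s)
    ae1 <- quantifyCohort(list(A = inst$spots), inst$manifest)
    pos1 <- detectionCalls(ae1)[, 1]
    target <- names(pos1)[pos1][1]
    if (is.na(target)) next
    pr <- inst$manifest$probe_id[inst$manifest$species == target]
    up <- inst$spots
    up$F635_Mean[up$Probe_ID %in% pr] <- up$F635_Mean[up$Probe_ID %in% pr] * 3
    ae2 <- quantifyCohort(list(A = up), inst$manifest)
    expect_true(detectionCalls(ae2)[target, 1])
  }
})

test_that("quantification recovers a planted community ranking", {
  cfg <- simulationConfig(n_all = 3, n_nc = 2, n_species = 60,
                          n_differential = 2, triplicate_cv = 0.05, seed = 31)
  sim <- simulateCohort(cfg)
  ae <- quantifyCohort(sim@spotTables, sim@manifest)
  tru <- plantedAbundance(sim)
  rhos <- vapply(seq_len(ncol(ae)), function(i) {
    pos <- detectionCalls(ae)[, i]
    cor(abundances(ae)[pos, i], tru[pos, i], method = "spearman")
  }, numeric(1))
  expect_true(all(rhos >= 0.9))
})

test_that("rank aggregation sums abundances and preserves row totals", {
  m <- rbind(c(0.2, 0.3, 0.5), c(0.1, 0.6, 0.3))
  colnames(m) <- c("sp01", "sp02", "sp03")
  tax <- data.frame(genus = c("g01", "g01", "g02"),
                    family = c("f01", "f01", "f01"), order = "o1",
                    row.names = colnames(m))
  ae <- ae_from_matrix(m, taxonomy = tax)
  g <- aggregateToRank(ae, "genus")
  expect_equal(unname(abundances(g)["g01", ]), c(0.5, 0.7))
  expect_equal(colSums(abundances(g)), colSums(abundances(ae)))
  expect_identical(aggregateToRank(ae, "species"), ae)
  f <- aggregateToRank(ae, "family")
  expect_equal(unname(abundances(f)["f01", ]), c(1, 1))
  expect_error(aggregateToRank(ae, "phylum"))
})
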