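# The synthetic-data generator: determinism, planted structure, noise model,
# and lossless round-trips of its file formats.

test_that("community generation plants the requested structure deterministically", {
  cfg <- simulationConfig(n_species = 10, n_differential = 2, seed = 1)
  tr <- generateCommunity(cfg)
  expect_equal(nrow(tr@differentialSpecies), 2)
  expect_true(all(tr@differentialSpecies$species %in% tr@speciesNames))
  expect_true(all(tr@differentialSpecies$fold_change > 0))
  expect_equal(sum(tr@baseAbundance), 1, tolerance = 1e-12)
  expect_equal(unname(colSums(tr@sampleAbundance)),
               rep(1, cfg$n_all + cfg$n_nc), tolerance = 1e-9)
  tr2 <- generateCommunity(cfg)
  expect_identical(tr@baseAbundance, tr2@baseAbundance)
  expect_identical(tr@sampleAbundance, tr2@sampleAbundance)
  expect_identical(tr@differentialSpecies, tr2@differentialSpecies)
})

test_that("whole-cohort rendering is byte-deterministic under one seed", {
  cfg <- simulationConfig(n_all = 4, n_nc = 3, n_species = 12,
                          n_differential = 2, seed = 9)
  s1 <- simulateCohort(cfg)
  s2 <- simulateCohort(cfg)
  expect_identical(s1@spotTables, s2@spotTables)
  expect_identical(s1@sampleMetadata, s2@sampleMetadata)
  expect_identical(s1@ctTable, s2@ctTable)
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(n_differential = 20, n_species = 10),
               "configuration error")
  expect_error(simulationConfig(triplicate_cv = -0.1), "configuration error")
  expect_error(simulationConfig(coupled_cytokine = "IL-99"),
               "configuration error")
  expect_error(simulationConfig(n_all = 0), "configuration error")
})

test_that("spot tables have triplicate layout and honour the noise model", {
  cfg <- simulationConfig(n_all = 2, n_nc = 2, n_species = 10,
                          n_differential = 1, seed = 3)
  tr <- generateCommunity(cfg)
  spots <- renderSpotTables(tr, cfg)
  expect_length(spots, 4)
  expect_true(all(vapply(spots, nrow, 1L) == 30))

  # no noise -> the three spots of a species are identical
  cfg0 <- simulationConfig(n_all = 2, n_nc = 2, n_species = 10,
                          n_differential = 1, triplicate_cv = 0, seed = 3)
  sp0 <- renderSpotTables(generateCommunity(cfg0), cfg0)[[1]]
  per_probe <- tapply(sp0$F635_Mean, sp0$Probe_ID, function(v) diff(range(v)))
  expect_true(all(per_probe == 0))
})

test_that("absent species hybridise at background level", {
  # Monte-Carlo check of the generator's own noise model: pooled over absent
  # species' spots, the mean Cy5 sits within 3 standard errors of the
  # configured background.
  cfg <- simulationConfig(n_all = 10, n_nc = 10, n_species = 40,
                          prop_present = 0.5, n_differential = 2,
                          triplicate_cv = 0.2, seed = 11)
  tr <- generateCommunity(cfg)
  spots <- renderSpotTables(tr, cfg)
  absent <- tr@speciesNames[tr@baseAbundance == 0]
  manifest <- buildManifest(cfg)
  pr <- manifest$probe_id[manifest$species %in% absent]
  vals <- unlist(lapply(spots, function(s) s$F635_Mean[s$Probe_ID %in% pr]))
  se <- cfg$background_mean * cfg$triplicate_cv / sqrt(length(vals))
  expect_gt(length(vals), 1000)
  expect_lt(abs(mean(vals) - cfg$background_mean), 3 * se)
})

test_that("metadata carries the cytokine coupling and cohort shape", {
  cfg <- simulationConfig(seed = 2)   # default 58 ALL + 23 NC
  tr <- generateCommunity(cfg)
  md <- renderMetadata(tr, cfg)
  expect_equal(nrow(md), 81)
  expect_equal(sum(md$group == "ALL"), 58)
  expect_true(all(c("IL-1B", "IL-2R", "IL-6", "IL-8", "IL-10", "TNF-a")
                  %in% colnames(md)))

  # noise-free positive coupling is perfectly monotone
  cfg0 <- simulationConfig(n_all = 10, n_nc = 5, n_species = 30,
                           n_differential = 2, coupling_noise_sd = 0, seed = 4)
  tr0 <- generateCommunity(cfg0)
  md0 <- renderMetadata(tr0, cfg0)
  sp <- tr0@cytokineCoupling$species[tr0@cytokineCoupling$cytokine == "IL-10"]
  rho <- cor(md0[["IL-10"]], tr0@sampleAbundance[sp, ], method = "spearman")
  expect_equal(rho, 1)
})

test_that("uncoupled cytokines are null on average across seeds", {
  rhos <- vapply(1:20, function(s) {
    cfg <- simulationConfig(n_all = 15, n_nc = 10, n_species = 20,
                            n_differential = 1, seed = 100 + s)
    tr <- generateCommunity(cfg)
    md <- renderMetadata(tr, cfg)
    sp <- tr@differentialSpecies$species[1]
    cor(md[["IL-6"]], tr@sampleAbundance[sp, ], method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.15)
})

test_that("Ct tables invert to the planted abundance and censor absences", {
  cfg <- simulationConfig(n_all = 5, n_nc = 4, n_species = 20,
                          prop_present = 0.5, n_differential = 2,
                          ct_noise_sd = 0, seed = 6)
  tr <- generateCommunity(cfg)
  ct <- renderCtTable(tr, cfg)
  q <- qpcrQuantify(ct)
  tg <- unique(q$target)
  for (t in tg) {
    planted <- tr@sampleAbundance[t, q$sample_id[q$target == t]]
    expect_equal(q$value[q$target == t], unname(10000 * planted),
                 tolerance = 1e-9)
  }

  # a target absent from the community is censored at the cycle ceiling
  absent <- tr@speciesNames[tr@baseAbundance == 0][1]
  ct2 <- renderCtTable(tr, cfg, targets = absent)
  sub <- ct2[ct2$target == absent, ]
  expect_true(all(sub$censored))
  expect_true(all(sub$ct == cfg$max_cycles))
  expect_error(renderCtTable(tr, cfg, targets = "not-a-species"),
               "configuration error")
})

test_that("all generated files round-trip through the package readers", {
  cfg <- simulationConfig(n_all = 3, n_nc = 2, n_species = 8,
                          n_differential = 1, seed = 5)
  sim <- simulateCohort(cfg)
  d <- withr::local_tempdir()
  writeCohort(sim, d)
  spots <- readSpotTables(file.path(d, "spots"))
  expect_equal(names(spots), names(sim@spotTables))
  expect_equal(spots[[1]]$F635_Mean, sim@spotTables[[1]]$F635_Mean,
               tolerance = 1e-12)
  expect_equal(readManifest(file.path(d, "manifest.tsv")), sim@manifest)
  md <- readMetadata(file.path(d, "metadata.tsv"))
  expect_equal(md$sample_id, sim@sampleMetadata$sample_id)
  expect_equal(md[["IL-10"]], sim@sampleMetadata[["IL-10"]], tolerance = 1e-12)
  ct <- readCtTable(file.path(d, "ct.tsv"))
  expect_equal(ct$ct, sim@ctTable$ct, tolerance = 1e-12)
  expect_identical(ct$censored, sim@ctTable$censored)

  ae <- quantifyCohort(sim@spotTables, sim@manifest)
  writeAbundance(ae, file.path(d, "ab"))
  ae2 <- readAbundance(file.path(d, "ab"))
  expect_equal(abundances(ae2), abundances(ae), tolerance = 1e-12)
  expect_identical(detectionCalls(ae2), detectionCalls(ae))
  expect_equal(taxonomy(ae2), taxonomy(ae))
})
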