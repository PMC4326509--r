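test_that("simulation is deterministic in the seed", {
  c1 <- simulateCohort(simConfig(seed = 42, nInfants = 8))
  c2 <- simulateCohort(simConfig(seed = 42, nInfants = 8))
  expect_identical(c1$samples, c2$samples)
  expect_identical(c1$scores, c2$scores)
  r1 <- renderGels(c1)
  r2 <- renderGels(c2)
  expect_identical(lapply(r1$fingerprints, bands),
                   lapply(r2$fingerprints, bands))
  c3 <- simulateCohort(simConfig(seed = 43, nInfants = 8))
  expect_false(identical(c1$scores, c3$scores))
})

test_that("simulated cohorts respect the sampling calendar", {
  co <- simulateCohort(simConfig(seed = 5))
  expect_equal(length(unique(co$samples$infant_id)), 30)
  expect_true(all(co$samples$day_of_life >= 3 & co$samples$day_of_life <= 56))
  expect_true(all(co$samples$week >= 1 & co$samples$week <= 8))
  perInfant <- table(co$samples$infant_id)
  expect_true(mean(perInfant) > 8 && mean(perInfant) < 16)
  # scores reference existing samples, valid classes, one row per (sample, otu)
  expect_true(all(co$scores$sample_id %in% co$samples$sample_id))
  expect_true(all(co$scores$score %in% 1:3))
  expect_false(anyDuplicated(paste(co$scores$sample_id,
                                   co$scores$slotu_id)) > 0)
})

test_that("degenerate colonization configs behave as forced", {
  base <- simConfig(seed = 9, nInfants = 6)
  gp <- base$glotuParams["Staphylococcus"]
  # certain onset in week 1 + persistence 1: positive in every sample
  gp$Staphylococcus$onset <- c(1, 0, 0, 0, 0, 0, 0, 0)
  gp$Staphylococcus$persistence <- 1
  cfg <- simConfig(seed = 9, nInfants = 6, glotuParams = gp,
                   slotuPools = base$slotuPools["Staphylococcus"])
  co <- simulateCohort(cfg)
  expect_equal(nrow(co$scores), nrow(co$samples))
  for (inf in unique(co$samples$infant_id)) {
    pos <- co$samples$sample_id[co$samples$infant_id == inf] %in%
      co$scores$sample_id
    expect_equal(classifyColonization(pos)$status, "persistent")
  }
  # onset mass zero everywhere: never colonized
  gp$Staphylococcus$onset <- rep(0, 8)
  gp$Staphylococcus$persistence <- 0.9
  co0 <- simulateCohort(simConfig(seed = 9, nInfants = 6, glotuParams = gp,
                                  slotuPools = base$slotuPools["Staphylococcus"]))
  expect_equal(nrow(co0$scores), 0)
})

test_that("invalid configs are rejected", {
  expect_error(simConfig(), "seed")
  expect_error(simConfig(seed = 1, failureProb = 1.5), "probabilities")
  expect_error(simConfig(seed = 1, startDay = 10, endDay = 5), "endDay")
  base <- simConfig(seed = 1)
  bad <- base$glotuParams
  bad$Staphylococcus$onset <- rep(0.2, 8)  # sums to 1.6
  expect_error(simConfig(seed = 1, glotuParams = bad), "summing")
})

test_that("rendered gels carry standards, provenance labels and failures", {
  co <- simulateCohort(simConfig(seed = 3, nInfants = 10))
  rg <- renderGels(co)
  expect_equal(length(rg$fingerprints), nrow(co$samples))
  ok <- !vapply(rg$fingerprints, amplificationFailed, logical(1))
  # three standards per analyzable lane, none on failed lanes
  expect_true(all(vapply(rg$fingerprints[ok],
                         function(f) nrow(standardsObserved(f)), integer(1)) == 3L))
  expect_true(all(vapply(rg$fingerprints[!ok],
                         function(f) nrow(bands(f)), integer(1)) == 0L))
  # every rendered band has exactly one provenance label
  allBands <- unlist(lapply(rg$fingerprints[ok],
                            function(f) bands(f)$band_id))
  expect_setequal(allBands, rg$bandTruth$band_id)
  expect_true(all(rg$bandTruth$provenance %in%
                  c("real", "heteroduplex", "spurious")))
  # heteroduplexes only in lanes with >= 2 distinct true taxa
  nTaxa <- table(co$scores$sample_id)
  hdLanes <- unique(rg$bandTruth$sample_id[
    rg$bandTruth$provenance == "heteroduplex"])
  expect_true(all(nTaxa[hdLanes] >= 2))
})

test_that("a noiseless render is losslessly recovered end to end", {
  cfg <- simConfig(seed = 11, nInfants = 12, jitterSd = 0,
                   hdProbPerPair = 0, spuriousRate = 0, failureProb = 0)
  co <- simulateCohort(cfg)
  rg <- renderGels(co)
  res <- analyzeCohort(rg$fingerprints, simMetadata(co))
  met <- evaluateRecovery(res, co, rg)
  expect_equal(met$affiliationPrecision, 1)
  expect_equal(met$affiliationRecall, 1)
  expect_equal(met$scoreAgreement, 1)
  expect_equal(met$statusAgreement, 1)
  expect_equal(met$ndRate, 0)
  # presence/score tables coincide exactly with the ground truth
  pipe <- timelineScores(res$timeline)
  expect_equal(nrow(pipe), nrow(co$scores))
  key <- function(d) paste(d$sample_id, d$slotu_id, d$score)
  expect_setequal(key(pipe), key(co$scores))
})

test_that("affine gel distortion is undone exactly at the standards", {
  cfg <- simConfig(seed = 21, nInfants = 6, jitterSd = 0,
                   hdProbPerPair = 0, spuriousRate = 0, failureProb = 0)
  co <- simulateCohort(cfg)
  rg <- renderGels(co)
  lad <- ladderEntries(defaultLadder())
  truePos <- structure(lad$reference_distance, names = lad$slotu_id)
  for (sid in names(rg$fingerprints)[1:5]) {
    fp <- rg$fingerprints[[sid]]
    std <- standardizeFingerprint(fp, rg$standardsReference)
    obs <- standardsObserved(fp)
    w <- fitWarp(obs, data.frame(standard_id = names(rg$standardsReference),
                                 reference_distance = unname(rg$standardsReference)))
    expect_equal(applyWarp(w, obs$observed_distance),
                 unname(rg$standardsReference[obs$standard_id]))
    # with zero jitter the true ladder positions are recovered everywhere
    truth <- co$scores[co$scores$sample_id == sid, ]
    if (nrow(truth))
      expect_equal(sort(bands(std)$distance_std),
                   sort(unname(truePos[truth$slotu_id])), tolerance = 1e-9)
  }
})

test_that("onset and persistence are recovered at n = 100 within sampling error", {
  base <- simConfig(seed = 1)
  gp <- base$glotuParams["Enterococcus"]
  gp$Enterococcus$onset <- c(0.3, 0.2, 0.2, 0.1, 0.1, 0.1, 0, 0)
  gp$Enterococcus$persistence <- 0.8
  cfg <- simConfig(seed = 77, nInfants = 100, glotuParams = gp,
                   slotuPools = base$slotuPools["Enterococcus"],
                   dropout = 0, failureProb = 0)
  co <- simulateCohort(cfg)
  # estimate onset week as the true first positive week; with weekly sampling
  # and dropout 0 the first eligible sample is always observed
  colonized <- unique(co$scores$infant_id)
  expect_gt(length(colonized), 80)  # onset mass 1.0
  firstWeek <- vapply(colonized, function(inf)
    min(co$scores$week[co$scores$infant_id == inf]), integer(1))
  emp <- as.numeric(table(factor(firstWeek, levels = 1:8)) / length(firstWeek))
  # 3-sigma binomial envelope per week around the configured distribution
  tol <- 3 * sqrt(gp$Enterococcus$onset * (1 - gp$Enterococcus$onset) / 100)
  expect_true(all(abs(emp - gp$Enterococcus$onset) <= pmax(tol, 0.02)))
  # persistence: positives among samples after each infant's first positive
  est <- local({
    num <- 0; den <- 0
    for (inf in colonized) {
      mine <- co$samples[co$samples$infant_id == inf, ]
      pos <- mine$sample_id %in% co$scores$sample_id
      first <- which(pos)[1]
      later <- pos[-seq_len(first)]
      num <- num + sum(later); den <- den + length(later)
    }
    num / den
  })
  se <- sqrt(0.8 * 0.2 / 600)  # >= ~600 subsequent samples observed
  expect_lt(abs(est - 0.8), 4 * se)
})

test_that("the default configuration reproduces the study's artifact load", {
  cfg <- simConfig(seed = 123)
  co <- simulateCohort(cfg)
  rg <- renderGels(co)
  res <- analyzeCohort(rg$fingerprints, simMetadata(co))
  frac <- with(res$accounting, n_artifact / n_detected)
  expect_gte(frac, cfg$artifactBand[1])
  expect_lte(frac, cfg$artifactBand[2])
  # flagged artifacts are overwhelmingly true heteroduplexes
  met <- evaluateRecovery(res, co, rg)
  expect_gt(met$artifactSensitivity, 0.8)
  expect_gt(met$artifactSpecificity, 0.95)
})
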