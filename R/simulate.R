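#' Default packaged (synthetic) diversity ladder
#'
#' Reference migration distances for the 50 SLOTUs of the default taxonomy.
#' The study's real ladder positions are not published, so these positions
#' are synthetic: 50 entries spaced 1.6 standardized units apart (more than
#' twice the default 0.5 matching tolerance, so adjacent entries can never
#' both fall inside one matching window).
#'
#' @return A [DiversityLadder-class] with 50 entries.
#' @export
defaultLadder <- function() {
  readLadder(system.file("extdata", "ladder_synthetic.tsv",
                         package = "ttgedyn", mustWork = TRUE))
}

.defaultGlotuParams <- function() {
  # Onset-week probabilities over weeks 1-8 (remaining mass = never
  # colonized), per-sample persistence after onset, and the initial score
  # distribution over {1,2,3}. Values emulate the cohort's qualitative
  # dynamics: staphylococci early and universal; enterococci early in a few
  # infants then steadily accruing; clostridia from the 2nd week reaching
  # ~70% of infants; enterobacteria delayed towards the 5th-8th week;
  # Veillonella in about a quarter of infants.
  list(
    "Staphylococcus" = list(
      onset = c(0.80, 0.13, 0.05, 0.02, 0, 0, 0, 0),
      persistence = 0.90, scoreInit = c(0.15, 0.30, 0.55), drift = 0.2),
    "Enterococcus" = list(
      onset = c(0.13, 0.05, 0.08, 0.10, 0.12, 0.10, 0.10, 0.09),
      persistence = 0.85, scoreInit = c(0.15, 0.25, 0.60), drift = 0.2),
    "Clostridium/Clostridiaceae" = list(
      onset = c(0, 0.10, 0.08, 0.15, 0.15, 0.12, 0.05, 0.05),
      persistence = 0.70, scoreInit = c(0.30, 0.30, 0.40), drift = 0.2),
    "Enterobacteriaceae" = list(
      onset = c(0.02, 0, 0, 0.03, 0.05, 0.08, 0.08, 0.07),
      persistence = 0.85, scoreInit = c(0.30, 0.20, 0.50), drift = 0.2),
    "Veillonella" = list(
      onset = c(0.05, 0, 0, 0.08, 0.08, 0.03, 0.02, 0),
      persistence = 0.80, scoreInit = c(0.50, 0.20, 0.30), drift = 0.2))
}

.defaultSlotuPools <- function() {
  tax <- readTaxonomyMap(system.file("extdata", "taxonomy_default.tsv",
                                     package = "ttgedyn", mustWork = TRUE))
  glotus <- names(.defaultGlotuParams())
  pools <- lapply(glotus, function(g)
    names(tax@slotuToGlotu)[tax@slotuToGlotu == g])
  names(pools) <- glotus
  pools
}

#' Simulation configuration
#'
#' Defines the synthetic cohort (infants, sampling calendar, per-GLOTU
#' colonization model) and the gel-rendering model (per-gel affine
#' distortion, per-band jitter, heteroduplex and spurious-band rates,
#' amplification failures). All defaults emulate the study conditions: 30
#' very preterm infants sampled once to twice a week between day 3 and day
#' 56, dominant early staphylococcal colonization, delayed
#' enterococcal/clostridial/enterobacterial colonization, roughly a quarter
#' of bands being heteroduplex artifacts and a few percent unassignable
#' faint bands, with occasional amplification failures.
#'
#' @param seed mandatory integer seed; the entire simulation is reproducible
#'   from it.
#' @param nInfants number of infants (default 30).
#' @param startDay,endDay sampling window in days of life (defaults 3, 56).
#' @param pTwoPerWeek probability a sampled week yields two samples instead
#'   of one (default 0.5, i.e. "once to twice a week").
#' @param dropout per-week probability the infant leaves the unit and
#'   sampling stops (default 0.02).
#' @param glotuParams named list of per-GLOTU colonization parameters
#'   (`onset` over weeks 1-8, `persistence`, `scoreInit`, `drift`); see
#'   defaults in the source.
#' @param slotuPools named list (same names) of candidate SLOTUs per GLOTU;
#'   one SLOTU is drawn per colonization episode.
#' @param lanesPerGel lanes per rendered gel (default 16).
#' @param slopeRange,interceptRange per-gel affine distortion ranges
#'   (defaults 0.9-1.1 and -2..2 standardized units).
#' @param jitterSd per-band positional jitter standard deviation (default
#'   0.15 units).
#' @param hdProbPerPair probability each pair of co-amplified taxa in a lane
#'   produces a heteroduplex band (default 0.55, calibrated so the rendered
#'   artifact-band fraction matches the study's observed 440/1772, about a
#'   quarter of bands).
#' @param spuriousRate Poisson mean of spurious faint off-ladder bands per
#'   lane (default 0.12, matching the study's 93/1772 unassignable bands).
#' @param failureProb per-sample amplification-failure probability (default
#'   0.04, about 14 in 354).
#' @param standardsReference named vector of the three internal standards'
#'   reference positions (default S1=10, S2=50, S3=90).
#' @param artifactBand acceptable range for the realism check on the
#'   simulated artifact-band fraction (default 0.15-0.35 around the study's
#'   observed ~25%).
#' @return A validated config list of class `ttge_sim_config`.
#' @export
simConfig <- function(seed, nInfants = 30, startDay = 3, endDay = 56,
                      pTwoPerWeek = 0.5, dropout = 0.02,
                      glotuParams = .defaultGlotuParams(),
                      slotuPools = .defaultSlotuPools(),
                      lanesPerGel = 16,
                      slopeRange = c(0.9, 1.1), interceptRange = c(-2, 2),
                      jitterSd = 0.15, hdProbPerPair = 0.55,
                      spuriousRate = 0.12, failureProb = 0.04,
                      standardsReference = c(S1 = 10, S2 = 50, S3 = 90),
                      artifactBand = c(0.15, 0.35)) {
  if (missing(seed) || !is.numeric(seed))
    stop("config error: a numeric seed is mandatory")
  probs <- c(pTwoPerWeek, dropout, hdProbPerPair, failureProb,
             unlist(lapply(glotuParams, function(p)
               c(p$onset, p$persistence, p$scoreInit, p$drift))))
  if (any(probs < 0 | probs > 1))
    stop("config error: all probabilities must lie in [0, 1]")
  if (endDay < startDay) stop("config error: endDay must be >= startDay")
  for (g in names(glotuParams)) {
    if (length(glotuParams[[g]]$onset) != 8 ||
        sum(glotuParams[[g]]$onset) > 1 + 1e-9)
      stop("config error: onset for ", g,
           " must give 8 weekly probabilities summing to <= 1")
    if (!length(slotuPools[[g]]))
      stop("config error: empty SLOTU pool for ", g)
  }
  structure(list(seed = seed, nInfants = nInfants, startDay = startDay,
                 endDay = endDay, pTwoPerWeek = pTwoPerWeek,
                 dropout = dropout, glotuParams = glotuParams,
                 slotuPools = slotuPools, lanesPerGel = lanesPerGel,
                 slopeRange = slopeRange, interceptRange = interceptRange,
                 jitterSd = jitterSd, hdProbPerPair = hdProbPerPair,
                 spuriousRate = spuriousRate, failureProb = failureProb,
                 standardsReference = standardsReference,
                 artifactBand = artifactBand),
            class = "ttge_sim_config")
}

.walkScore <- function(prev, drift) {
  if (stats::runif(1) >= drift) return(prev)
  min(3L, max(1L, prev + sample(c(-1L, 1L), 1)))
}

#' Simulate a longitudinal preterm cohort
#'
#' Colonization is modeled per (infant, GLOTU): an onset week is drawn from
#' the configured categorical distribution (possibly "never"); the first
#' sample at or after the onset week is positive, each later sample
#' independently positive with the persistence probability. One SLOTU per
#' episode is drawn from the GLOTU's pool; scores start from the initial
#' score distribution and evolve by a lazy random walk on {1,2,3}. Fully
#' reproducible from the config seed.
#'
#' @param config a [simConfig()] object.
#' @return list of class `ttge_sim_cohort` with `samples` (data.frame
#'   `infant_id`, `sample_id`, `day_of_life`, `week`), `scores` (data.frame
#'   `sample_id`, `infant_id`, `day_of_life`, `week`, `glotu_id`,
#'   `slotu_id`, `score`), `onsets` (data.frame of the drawn ground-truth
#'   onset weeks, NA = never) and `config`.
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "ttge_sim_config"))
  set.seed(as.integer(config$seed %% 2147483647))
  infants <- sprintf("I%02d", seq_len(config$nInfants))
  sampleRows <- list()
  for (inf in infants) {
    days <- integer()
    for (w in 1:8) {
      if (w > 1 && stats::runif(1) < config$dropout) break
      n <- 1L + (stats::runif(1) < config$pTwoPerWeek)
      lo <- max(config$startDay, 7 * (w - 1) + 1)
      hi <- min(config$endDay, 7 * w)
      if (lo > hi) next
      days <- c(days, sort(sample(lo:hi, min(n, hi - lo + 1))))
    }
    if (!length(days)) days <- config$startDay
    sampleRows[[inf]] <- data.frame(
      infant_id = inf,
      sample_id = sprintf("%s_d%02d", inf, days),
      day_of_life = days, week = weekOfLife(days),
      stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, sampleRows)
  rownames(samples) <- NULL

  onsetRows <- list()
  scoreRows <- list()
  for (inf in infants) {
    mine <- samples[samples$infant_id == inf, , drop = FALSE]
    for (g in names(config$glotuParams)) {
      p <- config$glotuParams[[g]]
      onset <- sample(c(1:8, NA), 1, prob = c(p$onset, 1 - sum(p$onset)))
      onsetRows[[paste(inf, g)]] <- data.frame(
        infant_id = inf, glotu_id = g, onset_week = onset,
        stringsAsFactors = FALSE)
      if (is.na(onset)) next
      eligible <- which(mine$week >= onset)
      if (!length(eligible)) next
      slotu <- sample(config$slotuPools[[g]], 1)
      score <- sample(1:3, 1, prob = p$scoreInit)
      for (k in seq_along(eligible)) {
        i <- eligible[k]
        positive <- k == 1 || stats::runif(1) < p$persistence
        if (positive) {
          scoreRows[[paste(inf, g, k)]] <- data.frame(
            sample_id = mine$sample_id[i], infant_id = inf,
            day_of_life = mine$day_of_life[i], week = mine$week[i],
            glotu_id = g, slotu_id = slotu, score = score,
            stringsAsFactors = FALSE)
          score <- .walkScore(score, p$drift)
        }
      }
    }
  }
  scores <- if (length(scoreRows)) do.call(rbind, scoreRows) else
    data.frame(sample_id = character(), infant_id = character(),
               day_of_life = integer(), week = integer(),
               glotu_id = character(), slotu_id = character(),
               score = integer(), stringsAsFactors = FALSE)
  scores <- scores[order(scores$infant_id, scores$day_of_life,
                         scores$slotu_id), , drop = FALSE]
  rownames(scores) <- NULL
  structure(list(samples = samples, scores = scores,
                 onsets = do.call(rbind, c(onsetRows,
                                           make.row.names = FALSE)),
                 config = config),
            class = "ttge_sim_cohort")
}

#' Render a simulated cohort to gel fingerprints
#'
#' Each sample becomes one lane; lanes are grouped onto gels and each gel
#' gets its own affine distortion (observed = intercept + slope * true).
#' Real bands sit at the SLOTU's ladder position plus per-band jitter;
#' internal standards are rendered through the same distortion, exactly.
#' Heteroduplex bands arise only in lanes with at least two distinct taxa
#' and are placed faint/thin either in the top zone or immediately next to a
#' bright parent band; spurious faint bands sit at off-ladder midpoints;
#' failed lanes carry nothing. Reproducible from the config seed
#' (independent of the stream used by [simulateCohort()]).
#'
#' @param cohort a `ttge_sim_cohort` from [simulateCohort()].
#' @param ladder the [DiversityLadder-class] providing true positions
#'   (default the packaged ladder); every simulated SLOTU must be on it.
#' @return list of class `ttge_sim_render`: `fingerprints` (list of
#'   [Fingerprint-class]), `bandTruth` (data.frame `band_id`, `sample_id`,
#'   `provenance` in {real, heteroduplex, spurious}, `true_slotu`), `gels`
#'   (per-gel distortion), `failedSamples` (character),
#'   `standardsReference`.
#' @export
renderGels <- function(cohort, ladder = defaultLadder()) {
  stopifnot(inherits(cohort, "ttge_sim_cohort"))
  config <- cohort$config
  set.seed(as.integer((config$seed + 777) %% 2147483647))
  e <- ladderEntries(ladder)
  pos <- structure(e$reference_distance, names = e$slotu_id)
  missingPos <- setdiff(unique(cohort$scores$slotu_id), names(pos))
  if (length(missingPos))
    stop("rendering error: no ladder position for ",
         paste(missingPos, collapse = ", "))
  mids <- (e$reference_distance[-1] + e$reference_distance[-nrow(e)]) / 2
  stdRef <- config$standardsReference
  samples <- cohort$samples
  nGels <- ceiling(nrow(samples) / config$lanesPerGel)
  gels <- data.frame(gel_id = sprintf("G%02d", seq_len(nGels)),
                     slope = stats::runif(nGels, config$slopeRange[1],
                                          config$slopeRange[2]),
                     intercept = stats::runif(nGels, config$interceptRange[1],
                                              config$interceptRange[2]),
                     stringsAsFactors = FALSE)
  fingerprints <- vector("list", nrow(samples))
  truthRows <- vector("list", nrow(samples))
  failed <- character()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    gelIdx <- ceiling(i / config$lanesPerGel)
    gid <- gels$gel_id[gelIdx]
    lid <- sprintf("L%02d", (i - 1) %% config$lanesPerGel + 1)
    warpTo <- function(true) gels$intercept[gelIdx] + gels$slope[gelIdx] * true
    if (stats::runif(1) < config$failureProb) {
      failed <- c(failed, sid)
      fingerprints[[i]] <- fingerprint(sid, gid, lid,
                                       amplificationFailed = TRUE)
      next
    }
    mine <- cohort$scores[cohort$scores$sample_id == sid, , drop = FALSE]
    dist <- numeric(); intens <- integer(); faint <- logical()
    prov <- character(); trueSlotu <- character()
    if (nrow(mine)) {
      dist <- warpTo(pos[mine$slotu_id]) +
        stats::rnorm(nrow(mine), 0, config$jitterSd)
      intens <- mine$score
      faint <- rep(FALSE, nrow(mine))
      prov <- rep("real", nrow(mine))
      trueSlotu <- mine$slotu_id
      # heteroduplexes need two distinct co-amplified templates
      if (nrow(mine) >= 2) {
        pairs <- utils::combn(nrow(mine), 2)
        for (k in seq_len(ncol(pairs))) {
          if (stats::runif(1) >= config$hdProbPerPair) next
          parents <- pairs[, k]
          bright <- parents[mine$score[parents] == 3]
          if (length(bright) && stats::runif(1) < 0.5) {
            anchor <- pos[mine$slotu_id[bright[1]]]
            hdTrue <- anchor + sample(c(-1, 1), 1) * stats::runif(1, 0.2, 0.6)
          } else {
            hdTrue <- stats::runif(1, 0.5, 4)
          }
          dist <- c(dist, max(0, warpTo(hdTrue)))  # a band cannot sit above the well
          intens <- c(intens, 1L)
          faint <- c(faint, TRUE)
          prov <- c(prov, "heteroduplex")
          trueSlotu <- c(trueSlotu, NA_character_)
        }
      }
    }
    nSpur <- stats::rpois(1, config$spuriousRate)
    if (nSpur > 0 && length(mids)) {
      spurTrue <- sample(mids, nSpur, replace = TRUE) +
        stats::runif(nSpur, -0.1, 0.1)
      dist <- c(dist, warpTo(spurTrue))
      intens <- c(intens, rep(1L, nSpur))
      faint <- c(faint, rep(FALSE, nSpur))
      prov <- c(prov, rep("spurious", nSpur))
      trueSlotu <- c(trueSlotu, rep(NA_character_, nSpur))
    }
    o <- order(dist)
    bandIds <- sprintf("%s:%s:b%02d", gid, lid, seq_along(dist))
    bandsDf <- if (length(dist))
      data.frame(band_id = bandIds, distance_raw = dist[o],
                 intensity_class = intens[o], is_faint_thin = faint[o],
                 sequence_ref = NA_character_, stringsAsFactors = FALSE)
      else .emptyBands()
    std <- data.frame(standard_id = names(stdRef),
                      observed_distance = unname(warpTo(stdRef)),
                      stringsAsFactors = FALSE)
    fingerprints[[i]] <- fingerprint(sid, gid, lid, bands = bandsDf,
                                     standardsObserved = std)
    if (length(dist))
      truthRows[[i]] <- data.frame(band_id = bandIds, sample_id = sid,
                                   provenance = prov[o],
                                   true_slotu = trueSlotu[o],
                                   stringsAsFactors = FALSE)
  }
  names(fingerprints) <- samples$sample_id
  bandTruth <- do.call(rbind, truthRows[!vapply(truthRows, is.null,
                                                logical(1))])
  if (is.null(bandTruth))
    bandTruth <- data.frame(band_id = character(), sample_id = character(),
                            provenance = character(),
                            true_slotu = character(), stringsAsFactors = FALSE)
  rownames(bandTruth) <- NULL
  structure(list(fingerprints = fingerprints, bandTruth = bandTruth,
                 gels = gels, failedSamples = failed,
                 standardsReference = stdRef),
            class = "ttge_sim_render")
}

#' Run the full analysis pipeline on a set of fingerprints
#'
#' Standardizes every non-failed lane against the shared standard reference
#' positions, assigns all bands (heteroduplex flagging, ladder matching,
#' optional sequence affiliation), and builds the scored cohort timeline.
#'
#' @param fingerprints list of [Fingerprint-class].
#' @param metadata data.frame (`sample_id`, `infant_id`, `day_of_life`).
#' @param ladder [DiversityLadder-class].
#' @param standardsReference named vector of shared standard positions.
#' @param sequences,referenceSeqs optional sequence collections for the 99%
#'   identity rule.
#' @param params [assignParams()].
#' @param taxmap [TaxonomyMap-class].
#' @return list with `assignments` (cohort band table), `timeline`
#'   ([CohortTimeline-class]), `accounting` (see [bandAccounting()]) and
#'   `failedSamples`.
#' @export
analyzeCohort <- function(fingerprints, metadata, ladder = defaultLadder(),
                          standardsReference = c(S1 = 10, S2 = 50, S3 = 90),
                          sequences = character(),
                          referenceSeqs = character(),
                          params = assignParams(),
                          taxmap = defaultTaxonomyMap()) {
  failed <- vapply(fingerprints, amplificationFailed, logical(1))
  assignments <- do.call(rbind, lapply(fingerprints[!failed], function(fp) {
    fp <- standardizeFingerprint(fp, standardsReference)
    assignFingerprint(fp, ladder, sequences, params, referenceSeqs)
  }))
  if (is.null(assignments))
    assignments <- data.frame(band_id = character(), sample_id = character(),
                              status = character(), slotu_id = character(),
                              method = character(), match_delta = numeric(),
                              intensity_class = integer(),
                              distance_std = numeric(), stringsAsFactors = FALSE)
  rownames(assignments) <- NULL
  failedIds <- vapply(fingerprints[failed], sampleId, character(1))
  timeline <- buildTimeline(assignments, metadata, taxmap,
                            failedSamples = unname(failedIds))
  list(assignments = assignments, timeline = timeline,
       accounting = bandAccounting(assignments),
       failedSamples = unname(failedIds))
}

#' Compare pipeline output against simulation ground truth
#'
#' @param result output of [analyzeCohort()] on the rendered fingerprints.
#' @param cohort the `ttge_sim_cohort` ground truth.
#' @param render the `ttge_sim_render` the pipeline consumed.
#' @param taxmap [TaxonomyMap-class] for status comparison at GLOTU level.
#' @return list of recovery metrics: `affiliationPrecision`,
#'   `affiliationRecall` (SLOTU-exact, over real bands), `artifactSensitivity`,
#'   `artifactSpecificity`, `ndRate`, `scoreAgreement` (fraction of
#'   (sample, SLOTU) detections with identical 0-3 score, over the union),
#'   `statusAgreement` (fraction of (infant, GLOTU) pairs with identical
#'   transient/persistent/not_colonized status). Metrics with an empty
#'   denominator are `NA`.
#' @export
evaluateRecovery <- function(result, cohort, render,
                             taxmap = defaultTaxonomyMap()) {
  a <- result$assignments
  tr <- render$bandTruth
  if (!all(a$band_id %in% tr$band_id))
    stop("alignment error: assignments contain bands unknown to the truth")
  m <- merge(a, tr, by = c("band_id", "sample_id"))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  isAff <- m$status == "affiliated"
  correct <- isAff & m$provenance == "real" &
    !is.na(m$slotu_id) & m$slotu_id == m$true_slotu
  metrics <- list(
    affiliationPrecision = ratio(sum(correct), sum(isAff)),
    affiliationRecall = ratio(sum(correct), sum(m$provenance == "real")),
    artifactSensitivity = ratio(
      sum(m$status == "artifact_heteroduplex" & m$provenance == "heteroduplex"),
      sum(m$provenance == "heteroduplex")),
    artifactSpecificity = ratio(
      sum(m$status != "artifact_heteroduplex" & m$provenance != "heteroduplex"),
      sum(m$provenance != "heteroduplex")),
    ndRate = ratio(sum(m$status == "not_determined"), nrow(m)))

  analyzable <- setdiff(cohort$samples$sample_id, render$failedSamples)
  truthScores <- cohort$scores[cohort$scores$sample_id %in% analyzable, ,
                               drop = FALSE]
  pipeScores <- timelineScores(result$timeline)
  keyT <- paste(truthScores$sample_id, truthScores$slotu_id)
  keyP <- paste(pipeScores$sample_id, pipeScores$slotu_id)
  allKeys <- union(keyT, keyP)
  sT <- truthScores$score[match(allKeys, keyT)]
  sP <- pipeScores$score[match(allKeys, keyP)]
  metrics$scoreAgreement <- ratio(sum(!is.na(sT) & !is.na(sP) & sT == sP),
                                  length(allKeys))

  truthTl <- cohortTimeline(
    data.frame(sample_id = cohort$samples$sample_id,
               infant_id = cohort$samples$infant_id,
               day_of_life = cohort$samples$day_of_life,
               analyzable = cohort$samples$sample_id %in% analyzable,
               stringsAsFactors = FALSE),
    truthScores[, c("sample_id", "slotu_id", "score")], taxmap)
  ctT <- colonizationTable(truthTl, level = "glotu")
  ctP <- colonizationTable(result$timeline, level = "glotu")
  kT <- paste(ctT$infant_id, ctT$otu_id)
  kP <- paste(ctP$infant_id, ctP$otu_id)
  allPairs <- union(kT, kP)
  stT <- ifelse(is.na(match(allPairs, kT)), "not_colonized",
                ctT$status[match(allPairs, kT)])
  stP <- ifelse(is.na(match(allPairs, kP)), "not_colonized",
                ctP$status[match(allPairs, kP)])
  metrics$statusAgreement <- ratio(sum(stT == stP), length(allPairs))
  metrics
}
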