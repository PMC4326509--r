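# A small hand-built two-infant timeline used across dynamics tests.
# I01: days 8, 10 (week 2), day 16 (week 3); I02: day 9 (week 2).
makeToyTimeline <- function() {
  sepi <- "Staphylococcus epidermidis group"
  shae <- "Staphylococcus haemolyticus"
  efae <- "Enterococcus faecalis"
  samples <- data.frame(
    infant_id = c("I01", "I01", "I01", "I02"),
    sample_id = c("a", "b", "c", "d"),
    day_of_life = c(8, 10, 16, 9), stringsAsFactors = FALSE)
  scores <- data.frame(
    sample_id = c("a", "a", "b", "c", "d"),
    slotu_id = c(sepi, shae, sepi, sepi, efae),
    score = c(3, 1, 1, 2, 2), stringsAsFactors = FALSE)
  cohortTimeline(samples, scores, defaultTaxonomyMap())
}

test_that("week binning follows ceil(day / 7)", {
  expect_equal(weekOfLife(c(1, 3, 7, 8, 14, 15, 50, 56)),
               c(1L, 1L, 1L, 2L, 2L, 3L, 8L, 8L))
  expect_error(weekOfLife(0), ">= 1")
})

test_that("per-sample scoring takes the brightest band per SLOTU", {
  asg <- data.frame(
    band_id = paste0("b", 1:4),
    status = c("affiliated", "affiliated", "affiliated",
               "artifact_heteroduplex"),
    slotu_id = c("X", "X", "Y", NA),
    intensity_class = c(1L, 3L, 2L, 3L), stringsAsFactors = FALSE)
  expect_equal(scoreSample(asg), c(X = 3L, Y = 2L))
  expect_length(scoreSample(asg[asg$status == "none", ]), 0)
})

test_that("weekly GLOTU score averages over samples and detected member OTUs", {
  tl <- makeToyTimeline()
  # week 2 for I01: samples a, b; members ever detected: sepi + shae
  # a: sepi 3, shae 1; b: sepi 1, shae 0 -> mean over 2x2 = 5/4
  w <- weeklyGlotuScore(tl, "I01", "Staphylococcus")
  expect_equal(w[["2"]], 5 / 4)
  # week 3: single sample c: sepi 2, shae 0 -> 1
  expect_equal(w[["3"]], 1)
  # never-colonized GLOTU: empty mapping, not zeros
  expect_length(weeklyGlotuScore(tl, "I01", "Veillonella"), 0)
  expect_error(weeklyGlotuScore(tl, "nobody", "Veillonella"), "unknown infant")
})

test_that("cohort weekly dynamics count colonized infants per sampled week", {
  tl <- makeToyTimeline()
  dyn <- cohortWeeklyDynamics(tl, "Staphylococcus")
  w2 <- dyn[dyn$week == 2, ]
  expect_equal(w2$n_sampled, 2)          # both infants sampled in week 2
  expect_equal(w2$n_colonized, 1)        # only I01 carries staphylococci
  expect_equal(w2$fraction_colonized, 0.5)
  expect_equal(w2$mean_score_colonized, 5 / 4)
  expect_equal(w2$mean_max_score_colonized, 3)  # I01's brightest that week
  ent <- cohortWeeklyDynamics(tl, "Enterococcus")
  expect_equal(ent$n_colonized[ent$week == 2], 1)
  expect_true(all(dyn$fraction_colonized >= 0 & dyn$fraction_colonized <= 1))
})

test_that("detection periods report min and max positive days", {
  tl <- makeToyTimeline()
  sepi <- "Staphylococcus epidermidis group"
  expect_equal(detectionPeriod(tl, sepi),
               c(first_day = 8, last_day = 16))
  expect_equal(detectionPeriod(tl, "Enterococcus faecalis"),
               c(first_day = 9, last_day = 9))
  expect_null(detectionPeriod(tl, "Veillonella dispar"))
  # per-infant restriction
  expect_equal(detectionPeriod(tl, sepi, infant_id = "I01"),
               c(first_day = 8, last_day = 16))
})

test_that("colonization classification matches the counting rule", {
  expect_equal(classifyColonization(c(TRUE, TRUE, TRUE, FALSE, TRUE))$status,
               "persistent")  # 3/4 subsequent positive
  expect_equal(classifyColonization(c(FALSE, TRUE, FALSE, FALSE, FALSE))$status,
               "transient")   # 0/3
  expect_equal(classifyColonization(c(FALSE, FALSE, TRUE))$status,
               "transient")   # empty subsequent set
  expect_equal(classifyColonization(logical(3))$status, "not_colonized")
  cl <- classifyColonization(c(FALSE, TRUE, TRUE), days = c(3, 10, 17))
  expect_equal(cl$first_day, 10)
  expect_equal(cl$last_day, 17)
  expect_equal(cl$n_subsequent_positive, 1L)
  expect_equal(cl$n_subsequent_total, 1L)
})

test_that("classification equals the exhaustive oracle on all length-8 series", {
  for (code in 0:(2^8 - 1)) {
    positive <- as.logical(bitwAnd(bitwShiftR(code, 0:7), 1))
    expect_equal(classifyColonization(positive)$status,
                 bruteForceStatus(positive), info = code)
  }
})

test_that("diversity statistics cover weekly means, per-sample max and totals", {
  tl <- makeToyTimeline()
  ds <- diversityStats(tl)
  i1 <- ds$weekly[ds$weekly$infant_id == "I01", ]
  expect_equal(i1$mean_n_otus[i1$week == 2], 1.5)  # {sepi,shae} then {sepi}
  p1 <- ds$per_infant[ds$per_infant$infant_id == "I01", ]
  expect_equal(p1$max_per_sample, 2)
  expect_equal(p1$total_distinct, 2)
  # an infant with no detections scores zero
  samples <- data.frame(infant_id = "I09", sample_id = "z", day_of_life = 5)
  empty <- cohortTimeline(samples)
  dz <- diversityStats(empty)
  expect_equal(dz$per_infant$total_distinct, 0)
  expect_equal(dz$weekly$mean_n_otus, 0)
})

test_that("statistics ignore non-analyzable samples and score-0 padding", {
  sepi <- "Staphylococcus epidermidis group"
  samples <- data.frame(
    infant_id = "I01", sample_id = c("a", "b", "c"),
    day_of_life = c(8, 10, 12), analyzable = c(TRUE, FALSE, TRUE))
  scores <- data.frame(sample_id = c("a", "c"), slotu_id = sepi,
                       score = c(3, 3))
  tl <- cohortTimeline(samples, scores, defaultTaxonomyMap())
  # failed sample b does not dilute the weekly mean
  expect_equal(weeklyGlotuScore(tl, "I01", "Staphylococcus")[["2"]], 3)
  # and a zero score is never stored
  scores0 <- rbind(scores, data.frame(sample_id = "a", slotu_id = "Veillonella dispar",
                                      score = 0))
  tl0 <- cohortTimeline(samples, scores0, defaultTaxonomyMap())
  expect_equal(nrow(timelineScores(tl0)), 2)
})
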