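#' Week-of-life index of a sampling day
#'
#' `ceiling(day / 7)`: days 1-7 are week 1, day 8 starts week 2, day 56 ends
#' week 8.
#'
#' @param day_of_life integer vector of days (>= 1).
#' @return Integer vector of week indices.
#' @export
weekOfLife <- function(day_of_life) {
  if (any(is.na(day_of_life)) || any(day_of_life < 1))
    stop("day_of_life must be >= 1")
  as.integer(ceiling(day_of_life / 7))
}

#' Semi-quantitative score of each OTU in one sample
#'
#' The 0-3 score is the band intensity class (+/++/+++ = 1/2/3); when one
#' SLOTU produced several bands in a lane the brightest wins. Absent OTUs
#' have score 0, implicitly: they do not appear in the result.
#'
#' @param assignments assignment data.frame for one sample (only
#'   `affiliated` rows are scored).
#' @return Named integer vector, SLOTU id -> score in {1,2,3}.
#' @export
scoreSample <- function(assignments) {
  aff <- assignments[assignments$status == "affiliated", , drop = FALSE]
  if (!nrow(aff)) return(structure(integer(), names = character()))
  vapply(split(aff$intensity_class, aff$slotu_id),
         function(x) as.integer(max(x)), integer(1))
}

#' Build a cohort timeline from assignments and sample metadata
#'
#' @param assignments row-bound assignment data.frame for the cohort (must
#'   carry `sample_id`).
#' @param metadata data.frame (`sample_id`, `infant_id`, `day_of_life`) from
#'   [readCohortMetadata()]; every assignment sample must be listed.
#' @param taxmap [TaxonomyMap-class] for GLOTU/PLOTU annotation.
#' @param failedSamples character vector of sample ids whose amplification
#'   failed; marked non-analyzable and excluded from denominators.
#' @return A [CohortTimeline-class].
#' @export
buildTimeline <- function(assignments, metadata, taxmap = defaultTaxonomyMap(),
                          failedSamples = character()) {
  unknown <- setdiff(unique(assignments$sample_id), metadata$sample_id)
  if (length(unknown))
    stop("assignments reference samples missing from metadata: ",
         paste(unknown, collapse = ", "))
  samples <- metadata
  samples$analyzable <- !(samples$sample_id %in% failedSamples)
  perSample <- lapply(split(assignments, assignments$sample_id), scoreSample)
  scoreRows <- do.call(rbind, lapply(names(perSample), function(sid) {
    sc <- perSample[[sid]]
    if (!length(sc)) return(NULL)
    data.frame(sample_id = sid, slotu_id = names(sc), score = unname(sc),
               stringsAsFactors = FALSE)
  }))
  cohortTimeline(samples, scoreRows, taxmap)
}

.memberOtus <- function(timeline, infant_id, glotu_id) {
  x <- timelineScores(timeline)
  unique(x$slotu_id[x$infant_id == infant_id & x$glotu_id == glotu_id])
}

#' Weekly mean GLOTU score for one infant
#'
#' For each week in which the infant has analyzable samples, the mean of the
#' member-OTU scores over that week's samples. Member OTUs are the SLOTUs of
#' the GLOTU ever detected in this infant: an OTU never detected contributes
#' nothing, while a detected-then-absent OTU contributes 0 for samples where
#' it is missing. Weeks without samples are absent from the result (not 0).
#'
#' @param timeline [CohortTimeline-class].
#' @param infant_id,glotu_id scalars identifying the series.
#' @return Named numeric vector, week -> mean score; empty when the infant
#'   never carried the GLOTU.
#' @export
weeklyGlotuScore <- function(timeline, infant_id, glotu_id) {
  s <- timelineSamples(timeline)
  if (!infant_id %in% s$infant_id) stop("unknown infant: ", infant_id)
  members <- .memberOtus(timeline, infant_id, glotu_id)
  if (!length(members)) return(structure(numeric(), names = character()))
  mine <- s[s$infant_id == infant_id & s$analyzable, , drop = FALSE]
  x <- timelineScores(timeline)
  x <- x[x$infant_id == infant_id & x$glotu_id == glotu_id, , drop = FALSE]
  out <- vapply(split(mine$sample_id, mine$week), function(sids) {
    # samples x member-OTUs score matrix, absent = 0
    tot <- 0
    for (sid in sids) for (m in members) {
      v <- x$score[x$sample_id == sid & x$slotu_id == m]
      tot <- tot + if (length(v)) v else 0
    }
    tot / (length(sids) * length(members))
  }, numeric(1))
  out
}

#' Cohort-level weekly dynamics of a GLOTU
#'
#' Per week: number of infants with at least one analyzable sample
#' (`n_sampled`), number colonized (weekly GLOTU score > 0), the colonized
#' fraction, the mean weekly GLOTU score among colonized infants, and the
#' mean of the colonized infants' maximal within-week scores. Mean columns
#' are `NA` in weeks without colonized infants. Two colonized fractions are
#' given: over infants sampled that week (`fraction_colonized`) and over the
#' whole cohort (`fraction_cohort`).
#'
#' @param timeline [CohortTimeline-class].
#' @param glotu_id GLOTU to trace.
#' @return data.frame with one row per week in the sampled range.
#' @export
cohortWeeklyDynamics <- function(timeline, glotu_id) {
  s <- timelineSamples(timeline)
  s <- s[s$analyzable, , drop = FALSE]
  x <- timelineScores(timeline)
  x <- x[x$glotu_id == glotu_id, , drop = FALSE]
  nInfants <- length(unique(timelineSamples(timeline)$infant_id))
  weeks <- sort(unique(s$week))
  rows <- lapply(weeks, function(w) {
    sw <- s[s$week == w, , drop = FALSE]
    sampled <- unique(sw$infant_id)
    xw <- x[x$week == w, , drop = FALSE]
    colonized <- intersect(sampled, unique(xw$infant_id))
    meanScore <- meanMax <- NA_real_
    if (length(colonized)) {
      perInfant <- vapply(colonized, function(inf) {
        ws <- weeklyGlotuScore(timeline, inf, glotu_id)
        ws[[as.character(w)]]
      }, numeric(1))
      meanScore <- mean(perInfant)
      meanMax <- mean(vapply(colonized, function(inf)
        max(xw$score[xw$infant_id == inf]), numeric(1)))
    }
    data.frame(week = w, n_sampled = length(sampled),
               n_colonized = length(colonized),
               fraction_colonized = length(colonized) / length(sampled),
               fraction_cohort = length(colonized) / nInfants,
               mean_score_colonized = meanScore,
               mean_max_score_colonized = meanMax)
  })
  do.call(rbind, rows)
}

#' First and last day of detection of an OTU
#'
#' @param timeline [CohortTimeline-class].
#' @param otu_id SLOTU to look up.
#' @param infant_id optional; restrict to one infant (default: whole
#'   cohort, i.e. min of first days and max of last days over infants).
#' @return Named numeric vector `c(first_day, last_day)`, or `NULL` when
#'   never detected.
#' @export
detectionPeriod <- function(timeline, otu_id, infant_id = NULL) {
  x <- timelineScores(timeline)
  x <- x[x$slotu_id == otu_id, , drop = FALSE]
  if (!is.null(infant_id)) x <- x[x$infant_id == infant_id, , drop = FALSE]
  if (!nrow(x)) return(NULL)
  c(first_day = min(x$day_of_life), last_day = max(x$day_of_life))
}

#' Classify an infant's colonization by an OTU as transient or persistent
#'
#' Samples strictly after the first positive sample form the subsequent set;
#' colonization is persistent when more than half of them are positive for
#' the OTU, transient when half or fewer. A first positive with no
#' subsequent samples is transient; an infant never positive is
#' `not_colonized`.
#'
#' @param positive logical vector of the infant's analyzable samples in day
#'   order (`TRUE` = OTU detected).
#' @param days optional integer vector of sampling days (same length),
#'   used only to report `first_day`/`last_day`.
#' @return list with `status` ("persistent", "transient" or
#'   "not_colonized"), `first_day`, `last_day`, `n_subsequent_positive`,
#'   `n_subsequent_total`.
#' @examples
#' classifyColonization(c(TRUE, TRUE, TRUE, FALSE, TRUE))$status  # persistent
#' classifyColonization(c(FALSE, TRUE, FALSE, FALSE, FALSE))$status  # transient
#' @export
classifyColonization <- function(positive, days = seq_along(positive)) {
  stopifnot(is.logical(positive), length(days) == length(positive))
  if (!any(positive))
    return(list(status = "not_colonized", first_day = NA_integer_,
                last_day = NA_integer_, n_subsequent_positive = 0L,
                n_subsequent_total = 0L))
  first <- which(positive)[1]
  subsequent <- positive[seq_along(positive) > first]
  nPos <- sum(subsequent)
  nTot <- length(subsequent)
  status <- if (nTot > 0 && nPos / nTot > 0.5) "persistent" else "transient"
  list(status = status, first_day = days[first],
       last_day = days[max(which(positive))],
       n_subsequent_positive = as.integer(nPos),
       n_subsequent_total = as.integer(nTot))
}

#' Colonization status of every (infant, OTU) pair in a timeline
#'
#' @param timeline [CohortTimeline-class].
#' @param level `"slotu"` (default) or `"glotu"`: the OTU granularity at
#'   which positivity is assessed.
#' @return data.frame: `infant_id`, `otu_id`, `status`, `first_day`,
#'   `last_day`, `n_subsequent_positive`, `n_subsequent_total`; one row per
#'   (infant, OTU-detected-in-that-infant) pair.
#' @export
colonizationTable <- function(timeline, level = c("slotu", "glotu")) {
  level <- match.arg(level)
  idCol <- if (level == "slotu") "slotu_id" else "glotu_id"
  s <- timelineSamples(timeline)
  s <- s[s$analyzable, , drop = FALSE]
  x <- timelineScores(timeline)
  pairs <- unique(x[, c("infant_id", idCol)])
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    inf <- pairs$infant_id[i]
    otu <- pairs[[idCol]][i]
    mine <- s[s$infant_id == inf, , drop = FALSE]
    mine <- mine[order(mine$day_of_life), , drop = FALSE]
    pos <- vapply(mine$sample_id, function(sid)
      any(x$sample_id == sid & x[[idCol]] == otu), logical(1))
    cl <- classifyColonization(pos, mine$day_of_life)
    data.frame(infant_id = inf, otu_id = otu, status = cl$status,
               first_day = cl$first_day, last_day = cl$last_day,
               n_subsequent_positive = cl$n_subsequent_positive,
               n_subsequent_total = cl$n_subsequent_total,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-infant diversity statistics
#'
#' For each infant: the mean number of distinct affiliated SLOTUs per sample
#' for every sampled week, the maximal number of SLOTUs seen in any single
#' sample, and the total distinct SLOTUs over all samples.
#'
#' @param timeline [CohortTimeline-class].
#' @return list with `weekly` (data.frame `infant_id`, `week`,
#'   `mean_n_otus`) and `per_infant` (data.frame `infant_id`,
#'   `max_per_sample`, `total_distinct`).
#' @export
diversityStats <- function(timeline) {
  s <- timelineSamples(timeline)
  s <- s[s$analyzable, , drop = FALSE]
  x <- timelineScores(timeline)
  nPerSample <- vapply(s$sample_id, function(sid)
    length(unique(x$slotu_id[x$sample_id == sid])), integer(1))
  weekly <- do.call(rbind, lapply(split(seq_len(nrow(s)),
                                        paste(s$infant_id, s$week, sep = "\r")),
    function(idx) data.frame(infant_id = s$infant_id[idx[1]],
                             week = s$week[idx[1]],
                             mean_n_otus = mean(nPerSample[idx]),
                             stringsAsFactors = FALSE)))
  weekly <- weekly[order(weekly$infant_id, weekly$week), , drop = FALSE]
  rownames(weekly) <- NULL
  perInfant <- do.call(rbind, lapply(split(seq_len(nrow(s)), s$infant_id),
    function(idx) {
      inf <- s$infant_id[idx[1]]
      data.frame(infant_id = inf,
                 max_per_sample = if (length(idx)) max(nPerSample[idx]) else 0L,
                 total_distinct = length(unique(
                   x$slotu_id[x$infant_id == inf])),
                 stringsAsFactors = FALSE)
    }))
  rownames(perInfant) <- NULL
  list(weekly = weekly, per_infant = perInfant)
}
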