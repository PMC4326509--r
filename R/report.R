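#' Band-accounting reconciliation
#'
#' Every detected band is exactly one of: affiliated to a SLOTU, excluded as
#' a heteroduplex artifact, or not determined (off-ladder and too faint to
#' sequence). Given any two of the partition's pieces plus the total, the
#' third follows; given a cohort assignment table, all four are counted.
#'
#' @param x either a cohort assignment data.frame (with a `status` column)
#'   or `NULL` when the explicit counts are supplied.
#' @param n_detected,n_artifact,n_unassigned explicit counts (used when `x`
#'   is NULL); `n_affiliated` is derived as their difference.
#' @return list `n_detected`, `n_artifact`, `n_unassigned`, `n_affiliated`
#'   satisfying `n_detected = n_artifact + n_unassigned + n_affiliated`.
#' @examples
#' bandAccounting(n_detected = 1772, n_artifact = 440, n_unassigned = 93)
#' @export
bandAccounting <- function(x = NULL, n_detected = NULL, n_artifact = NULL,
                           n_unassigned = NULL) {
  if (!is.null(x)) {
    acc <- list(n_detected = nrow(x),
                n_artifact = sum(x$status == "artifact_heteroduplex"),
                n_unassigned = sum(x$status == "not_determined"),
                n_affiliated = sum(x$status == "affiliated"))
  } else {
    acc <- list(n_detected = n_detected, n_artifact = n_artifact,
                n_unassigned = n_unassigned,
                n_affiliated = n_detected - n_artifact - n_unassigned)
  }
  if (acc$n_detected !=
      acc$n_artifact + acc$n_unassigned + acc$n_affiliated ||
      acc$n_affiliated < 0)
    stop("band accounting does not reconcile")
  acc
}

#' Per-SLOTU summary table (occurrence, period, score spectrum)
#'
#' One row per detected SLOTU: number and percentage of positive samples,
#' number and percentage of colonized infants, detection period, counts of
#' the three score classes (which sum to the positive-sample count, one
#' score per positive sample) and the modal score class. Percentages are
#' recomputed from counts at render time. Rows are ordered by GLOTU
#' occurrence (total positive samples, decreasing) and, within a GLOTU, by
#' the SLOTU's sample count.
#'
#' @param timeline [CohortTimeline-class].
#' @param map [TaxonomyMap-class].
#' @return data.frame of summary rows.
#' @export
otuSummaryTable <- function(timeline, map = defaultTaxonomyMap()) {
  x <- timelineScores(timeline)
  s <- timelineSamples(timeline)
  nSamples <- sum(s$analyzable)
  nInfants <- length(unique(s$infant_id))
  if (!nrow(x))
    return(data.frame(slotu_id = character(), glotu_id = character(),
                      n_samples = integer(), pct_samples = numeric(),
                      n_infants = integer(), pct_infants = numeric(),
                      first_day = integer(), last_day = integer(),
                      score1_n = integer(), score2_n = integer(),
                      score3_n = integer(), modal_score = integer(),
                      stringsAsFactors = FALSE))
  rows <- lapply(split(x, x$slotu_id), function(g) {
    counts <- vapply(1:3, function(k) sum(g$score == k), integer(1))
    data.frame(slotu_id = g$slotu_id[1], glotu_id = g$glotu_id[1],
               n_samples = nrow(g),
               pct_samples = 100 * nrow(g) / nSamples,
               n_infants = length(unique(g$infant_id)),
               pct_infants = 100 * length(unique(g$infant_id)) / nInfants,
               first_day = min(g$day_of_life), last_day = max(g$day_of_life),
               score1_n = counts[1], score2_n = counts[2],
               score3_n = counts[3], modal_score = which.max(counts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  glotuTotals <- tapply(out$n_samples, out$glotu_id, sum)
  out <- out[order(-glotuTotals[out$glotu_id], out$glotu_id,
                   -out$n_samples), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' GLOTU repartition of affiliated bands
#'
#' @param assignments cohort assignment data.frame.
#' @param map [TaxonomyMap-class].
#' @return data.frame (`glotu_id`, `n_bands`, `pct_bands`); percentages over
#'   affiliated bands only (artifacts and undetermined excluded) and summing
#'   to 100 up to rounding.
#' @export
glotuRepartition <- function(assignments, map = defaultTaxonomyMap()) {
  g <- distinctGroups(assignments, map, level = "glotu")
  if (!nrow(g))
    return(data.frame(glotu_id = character(), n_bands = integer(),
                      pct_bands = numeric(), stringsAsFactors = FALSE))
  data.frame(glotu_id = g$group_id, n_bands = g$n_bands,
             pct_bands = 100 * g$n_bands / sum(g$n_bands),
             stringsAsFactors = FALSE)
}

#' High-level taxon (PLOTU) profile of one infant
#'
#' The fraction of the infant's positive (sample, OTU) detections falling in
#' each phylum/class-level group; fractions sum to 1 for infants with at
#' least one affiliated detection, and the profile is empty for infants with
#' none.
#'
#' @param timeline [CohortTimeline-class].
#' @param infant_id infant to profile.
#' @return Named numeric vector, PLOTU -> fraction.
#' @export
patientPlotuProfile <- function(timeline, infant_id) {
  s <- timelineSamples(timeline)
  if (!infant_id %in% s$infant_id) stop("unknown infant: ", infant_id)
  x <- timelineScores(timeline)
  x <- x[x$infant_id == infant_id, , drop = FALSE]
  if (!nrow(x)) return(structure(numeric(), names = character()))
  tab <- table(x$plotu_id)
  structure(as.numeric(tab) / sum(tab), names = names(tab))
}

#' Load the packaged cohort summary-table fixture
#'
#' A machine-readable transcription of the study's published per-OTU summary
#' table: 50 species-level OTU rows (plus the separate not-determined band
#' group) with sample counts, infant counts, detection periods and score
#' spectra, together with the cohort constants (30 infants, 354 samples of
#' which 14 failed amplification). Printed percentages are kept verbatim in
#' `pct_samples_printed` / `pct_infants_printed` for provenance; all
#' computation uses the counts. Known print inconsistencies are annotated in
#' `remarks`, not silently corrected.
#'
#' @return list with `rows` (50-row data.frame of SLOTU summaries), `nd`
#'   (the one not-determined row), `n_infants` (30), `n_samples` (354),
#'   `n_failed` (14).
#' @export
loadPaperTable1 <- function() {
  path <- system.file("extdata", "table1_fixture.tsv", package = "ttgedyn",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  rows <- tab[tab$is_slotu, , drop = FALSE]
  nd <- tab[!tab$is_slotu, , drop = FALSE]
  rownames(rows) <- rownames(nd) <- NULL
  if (nrow(rows) != 50)
    stop("fixture integrity failure: expected 50 SLOTU rows, got ",
         nrow(rows))
  bad <- rows$score1_n + rows$score2_n + rows$score3_n != rows$n_samples
  if (any(bad))
    stop("fixture integrity failure: score counts do not sum to n_samples for ",
         paste(rows$slotu_id[bad], collapse = ", "))
  list(rows = rows, nd = nd, n_infants = 30L, n_samples = 354L,
       n_failed = 14L)
}
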