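#' Accessors for package classes
#'
#' `bands()`, `standardsObserved()`, `sampleId()`, `gelId()`, `laneId()` and
#' `amplificationFailed()` read the slots of a [Fingerprint-class];
#' `ladderEntries()` the entries of a [DiversityLadder-class];
#' `timelineSamples()` and `timelineScores()` the two tables of a
#' [CohortTimeline-class]; `warpKnots()` the knot matrix of a
#' [WarpFunction-class].
#'
#' @param x an object of the respective class.
#' @return The slot contents (a data.frame, matrix or scalar).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bands", function(x) standardGeneric("bands"))
#' @rdname accessors
#' @export
setGeneric("standardsObserved",
           function(x) standardGeneric("standardsObserved"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("gelId", function(x) standardGeneric("gelId"))
#' @rdname accessors
#' @export
setGeneric("laneId", function(x) standardGeneric("laneId"))
#' @rdname accessors
#' @export
setGeneric("amplificationFailed",
           function(x) standardGeneric("amplificationFailed"))
#' @rdname accessors
#' @export
setGeneric("ladderEntries", function(x) standardGeneric("ladderEntries"))
#' @rdname accessors
#' @export
setGeneric("timelineSamples", function(x) standardGeneric("timelineSamples"))
#' @rdname accessors
#' @export
setGeneric("timelineScores", function(x) standardGeneric("timelineScores"))
#' @rdname accessors
#' @export
setGeneric("warpKnots", function(x) standardGeneric("warpKnots"))

#' @rdname accessors
setMethod("bands", "Fingerprint", function(x) x@bands)
#' @rdname accessors
setMethod("standardsObserved", "Fingerprint",
          function(x) x@standardsObserved)
#' @rdname accessors
setMethod("sampleId", "Fingerprint", function(x) x@sampleId)
#' @rdname accessors
setMethod("gelId", "Fingerprint", function(x) x@gelId)
#' @rdname accessors
setMethod("laneId", "Fingerprint", function(x) x@laneId)
#' @rdname accessors
setMethod("amplificationFailed", "Fingerprint",
          function(x) x@amplificationFailed)
#' @rdname accessors
setMethod("ladderEntries", "DiversityLadder", function(x) x@entries)
#' @rdname accessors
setMethod("timelineSamples", "CohortTimeline", function(x) x@samples)
#' @rdname accessors
setMethod("timelineScores", "CohortTimeline", function(x) x@scores)
#' @rdname accessors
setMethod("warpKnots", "WarpFunction", function(x) x@knots)

setMethod("show", "Fingerprint", function(object) {
  cat("Fingerprint for sample", object@sampleId,
      sprintf("(gel %s, lane %s)\n", object@gelId, object@laneId))
  if (object@amplificationFailed) {
    cat("  amplification failed (no bands)\n")
  } else {
    cat(sprintf("  %d band(s), %d internal standard(s) observed\n",
                nrow(object@bands), nrow(object@standardsObserved)))
  }
  invisible(NULL)
})

setMethod("show", "DiversityLadder", function(object) {
  e <- object@entries
  cat(sprintf("DiversityLadder with %d entries", nrow(e)))
  if (nrow(e))
    cat(sprintf(" spanning %.1f-%.1f standardized units",
                min(e$reference_distance), max(e$reference_distance)))
  cat("\n")
  invisible(NULL)
})

setMethod("show", "TaxonomyMap", function(object) {
  cat(sprintf(
    "TaxonomyMap: %d SLOTUs -> %d GLOTUs -> %d PLOTUs (%d override(s))\n",
    length(object@slotuToGlotu), length(unique(object@slotuToGlotu)),
    length(unique(object@glotuToPlotu)), length(object@overrides)))
  invisible(NULL)
})

setMethod("show", "WarpFunction", function(object) {
  k <- object@knots
  cat(sprintf("WarpFunction with %d knots: ", nrow(k)))
  cat(paste(sprintf("%.3g->%.3g", k[, 1], k[, 2]), collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "CohortTimeline", function(object) {
  s <- object@samples
  cat(sprintf(paste0("CohortTimeline: %d infants, %d samples ",
                     "(%d analyzable), %d positive (sample, OTU) scores\n"),
              length(unique(s$infant_id)), nrow(s), sum(s$analyzable),
              nrow(object@scores)))
  invisible(NULL)
})
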