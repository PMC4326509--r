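#' @import methods
NULL

# Column layouts shared by readers, constructors and validity checks.
.BAND_COLS <- c("band_id", "distance_raw", "intensity_class",
                "is_faint_thin", "sequence_ref")
.STD_COLS <- c("standard_id", "observed_distance")

.emptyBands <- function() {
  data.frame(band_id = character(), distance_raw = numeric(),
             intensity_class = integer(), is_faint_thin = logical(),
             sequence_ref = character(), stringsAsFactors = FALSE)
}

.emptyStandards <- function() {
  data.frame(standard_id = character(), observed_distance = numeric(),
             stringsAsFactors = FALSE)
}

#' Fingerprint: one sample's TTGE lane
#'
#' A `Fingerprint` holds the digitized content of a single gel lane: the
#' detected bands (migration distance from the well, ordinal intensity class
#' 1-3 corresponding to +/++/+++, and a faint/thin morphology flag used for
#' heteroduplex screening), the lane's observed internal migration standards,
#' and an amplification-failure flag. Failed lanes carry no bands and are
#' excluded from analysis denominators.
#'
#' Distances are dimensionless gel units (0 at the well, increasing towards
#' the gel bottom, nominally 0-100 over a lane). A standardized-coordinate
#' column `distance_std` is added to `bands` by
#' [standardizeFingerprint()].
#'
#' @slot sampleId character scalar, the stool-sample identifier.
#' @slot gelId character scalar, the gel the lane was run on.
#' @slot laneId character scalar, lane within the gel.
#' @slot bands data.frame with columns `band_id`, `distance_raw`,
#'   `intensity_class`, `is_faint_thin`, `sequence_ref` (NA when the band was
#'   not excised and sequenced), sorted by increasing `distance_raw`.
#' @slot standardsObserved data.frame with columns `standard_id`,
#'   `observed_distance`; either empty or exactly three rows (the three
#'   internal migration standards).
#' @slot amplificationFailed logical scalar; `TRUE` lanes have no bands.
#'
#' @seealso [fingerprint()] for the user-facing constructor,
#'   [readBandTable()] to parse a digitized band table.
#' @export
setClass("Fingerprint",
  representation(sampleId = "character", gelId = "character",
                 laneId = "character", bands = "data.frame",
                 standardsObserved = "data.frame",
                 amplificationFailed = "logical"),
  prototype(sampleId = NA_character_, gelId = NA_character_,
            laneId = NA_character_, bands = .emptyBands(),
            standardsObserved = .emptyStandards(),
            amplificationFailed = FALSE))

setValidity("Fingerprint", function(object) {
  msg <- character()
  b <- object@bands
  if (!all(.BAND_COLS %in% names(b)))
    msg <- c(msg, paste("bands must have columns:",
                        paste(.BAND_COLS, collapse = ", ")))
  else {
    if (nrow(b)) {
      if (any(is.na(b$distance_raw)) || any(b$distance_raw < 0))
        msg <- c(msg, "band distances must be non-negative")
      if (!all(b$intensity_class %in% 1:3))
        msg <- c(msg, "intensity_class must be in {1, 2, 3}")
      if (is.unsorted(b$distance_raw))
        msg <- c(msg, "bands must be sorted by increasing distance_raw")
      if (anyDuplicated(b$band_id))
        msg <- c(msg, "band_id values must be unique within a lane")
    }
    if (isTRUE(object@amplificationFailed) && nrow(b) > 0)
      msg <- c(msg, "a failed lane cannot carry bands")
  }
  s <- object@standardsObserved
  if (!all(.STD_COLS %in% names(s)))
    msg <- c(msg, paste("standardsObserved must have columns:",
                        paste(.STD_COLS, collapse = ", ")))
  else if (!isTRUE(object@amplificationFailed) && !nrow(s) %in% c(0L, 3L))
    msg <- c(msg, "a non-failed lane must record 0 or exactly 3 internal standards")
  if (length(msg)) msg else TRUE
})

#' Construct a Fingerprint
#'
#' Bands are re-sorted by migration distance; missing optional columns
#' (`is_faint_thin`, `sequence_ref`) are filled with defaults.
#'
#' @param sampleId,gelId,laneId identifiers (character scalars).
#' @param bands data.frame of bands; at minimum `band_id`, `distance_raw`
#'   and `intensity_class`.
#' @param standardsObserved data.frame with `standard_id` and
#'   `observed_distance` (0 or 3 rows).
#' @param amplificationFailed logical; failed lanes must be band-free.
#' @return A [Fingerprint-class] object.
#' @examples
#' fp <- fingerprint("S1", "G1", "L1",
#'   bands = data.frame(band_id = c("b2", "b1"),
#'                      distance_raw = c(40, 12), intensity_class = c(3, 1)))
#' bands(fp)$band_id  # sorted by distance: "b1", "b2"
#' @export
fingerprint <- function(sampleId, gelId = NA_character_, laneId = NA_character_,
                        bands = .emptyBands(),
                        standardsObserved = .emptyStandards(),
                        amplificationFailed = FALSE) {
  bands <- as.data.frame(bands, stringsAsFactors = FALSE)
  if (nrow(bands)) {
    if (is.null(bands$is_faint_thin)) bands$is_faint_thin <- FALSE
    if (is.null(bands$sequence_ref)) bands$sequence_ref <- NA_character_
    bands$intensity_class <- as.integer(bands$intensity_class)
    bands <- bands[order(bands$distance_raw), , drop = FALSE]
    rownames(bands) <- NULL
  } else {
    bands <- .emptyBands()
  }
  new("Fingerprint", sampleId = as.character(sampleId),
      gelId = as.character(gelId), laneId = as.character(laneId),
      bands = bands,
      standardsObserved = as.data.frame(standardsObserved,
                                        stringsAsFactors = FALSE),
      amplificationFailed = isTRUE(amplificationFailed))
}

#' DiversityLadder: reference migration distances of known SLOTUs
#'
#' The diversity ladder is the band-identification target: a set of reference
#' migration distances (standardized gel units) for species-level OTUs
#' obtained from pure strains. A standardized band co-migrating with a ladder
#' entry (within a matching tolerance) is affiliated to that SLOTU.
#'
#' @slot entries data.frame with columns `slotu_id`, `reference_distance`,
#'   sorted by increasing distance; ids unique, distances strictly positive.
#' @seealso [diversityLadder()], [readLadder()], [matchLadder()]
#' @export
setClass("DiversityLadder",
  representation(entries = "data.frame"),
  prototype(entries = data.frame(slotu_id = character(),
                                 reference_distance = numeric(),
                                 stringsAsFactors = FALSE)))

setValidity("DiversityLadder", function(object) {
  e <- object@entries
  msg <- character()
  if (!all(c("slotu_id", "reference_distance") %in% names(e)))
    return("entries must have columns slotu_id and reference_distance")
  if (nrow(e)) {
    if (any(e$reference_distance <= 0))
      msg <- c(msg, "reference distances must be strictly positive")
    if (is.unsorted(e$reference_distance))
      msg <- c(msg, "entries must be sorted by reference_distance")
    if (anyDuplicated(e$slotu_id))
      msg <- c(msg, "slotu_id values must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DiversityLadder
#'
#' @param slotu_id character vector of SLOTU identifiers (unique).
#' @param reference_distance numeric vector of standardized migration
#'   distances (> 0); entries are sorted by distance.
#' @return A [DiversityLadder-class].
#' @export
diversityLadder <- function(slotu_id = character(),
                            reference_distance = numeric()) {
  if (anyDuplicated(slotu_id))
    stop("duplicate slotu_id in ladder: ",
         paste(unique(slotu_id[duplicated(slotu_id)]), collapse = ", "))
  o <- order(reference_distance)
  new("DiversityLadder",
      entries = data.frame(slotu_id = as.character(slotu_id)[o],
                           reference_distance = as.numeric(reference_distance)[o],
                           stringsAsFactors = FALSE))
}

#' TaxonomyMap: SLOTU to GLOTU to PLOTU roll-up
#'
#' Maps species-level OTUs to genus/family-level groups (GLOTUs) and those to
#' phylum-level groups (PLOTUs; the phylum Firmicutes is split into its
#' classes). Lookup order for a SLOTU's GLOTU: explicit `overrides` first,
#' then the `slotuToGlotu` table, then derivation from the first token of the
#' SLOTU name when that token is itself a known GLOTU. Overrides cover cases
#' where the genus in the name is taxonomically misleading (e.g. *Clostridium
#' innocuum*, which belongs to *Erysipelotrichaceae*).
#'
#' @slot slotuToGlotu named character vector, SLOTU id -> GLOTU id.
#' @slot glotuToPlotu named character vector, GLOTU id -> PLOTU id.
#' @slot overrides named character vector of SLOTU -> GLOTU exceptions that
#'   take precedence over everything else.
#' @seealso [taxonomyMap()], [defaultTaxonomyMap()], [rollupGlotu()],
#'   [rollupPlotu()]
#' @export
setClass("TaxonomyMap",
  representation(slotuToGlotu = "character", glotuToPlotu = "character",
                 overrides = "character"),
  prototype(slotuToGlotu = structure(character(), names = character()),
            glotuToPlotu = structure(character(), names = character()),
            overrides = structure(character(), names = character())))

setValidity("TaxonomyMap", function(object) {
  msg <- character()
  if (length(object@slotuToGlotu) && is.null(names(object@slotuToGlotu)))
    msg <- c(msg, "slotuToGlotu must be named by SLOTU id")
  if (length(object@glotuToPlotu) && is.null(names(object@glotuToPlotu)))
    msg <- c(msg, "glotuToPlotu must be named by GLOTU id")
  known <- names(object@glotuToPlotu)
  dangling <- setdiff(unique(c(object@slotuToGlotu, object@overrides)), known)
  if (length(dangling))
    msg <- c(msg, paste("GLOTUs without a PLOTU:",
                        paste(dangling, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a TaxonomyMap
#'
#' @param slotuToGlotu named character vector (names = SLOTU ids).
#' @param glotuToPlotu named character vector (names = GLOTU ids); must cover
#'   every GLOTU referenced by `slotuToGlotu` or `overrides`.
#' @param overrides named character vector of explicit SLOTU -> GLOTU
#'   exceptions.
#' @return A [TaxonomyMap-class].
#' @export
taxonomyMap <- function(slotuToGlotu = character(),
                        glotuToPlotu = character(),
                        overrides = character()) {
  if (!length(overrides)) overrides <- structure(character(), names = character())
  new("TaxonomyMap", slotuToGlotu = slotuToGlotu,
      glotuToPlotu = glotuToPlotu, overrides = overrides)
}

#' WarpFunction: monotone piecewise-linear lane-to-reference map
#'
#' Fitted from the lane's observed internal-standard positions against their
#' shared reference positions; maps raw migration distances onto the
#' cross-gel standardized coordinate system. Linear between knots, linearly
#' extrapolated from the terminal segments, exact at the knots.
#'
#' @slot knots two-column numeric matrix (`observed`, `reference`), strictly
#'   increasing in both columns, at least two rows.
#' @seealso [fitWarp()], [applyWarp()]
#' @export
setClass("WarpFunction", representation(knots = "matrix"))

setValidity("WarpFunction", function(object) {
  k <- object@knots
  if (!is.numeric(k) || ncol(k) != 2 || nrow(k) < 2)
    return("knots must be a numeric matrix with 2 columns and >= 2 rows")
  if (any(diff(k[, 1]) <= 0) || any(diff(k[, 2]) <= 0))
    return("knots must be strictly increasing in both coordinates")
  TRUE
})

#' CohortTimeline: scored longitudinal colonization data
#'
#' The substrate for all dynamics statistics: one row per analyzable stool
#' sample in `samples` and one row per positive (sample, OTU) pair in
#' `scores`, each score the ordinal 0-3 semi-quantitative class derived from
#' band intensity (absence is implicit, score 0). Week indices use
#' `ceiling(day / 7)`, so days 1-7 are week 1 and day 56 is week 8.
#'
#' @slot samples data.frame: `infant_id`, `sample_id`, `day_of_life`, `week`,
#'   `analyzable` (FALSE for amplification failures, which are excluded from
#'   all denominators).
#' @slot scores data.frame: `infant_id`, `sample_id`, `day_of_life`, `week`,
#'   `slotu_id`, `glotu_id`, `plotu_id`, `score` (1-3).
#' @seealso [cohortTimeline()], [buildTimeline()], [weeklyGlotuScore()],
#'   [classifyColonization()]
#' @export
setClass("CohortTimeline",
  representation(samples = "data.frame", scores = "data.frame"))

setValidity("CohortTimeline", function(object) {
  msg <- character()
  needS <- c("infant_id", "sample_id", "day_of_life", "week", "analyzable")
  needX <- c("infant_id", "sample_id", "day_of_life", "week",
             "slotu_id", "glotu_id", "plotu_id", "score")
  if (!all(needS %in% names(object@samples)))
    msg <- c(msg, paste("samples must have columns:",
                        paste(needS, collapse = ", ")))
  if (!all(needX %in% names(object@scores)))
    msg <- c(msg, paste("scores must have columns:",
                        paste(needX, collapse = ", ")))
  if (!length(msg)) {
    if (nrow(object@samples) && any(object@samples$week < 1))
      msg <- c(msg, "week index must be >= 1")
    if (nrow(object@scores)) {
      if (!all(object@scores$score %in% 1:3))
        msg <- c(msg, "stored scores must be in {1, 2, 3} (0 is implicit absence)")
      key <- paste(object@scores$sample_id, object@scores$slotu_id)
      if (anyDuplicated(key))
        msg <- c(msg, "one score per (sample, SLOTU) pair")
      if (!all(object@scores$sample_id %in%
               object@samples$sample_id[object@samples$analyzable]))
        msg <- c(msg, "scores may only reference analyzable samples")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CohortTimeline
#'
#' @param samples data.frame with `infant_id`, `sample_id`, `day_of_life`
#'   and optionally `analyzable` (default TRUE); `week` is computed.
#' @param scores data.frame with `sample_id`, `slotu_id`, `score` plus
#'   optional taxonomy columns; infant/day/week are joined from `samples`,
#'   GLOTU/PLOTU filled from `taxmap` when given. Zero scores are dropped.
#' @param taxmap optional [TaxonomyMap-class] used to annotate scores with
#'   `glotu_id` and `plotu_id`.
#' @return A [CohortTimeline-class].
#' @export
cohortTimeline <- function(samples, scores = NULL, taxmap = NULL) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(samples$analyzable)) samples$analyzable <- TRUE
  samples$week <- weekOfLife(samples$day_of_life)
  samples <- samples[order(samples$infant_id, samples$day_of_life), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  if (is.null(scores) || !nrow(as.data.frame(scores))) {
    scores <- data.frame(infant_id = character(), sample_id = character(),
                         day_of_life = integer(), week = integer(),
                         slotu_id = character(), glotu_id = character(),
                         plotu_id = character(), score = integer(),
                         stringsAsFactors = FALSE)
  } else {
    scores <- as.data.frame(scores, stringsAsFactors = FALSE)
    scores <- scores[scores$score > 0, , drop = FALSE]
    idx <- match(scores$sample_id, samples$sample_id)
    if (anyNA(idx))
      stop("scores reference unknown sample_id: ",
           paste(unique(scores$sample_id[is.na(idx)]), collapse = ", "))
    scores$infant_id <- samples$infant_id[idx]
    scores$day_of_life <- samples$day_of_life[idx]
    scores$week <- samples$week[idx]
    if (!is.null(taxmap)) {
      scores$glotu_id <- rollupGlotu(scores$slotu_id, taxmap)
      scores$plotu_id <- rollupPlotu(scores$glotu_id, taxmap)
    } else {
      if (is.null(scores$glotu_id)) scores$glotu_id <- NA_character_
      if (is.null(scores$plotu_id)) scores$plotu_id <- NA_character_
    }
    scores$score <- as.integer(scores$score)
    scores <- scores[order(scores$infant_id, scores$day_of_life,
                           scores$slotu_id), , drop = FALSE]
    rownames(scores) <- NULL
  }
  new("CohortTimeline", samples = samples,
      scores = scores[, c("infant_id", "sample_id", "day_of_life", "week",
                          "slotu_id", "glotu_id", "plotu_id", "score")])
}
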