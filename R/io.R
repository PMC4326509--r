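#' Read a digitized TTGE band table
#'
#' Parses a tab-separated band table (one row per band) into one
#' [Fingerprint-class] per gel lane. Required columns: `gel_id`, `lane_id`,
#' `sample_id`, `distance`, `intensity`, `faint_thin`, `seq_ref`. Optional
#' columns: `failed` (a `TRUE` sidecar row with empty band fields marks a
#' lane whose PCR amplification failed) and `standard_id` (rows with a
#' non-empty `standard_id` are internal-standard observations, not bands;
#' their position is taken from `distance`).
#'
#' @param path path to the TSV file.
#' @return A list of [Fingerprint-class], one per (gel, lane), named by
#'   sample id.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("gel_id\tlane_id\tsample_id\tdistance\tintensity\tfaint_thin\tseq_ref",
#'              "G1\tL1\tS1\t30\t3\tFALSE\t",
#'              "G1\tL1\tS1\t12.5\t1\tTRUE\t"), tsv)
#' fps <- readBandTable(tsv)
#' bands(fps[[1]])
#' @seealso [writeBandTable()] for the inverse operation.
#' @export
readBandTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("gel_id", "lane_id", "sample_id", "distance", "intensity",
                "faint_thin", "seq_ref")
  missingCols <- setdiff(required, names(tab))
  if (length(missingCols))
    stop("band table is missing required column(s): ",
         paste(missingCols, collapse = ", "))
  if (is.null(tab$failed)) tab$failed <- "FALSE"
  if (is.null(tab$standard_id)) tab$standard_id <- ""
  tab$failed[is.na(tab$failed) | tab$failed == ""] <- "FALSE"
  tab$standard_id[is.na(tab$standard_id)] <- ""
  tab$.row <- seq_len(nrow(tab))

  key <- paste(tab$gel_id, tab$lane_id, sep = "\r")
  lapplyNamed <- function(groups, f) {
    out <- lapply(groups, f)
    names(out) <- vapply(out, sampleId, character(1))
    out
  }
  fps <- lapplyNamed(split(tab, factor(key, levels = unique(key))),
                     function(g) {
    failed <- any(toupper(g$failed) %in% c("TRUE", "T", "1"))
    isStd <- g$standard_id != ""
    isBand <- !isStd & !(toupper(g$failed) %in% c("TRUE", "T", "1") &
                         (is.na(g$distance) | g$distance == ""))
    bandRows <- g[isBand, , drop = FALSE]
    if (failed && nrow(bandRows))
      stop("lane ", g$lane_id[1], " on gel ", g$gel_id[1],
           " is marked failed but has band rows")
    std <- .emptyStandards()
    if (any(isStd))
      std <- data.frame(standard_id = g$standard_id[isStd],
                        observed_distance = as.numeric(g$distance[isStd]),
                        stringsAsFactors = FALSE)
    bandsDf <- .emptyBands()
    if (nrow(bandRows)) {
      dist <- suppressWarnings(as.numeric(bandRows$distance))
      if (anyNA(dist))
        stop("non-numeric distance at row ",
             bandRows$.row[which(is.na(dist))[1]])
      if (any(dist < 0))
        stop("negative distance at row ", bandRows$.row[which(dist < 0)[1]])
      intens <- suppressWarnings(as.integer(bandRows$intensity))
      bad <- is.na(intens) | !(intens %in% 1:3)
      if (any(bad))
        stop("intensity outside {1,2,3} at row ", bandRows$.row[which(bad)[1]])
      seqRef <- bandRows$seq_ref
      seqRef[is.na(seqRef) | seqRef == ""] <- NA_character_
      bandsDf <- data.frame(
        band_id = sprintf("%s:%s:b%02d", g$gel_id[1], g$lane_id[1],
                          seq_len(nrow(bandRows))),
        distance_raw = dist, intensity_class = intens,
        is_faint_thin = toupper(bandRows$faint_thin) %in% c("TRUE", "T", "1"),
        sequence_ref = seqRef, stringsAsFactors = FALSE)
    }
    fingerprint(sampleId = g$sample_id[1], gelId = g$gel_id[1],
                laneId = g$lane_id[1], bands = bandsDf,
                standardsObserved = std, amplificationFailed = failed)
  })
  unname(fps) -> fps2
  names(fps2) <- vapply(fps2, sampleId, character(1))
  fps2
}

#' Write fingerprints back to a band table
#'
#' Inverse of [readBandTable()]: the written file reads back into
#' content-identical fingerprints (band ids are positional and regenerated).
#'
#' @param fps list of [Fingerprint-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeBandTable <- function(fps, path) {
  rows <- lapply(fps, function(fp) {
    b <- bands(fp)
    s <- standardsObserved(fp)
    out <- list()
    if (amplificationFailed(fp))
      out$failedRow <- data.frame(gel_id = gelId(fp), lane_id = laneId(fp),
                                  sample_id = sampleId(fp), distance = "",
                                  intensity = "", faint_thin = "",
                                  seq_ref = "", failed = "TRUE",
                                  standard_id = "", stringsAsFactors = FALSE)
    if (nrow(b))
      out$bands <- data.frame(gel_id = gelId(fp), lane_id = laneId(fp),
                              sample_id = sampleId(fp),
                              distance = as.character(b$distance_raw),
                              intensity = as.character(b$intensity_class),
                              faint_thin = as.character(b$is_faint_thin),
                              seq_ref = ifelse(is.na(b$sequence_ref), "",
                                               b$sequence_ref),
                              failed = "FALSE", standard_id = "",
                              stringsAsFactors = FALSE)
    if (nrow(s))
      out$std <- data.frame(gel_id = gelId(fp), lane_id = laneId(fp),
                            sample_id = sampleId(fp),
                            distance = as.character(s$observed_distance),
                            intensity = "", faint_thin = "", seq_ref = "",
                            failed = if (amplificationFailed(fp)) "TRUE" else "FALSE",
                            standard_id = s$standard_id,
                            stringsAsFactors = FALSE)
    do.call(rbind, out)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a diversity ladder
#'
#' @param path TSV with columns `slotu_id` and `reference_distance`.
#' @return A [DiversityLadder-class], sorted by reference distance.
#'   Duplicate SLOTU ids are an error; an empty file yields an empty ladder
#'   (every band will be unmatched).
#' @export
readLadder <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("slotu_id", "reference_distance")
  missingCols <- setdiff(required, names(tab))
  if (length(missingCols))
    stop("ladder file is missing required column(s): ",
         paste(missingCols, collapse = ", "))
  diversityLadder(tab$slotu_id, tab$reference_distance)
}

#' Read excised-band sequences from FASTA
#'
#' Sequences are uppercased and restricted to the DNA alphabet ACGTN;
#' records are keyed by their FASTA header (the `sequence_ref` used in band
#' tables). Duplicate headers and non-DNA characters (e.g. RNA `U`) are
#' errors.
#'
#' @param path FASTA file.
#' @return A named character vector of uppercase DNA sequences.
#' @export
readSequences <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-DNA characters in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  names(seqs) <- ids
  seqs
}

#' Read a taxonomy map
#'
#' @param path TSV with columns `slotu_id`, `glotu_id`, `plotu_id`.
#' @return A [TaxonomyMap-class]. Rows whose GLOTU differs from the first
#'   token of the SLOTU name are additionally recorded as overrides.
#' @export
readTaxonomyMap <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("slotu_id", "glotu_id", "plotu_id")
  missingCols <- setdiff(required, names(tab))
  if (length(missingCols))
    stop("taxonomy map is missing required column(s): ",
         paste(missingCols, collapse = ", "))
  if (anyDuplicated(tab$slotu_id))
    stop("duplicate slotu_id in taxonomy map")
  s2g <- structure(tab$glotu_id, names = tab$slotu_id)
  g2p <- tab$plotu_id[!duplicated(tab$glotu_id)]
  names(g2p) <- tab$glotu_id[!duplicated(tab$glotu_id)]
  incons <- tapply(tab$plotu_id, tab$glotu_id,
                   function(x) length(unique(x)) > 1)
  if (any(incons))
    stop("GLOTU(s) mapped to multiple PLOTUs: ",
         paste(names(incons)[incons], collapse = ", "))
  firstTok <- sub("\\s.*$", "", tab$slotu_id)
  ov <- tab$glotu_id != firstTok
  overrides <- structure(tab$glotu_id[ov], names = tab$slotu_id[ov])
  taxonomyMap(s2g, g2p, overrides)
}

#' Read per-sample cohort metadata
#'
#' @param path TSV with columns `sample_id`, `infant_id`, `day_of_life`.
#' @return data.frame with those columns, `day_of_life` integer (>= 1).
#' @export
readCohortMetadata <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "infant_id", "day_of_life")
  missingCols <- setdiff(required, names(tab))
  if (length(missingCols))
    stop("metadata is missing required column(s): ",
         paste(missingCols, collapse = ", "))
  tab$day_of_life <- as.integer(tab$day_of_life)
  if (any(is.na(tab$day_of_life)) || any(tab$day_of_life < 1))
    stop("day_of_life must be an integer >= 1")
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in metadata")
  tab[, required]
}
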