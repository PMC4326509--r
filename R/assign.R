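#' Band-assignment parameters
#'
#' @param tolerance maximum |distance difference| (standardized units, i.e.
#'   percent of lane length) for a ladder match; default 0.5.
#' @param hdTopZone distance below which a faint/thin band is eligible for
#'   heteroduplex flagging (heteroduplexes melt early and sit at the top of
#'   the gel); default 5.
#' @param hdAdjacency maximum gap to a bright (class 3) band for flagging a
#'   faint/thin satellite band as a heteroduplex; default 1.
#' @return A named list of validated parameters.
#' @export
assignParams <- function(tolerance = 0.5, hdTopZone = 5, hdAdjacency = 1) {
  p <- list(tolerance = tolerance, hdTopZone = hdTopZone,
            hdAdjacency = hdAdjacency)
  if (any(vapply(p, function(x) !is.numeric(x) || length(x) != 1 || x <= 0,
                 logical(1))))
    stop("all assignment parameters must be strictly positive scalars")
  p
}

#' Flag heteroduplex artifact bands in a standardized lane
#'
#' Heteroduplexes are chimeric double-stranded PCR products whose strands
#' come from two different community members; they melt early and appear as
#' thin and/or faint bands at the top of the gel, or as faint satellites
#' immediately next to an intense band. A band is flagged iff it is
#' faint/thin and either lies above `hdTopZone` (distance < hdTopZone) or
#' has a class-3 band within `hdAdjacency` on either side. Flagged bands are
#' excluded from all downstream counting.
#'
#' @param fp a standardized [Fingerprint-class] (bands carry `distance_std`).
#' @param params see [assignParams()].
#' @return Character vector of flagged `band_id`s.
#' @export
flagHeteroduplex <- function(fp, params = assignParams()) {
  b <- bands(fp)
  if (!nrow(b)) return(character())
  if (is.null(b$distance_std))
    stop("fingerprint must be standardized before heteroduplex flagging")
  d <- b$distance_std
  bright <- d[b$intensity_class == 3]
  nearBright <- vapply(seq_len(nrow(b)), function(i) {
    others <- bright[!(b$intensity_class[i] == 3 & bright == d[i])]
    length(others) && any(abs(others - d[i]) <= params$hdAdjacency)
  }, logical(1))
  flagged <- b$is_faint_thin & (d < params$hdTopZone | nearBright)
  b$band_id[flagged]
}

#' Match a standardized distance against the diversity ladder
#'
#' Returns the SLOTU of the unique nearest ladder entry within `tolerance`.
#' If the two nearest in-tolerance entries are equidistant the match is
#' ambiguous and `NA` is returned. Deterministic and vectorized over
#' queries.
#'
#' @param distance_std numeric vector of standardized distances.
#' @param ladder a [DiversityLadder-class].
#' @param tolerance maximum |distance difference| for a match.
#' @return Character vector: matched `slotu_id` or `NA` (unmatched or tie).
#' @export
matchLadder <- function(distance_std, ladder, tolerance = 0.5) {
  e <- ladderEntries(ladder)
  if (!nrow(e)) return(rep(NA_character_, length(distance_std)))
  unname(vapply(distance_std, function(q) {
    delta <- abs(e$reference_distance - q)
    inTol <- which(delta <= tolerance)
    if (!length(inTol)) return(NA_character_)
    best <- inTol[delta[inTol] == min(delta[inTol])]
    if (length(best) > 1) return(NA_character_)  # symmetric tie: ambiguous
    e$slotu_id[best]
  }, character(1)))
}

#' Percent identity between two 16S amplicon sequences
#'
#' Global (Needleman-Wunsch) alignment maximizing the number of matched
#' bases, with gap columns counted in the alignment length (ties between
#' max-match alignments are resolved towards fewer gap columns). Identity is
#' `100 * matches / alignment_length`, symmetric in its arguments.
#'
#' @param seq_a,seq_b non-empty DNA strings (ACGTN).
#' @return Percent identity in [0, 100].
#' @examples
#' seqIdentity("ACGT", "ACGA")  # 75
#' @export
seqIdentity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("sequences must be non-empty")
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                  baseOnly = FALSE)
  # tiny gap cost: among equal-match alignments prefer fewer gap columns,
  # never at the price of a match (max total penalty << 1)
  aln <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "global",
                                       substitutionMatrix = sub,
                                       gapOpening = 0, gapExtension = 1e-6)
  # full alignment length including terminal gap columns
  alnLen <- Biostrings::width(Biostrings::alignedPattern(aln))
  100 * Biostrings::nmatch(aln) / alnLen
}

.hashSequence <- function(seq) {
  # deterministic 32-bit polynomial rolling hash, for reproducible novel ids
  h <- 0
  for (v in utf8ToInt(seq)) h <- (h * 131 + v) %% 2147483647
  sprintf("%08x", h)
}

#' Affiliate a sequenced band to a SLOTU by the 99% identity rule
#'
#' Two phylotypes belong to the same species-level OTU when their 16S
#' sequence identity exceeds 99%. The query is assigned to the reference of
#' maximal identity if that identity is > 99 (ties broken by first-listed
#' reference); otherwise a new SLOTU is minted with the query as its
#' representative, its id derived deterministically from the sequence.
#'
#' @param seq query DNA string.
#' @param references named character vector (names = SLOTU ids) of
#'   representative sequences; may be empty.
#' @param threshold identity percentage above which sequences share a SLOTU
#'   (strict inequality); default 99.
#' @return list with `slotu_id`, `identity` (NA when minted), and `novel`
#'   (logical).
#' @export
affiliateSequence <- function(seq, references = character(), threshold = 99) {
  if (length(references)) {
    ids <- vapply(references, function(r) seqIdentity(seq, r), numeric(1))
    best <- which.max(ids)  # first-listed wins ties
    if (ids[best] > threshold)
      return(list(slotu_id = names(references)[best],
                  identity = unname(ids[best]), novel = FALSE))
  }
  list(slotu_id = paste0("SLOTU_novel_", .hashSequence(seq)),
       identity = NA_real_, novel = TRUE)
}

#' Assign all bands of a standardized fingerprint
#'
#' Application order: heteroduplex flagging first; then ladder matching of
#' unflagged bands; then sequence affiliation for still-unmatched bands that
#' were excised and sequenced; anything left is `not_determined` (off-ladder
#' and too faint to sequence). Every input band appears exactly once.
#'
#' @param fp standardized [Fingerprint-class].
#' @param ladder [DiversityLadder-class].
#' @param sequences named character vector of excised-band sequences keyed
#'   by `sequence_ref` (may be empty).
#' @param params [assignParams()].
#' @param referenceSeqs named character vector of SLOTU representative
#'   sequences for the 99% rule (may be empty: every sequenced off-ladder
#'   band mints a novel SLOTU).
#' @return data.frame with one row per band: `band_id`, `sample_id`,
#'   `status` in {affiliated, artifact_heteroduplex, not_determined},
#'   `slotu_id` (NA unless affiliated), `method` (ladder/sequence/NA),
#'   `match_delta`, `intensity_class`, `distance_std`.
#' @export
assignFingerprint <- function(fp, ladder, sequences = character(),
                              params = assignParams(),
                              referenceSeqs = character()) {
  b <- bands(fp)
  out <- data.frame(band_id = character(), sample_id = character(),
                    status = character(), slotu_id = character(),
                    method = character(), match_delta = numeric(),
                    intensity_class = integer(), distance_std = numeric(),
                    stringsAsFactors = FALSE)
  if (!nrow(b)) return(out)
  if (is.null(b$distance_std))
    stop("fingerprint must be standardized before assignment")
  hd <- flagHeteroduplex(fp, params)
  status <- rep("not_determined", nrow(b))
  slotu <- rep(NA_character_, nrow(b))
  method <- rep(NA_character_, nrow(b))
  delta <- rep(NA_real_, nrow(b))
  isHd <- b$band_id %in% hd
  status[isHd] <- "artifact_heteroduplex"

  candidate <- which(!isHd)
  if (length(candidate)) {
    m <- matchLadder(b$distance_std[candidate], ladder, params$tolerance)
    hit <- !is.na(m)
    status[candidate[hit]] <- "affiliated"
    slotu[candidate[hit]] <- m[hit]
    method[candidate[hit]] <- "ladder"
    refD <- ladderEntries(ladder)$reference_distance[
      match(m[hit], ladderEntries(ladder)$slotu_id)]
    delta[candidate[hit]] <- abs(b$distance_std[candidate[hit]] - refD)
    # sequence affiliation for off-ladder bands that were sequenced
    for (i in candidate[!hit]) {
      ref <- b$sequence_ref[i]
      if (!is.na(ref) && ref %in% names(sequences)) {
        aff <- affiliateSequence(sequences[[ref]], referenceSeqs)
        status[i] <- "affiliated"
        slotu[i] <- aff$slotu_id
        method[i] <- "sequence"
      }
    }
  }
  data.frame(band_id = b$band_id, sample_id = sampleId(fp), status = status,
             slotu_id = slotu, method = method, match_delta = delta,
             intensity_class = b$intensity_class,
             distance_std = b$distance_std, stringsAsFactors = FALSE)
}
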