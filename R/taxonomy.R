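#' The packaged default taxonomy map
#'
#' Ships the 50 species-level OTUs of the study cohort with the roll-up the
#' current bacterial taxonomy implies, including the explicit exceptions:
#' the genera *Escherichia*, *Klebsiella* and *Enterobacter* merged into the
#' family *Enterobacteriaceae* (16S relatedness within the family),
#' *Clostridium innocuum* affiliated to *Erysipelotrichaceae* despite its
#' genus name, *Sarcina* kept as its own group within *Clostridiaceae*, and
#' an unidentified *Burkholderiales* group distinct from
#' *Aquabacterium/Burkholderiales*. At phylum level the Firmicutes are split
#' into their classes (Bacilli, Clostridia, Negativicutes);
#' *Erysipelotrichaceae* is tallied with the Clostridia, following how the
#' study groups its high-level taxa (taxonomically it forms its own class,
#' Erysipelotrichia).
#'
#' @return A [TaxonomyMap-class] covering 50 SLOTUs, 19 GLOTUs, 6 PLOTUs.
#' @export
defaultTaxonomyMap <- function() {
  readTaxonomyMap(system.file("extdata", "taxonomy_default.tsv",
                              package = "ttgedyn", mustWork = TRUE))
}

#' Roll a SLOTU up to its genus/family-level group (GLOTU)
#'
#' Lookup order: explicit overrides, then the map's SLOTU table, then
#' derivation from the first token of the SLOTU name when that token is a
#' known GLOTU. Vectorized.
#'
#' @param slotu_id character vector of SLOTU ids.
#' @param map a [TaxonomyMap-class].
#' @return Character vector of GLOTU ids.
#' @examples
#' tm <- defaultTaxonomyMap()
#' rollupGlotu("Escherichia coli", tm)      # "Enterobacteriaceae"
#' rollupGlotu("Clostridium innocuum", tm)  # "Erysipelotrichaceae"
#' @export
rollupGlotu <- function(slotu_id, map) {
  stopifnot(is(map, "TaxonomyMap"))
  out <- rep(NA_character_, length(slotu_id))
  ov <- match(slotu_id, names(map@overrides))
  out[!is.na(ov)] <- map@overrides[ov[!is.na(ov)]]
  need <- is.na(out)
  m <- match(slotu_id[need], names(map@slotuToGlotu))
  out[need][!is.na(m)] <- map@slotuToGlotu[m[!is.na(m)]]
  need <- is.na(out)
  if (any(need)) {
    tok <- sub("\\s.*$", "", slotu_id[need])
    known <- tok %in% names(map@glotuToPlotu)
    out[need][known] <- tok[known]
  }
  if (anyNA(out))
    stop("unmapped SLOTU(s): ",
         paste(unique(slotu_id[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Roll a GLOTU up to its phylum/class-level group (PLOTU)
#'
#' @param glotu_id character vector of GLOTU ids.
#' @param map a [TaxonomyMap-class].
#' @return Character vector of PLOTU ids (phylum, or class within the
#'   Firmicutes).
#' @examples
#' tm <- defaultTaxonomyMap()
#' rollupPlotu("Staphylococcus", tm)  # "Bacilli"
#' rollupPlotu("Veillonella", tm)     # "Negativicutes"
#' @export
rollupPlotu <- function(glotu_id, map) {
  stopifnot(is(map, "TaxonomyMap"))
  m <- match(glotu_id, names(map@glotuToPlotu))
  if (anyNA(m))
    stop("unmapped GLOTU(s): ",
         paste(unique(glotu_id[is.na(m)]), collapse = ", "))
  unname(map@glotuToPlotu[m])
}

#' Distinct taxonomic groups represented among affiliated bands
#'
#' @param assignments assignment data.frame (from [assignFingerprint()] or
#'   a row-bound cohort of them); only rows with status `affiliated` count.
#' @param map a [TaxonomyMap-class] (used for glotu/plotu levels).
#' @param level one of `"slotu"`, `"glotu"`, `"plotu"`.
#' @return data.frame (`group_id`, `n_bands`) for groups with >= 1
#'   affiliated band, sorted by decreasing band count.
#' @export
distinctGroups <- function(assignments, map, level = c("slotu", "glotu",
                                                       "plotu")) {
  level <- match.arg(level)
  aff <- assignments[assignments$status == "affiliated", , drop = FALSE]
  if (!nrow(aff))
    return(data.frame(group_id = character(), n_bands = integer(),
                      stringsAsFactors = FALSE))
  g <- aff$slotu_id
  if (level %in% c("glotu", "plotu")) g <- rollupGlotu(g, map)
  if (level == "plotu") g <- rollupPlotu(g, map)
  tab <- sort(table(g), decreasing = TRUE)
  data.frame(group_id = names(tab), n_bands = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}
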