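# Shared builders and independent oracles for the test suite.

# A minimal standardized lane: bands already carry distance_std so assign
# operations can be exercised without running the warp.
makeStdFingerprint <- function(dist, intensity, faint = rep(FALSE, length(dist)),
                               seqRef = rep(NA_character_, length(dist)),
                               sampleId = "S1") {
  fp <- fingerprint(sampleId, "G1", "L1",
                    bands = data.frame(
                      band_id = sprintf("b%02d", seq_along(dist)),
                      distance_raw = dist, intensity_class = intensity,
                      is_faint_thin = faint, sequence_ref = seqRef,
                      stringsAsFactors = FALSE))
  b <- bands(fp)
  b$distance_std <- b$distance_raw
  fp@bands <- b
  fp
}

# Identity-warp standards shared by lane and reference.
identityStandards <- c(S1 = 10, S2 = 50, S3 = 90)

makeLadder <- function(...) {
  entries <- c(...)
  if (is.null(entries)) return(diversityLadder())
  diversityLadder(names(entries), unname(entries))
}

writeTempTsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Brute-force global alignment oracle: enumerates every alignment of a and b
# recursively, maximizing matches then minimizing alignment length; returns
# 100 * matches / length. Only feasible for sequences of length <= 6.
bruteForceIdentity <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  best <- c(matches = -1, len = Inf)
  recurse <- function(i, j, matches, len) {
    if (i > length(a) && j > length(b)) {
      if (matches > best["matches"] ||
          (matches == best["matches"] && len < best["len"]))
        best <<- c(matches = matches, len = len)
      return(invisible())
    }
    if (i <= length(a) && j <= length(b))
      recurse(i + 1, j + 1, matches + (a[i] == b[j]), len + 1)
    if (i <= length(a)) recurse(i + 1, j, matches, len + 1)
    if (j <= length(b)) recurse(i, j + 1, matches, len + 1)
  }
  recurse(1, 1, 0, 0)
  100 * best[["matches"]] / best[["len"]]
}

# Exhaustive counting oracle for transient/persistent classification.
bruteForceStatus <- function(positive) {
  if (!any(positive)) return("not_colonized")
  first <- which(positive)[1]
  subsequent <- positive[-seq_len(first)]
  if (length(subsequent) > 0 && sum(subsequent) / length(subsequent) > 0.5)
    "persistent" else "transient"
}

# Metadata frame for a list of simulated/constructed fingerprints.
simMetadata <- function(cohort) {
  cohort$samples[, c("sample_id", "infant_id", "day_of_life")]
}
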