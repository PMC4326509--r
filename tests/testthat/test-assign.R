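test_that("heteroduplex flagging follows the top-zone and satellite rules", {
  params <- assignParams(tolerance = 0.5, hdTopZone = 5, hdAdjacency = 1)
  # single bright mid-gel band: nothing to flag
  expect_length(flagHeteroduplex(makeStdFingerprint(50, 3), params), 0)
  # faint thin band in the top zone
  fp <- makeStdFingerprint(c(2, 50), c(1, 3), faint = c(TRUE, FALSE))
  expect_equal(flagHeteroduplex(fp, params), "b01")
  # faint satellite next to a bright band, and the same band alone
  sat <- makeStdFingerprint(c(40, 40.5), c(3, 1), faint = c(FALSE, TRUE))
  expect_equal(flagHeteroduplex(sat, params), "b02")
  alone <- makeStdFingerprint(40.5, 1, faint = TRUE)
  expect_length(flagHeteroduplex(alone, params), 0)
  # faint band near a merely moderate band is not a satellite
  mod <- makeStdFingerprint(c(40, 40.5), c(2, 1), faint = c(FALSE, TRUE))
  expect_length(flagHeteroduplex(mod, params), 0)
})

test_that("ladder matching returns the unique nearest in-tolerance entry", {
  lad <- makeLadder(A = 10, B = 20)
  expect_equal(matchLadder(10, lad, 2), "A")      # exact
  expect_equal(matchLadder(11.5, lad, 2), "A")    # nearest within tolerance
  expect_true(is.na(matchLadder(15, lad, 2)))     # out of tolerance
  tie <- makeLadder(A = 10, B = 14)
  expect_true(is.na(matchLadder(12, tie, 3)))     # symmetric tie: ambiguous
  expect_true(is.na(matchLadder(12, makeLadder(), 3)))  # empty ladder
})

test_that("ladder matching agrees with a brute-force scan on random queries", {
  set.seed(7)
  entries <- sort(runif(20, 5, 95))
  names(entries) <- paste0("L", seq_along(entries))
  lad <- makeLadder(entries)
  tol <- 0.8
  brute <- function(q) {
    d <- abs(entries - q)
    ok <- d <= tol
    if (!any(ok)) return(NA_character_)
    best <- which(ok & d == min(d[ok]))
    if (length(best) > 1) NA_character_ else names(entries)[best]
  }
  queries <- c(runif(200, 0, 100), entries, entries + tol, entries - tol)
  expect_equal(matchLadder(queries, lad, tol),
               unname(vapply(queries, brute, character(1))))
})

test_that("sequence identity matches exhaustive alignment for short strings", {
  set.seed(11)
  for (rep in 1:30) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(1:6, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(1:6, 1), TRUE),
               collapse = "")
    expect_equal(seqIdentity(a, b), bruteForceIdentity(a, b),
                 tolerance = 1e-9, info = paste(a, b))
  }
})

test_that("sequence identity handles the amplicon-scale worked examples", {
  base <- paste(rep(c("A", "C", "G", "T"), length.out = 233), collapse = "")
  expect_equal(seqIdentity(base, base), 100)
  mut1 <- base
  substr(mut1, 117, 117) <- ifelse(substr(base, 117, 117) == "A", "C", "A")
  expect_equal(seqIdentity(base, mut1), 100 * 232 / 233, tolerance = 1e-9)
  expect_equal(seqIdentity(base, mut1), seqIdentity(mut1, base))
  expect_equal(seqIdentity("ACGT", "ACGA"), 75)
  expect_error(seqIdentity("", "ACGT"), "non-empty")
})

test_that("sequence affiliation applies the strict 99% rule", {
  base <- paste(rep(c("A", "C", "G", "T"), length.out = 233), collapse = "")
  mut <- function(n) {
    s <- base
    for (i in seq_len(n)) substr(s, i * 7, i * 7) <-
        ifelse(substr(base, i * 7, i * 7) == "A", "C", "A")
    s
  }
  refs <- c(R1 = base, R2 = mut(6))
  expect_equal(affiliateSequence(base, refs)$slotu_id, "R1")
  # 1 mismatch in 233 = 99.57 > 99: same SLOTU
  expect_equal(affiliateSequence(mut(1), refs)$slotu_id, "R1")
  # 3 mismatches = 98.71 < 99: novel SLOTU
  novel <- affiliateSequence(mut(3), refs["R1"])
  expect_true(novel$novel)
  expect_match(novel$slotu_id, "^SLOTU_novel_")
  # idempotence: re-affiliating a minted representative returns its own id
  refs2 <- c(refs, structure(mut(3), names = novel$slotu_id))
  again <- affiliateSequence(mut(3), refs2)
  expect_equal(again$slotu_id, novel$slotu_id)
  expect_false(again$novel)
  # empty reference set always mints, deterministically
  expect_equal(affiliateSequence(base)$slotu_id,
               affiliateSequence(base)$slotu_id)
})

test_that("assignment partitions every band exactly once", {
  lad <- makeLadder(A = 20, B = 30)
  params <- assignParams()
  # artifact + ladder hit + off-ladder faint
  fp <- makeStdFingerprint(c(2, 20.2, 25), c(1, 3, 1),
                           faint = c(TRUE, FALSE, FALSE))
  a <- assignFingerprint(fp, lad, params = params)
  expect_equal(nrow(a), 3)
  expect_setequal(a$status,
                  c("artifact_heteroduplex", "affiliated", "not_determined"))
  expect_equal(a$slotu_id[a$status == "affiliated"], "A")
  expect_equal(a$method[a$status == "affiliated"], "ladder")
  expect_lte(a$match_delta[a$status == "affiliated"], params$tolerance)
  # all on ladder
  all3 <- assignFingerprint(makeStdFingerprint(c(20, 29.9), c(2, 3)), lad,
                            params = params)
  expect_true(all(all3$status == "affiliated"))
  # empty lane
  expect_equal(nrow(assignFingerprint(fingerprint("S0"), lad,
                                      params = params)), 0)
})

test_that("off-ladder sequenced bands are affiliated by sequence, never overriding a ladder match", {
  base <- paste(rep(c("A", "C", "G", "T"), length.out = 233), collapse = "")
  lad <- makeLadder(A = 20)
  fp <- makeStdFingerprint(c(20.1, 40), c(2, 3),
                           seqRef = c("onLadder", "offLadder"))
  seqs <- c(onLadder = "GGGGGGGG", offLadder = base)
  a <- assignFingerprint(fp, lad, sequences = seqs,
                         referenceSeqs = c(REF = base))
  expect_equal(a$method, c("ladder", "sequence"))
  expect_equal(a$slotu_id, c("A", "REF"))
})
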