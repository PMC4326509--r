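---
title: "From gel bands to colonization dynamics: the ttgedyn methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From gel bands to colonization dynamics: the ttgedyn methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttgedyn)
```

PCR-TTGE separates same-length 16S rDNA amplicons (here the ~233 bp V2–V3
region) by their melting behaviour along a temporal temperature gradient, so
that a band's migration distance fingerprints the underlying sequence. For a
longitudinal cohort — very preterm infants sampled once to twice a week over
their first eight weeks of life — the analytical problem is to turn hundreds
of gel lanes into per-infant, per-taxon colonization trajectories. This
vignette explains each model and procedure in the package, the parameters
that matter, and the choices made where the design was genuinely open.

## Lane standardization

Gels and lanes migrate slightly differently, so raw distances are not
comparable across lanes. Each lane carries three internal migration
standards of known identity. `fitWarp()` builds a monotone piecewise-linear
map through the (observed, reference) standard positions and `applyWarp()`
applies it to every band. Between knots the map interpolates linearly; past
the terminal knots it extrapolates linearly along the terminal segments; at
the knots it is exact by construction.

Linear-in-segments is the minimal monotone interpolant available from three
calibration points; with no information about the distortion between
standards, any richer model would be unidentifiable. Degenerate inputs are
refused rather than repaired: fewer than two shared standards, two standards
observed at the same distance (co-migration, indicating a failed gel), or an
observed order contradicting the reference order (a physically inverted
lane) all raise errors. Distances are dimensionless gel units normalized to
a nominal 0–100 lane; the digitization convention, not a physical unit.

## Heteroduplex flagging

Heteroduplexes are chimeric double-stranded PCR products whose two strands
come from different templates in the community. Their imperfect duplex melts
early, so they run as thin and/or faint bands near the top of the gel, or as
faint satellites immediately adjacent to an intense parent band. The flagging
rule mirrors that morphology-plus-position description: a band is flagged iff
it is faint/thin **and** (its standardized distance is below `hdTopZone`,
default 5 units, **or** a bright class-3 band lies within `hdAdjacency`,
default 1 unit, on either side). Flagged bands are excluded from every
downstream count. Both zone parameters are conventions chosen at the scale of
the standardized coordinate system — the top twentieth of the lane, and a
satellite window narrower than the closest spacing of distinct taxa — since
the phenomenon is only ever described qualitatively.

## Band affiliation

Unflagged bands are matched against the diversity ladder — reference
positions of species-level OTUs (SLOTUs) obtained from pure strains — by
`matchLadder()`: the unique nearest entry within `tolerance` (default 0.5
units) wins; if two in-tolerance entries are exactly equidistant the match
is ambiguous and the band stays unmatched rather than being assigned by an
arbitrary tie-break. The 0.5-unit default is half the minimum spacing of the
packaged ladder, so no query can ever fall inside two windows at once.

Off-ladder bands that were excised and sequenced go through
`affiliateSequence()`: a global (Needleman–Wunsch) alignment maximizing
matched bases, with gap columns counted in the alignment length. Identity is
`100 · matches / alignment_length`, and two phylotypes share a SLOTU when
identity exceeds 99% (strict). Ties among references go to the first listed;
below threshold, a new SLOTU is minted with an id derived deterministically
from the sequence, so re-runs and re-affiliations are reproducible and
idempotent. Counting gaps in the denominator is the conservative choice;
near-identical V2–V3 amplicons rarely gap, so the distinction is minor in
practice. Sequence affiliation never overrides a ladder match: in the
original protocol only bands absent from the ladder were sequenced.

Everything still unmatched is `not_determined` — off-ladder and too faint to
excise. The three outcomes partition the bands, so cohort-wide
`n_detected = n_artifact + n_unassigned + n_affiliated` always holds
(`bandAccounting()` enforces it).

## Taxonomic roll-up

SLOTUs roll up to genus/family-level groups (GLOTUs) and those to
phylum-level groups (PLOTUs), with the phylum Firmicutes split into its
classes (Bacilli, Clostridia, Negativicutes). The packaged default map
covers the cohort's 50 SLOTUs and reproduces the published grouping exactly,
including its overrides: *Escherichia*, *Klebsiella* and *Enterobacter*
merged into *Enterobacteriaceae* (16S gene relatedness blurs the genera);
*Clostridium innocuum* affiliated to *Erysipelotrichaceae* despite its genus
name; *Sarcina* kept as its own Clostridiaceae group; an unidentified
*Burkholderiales* distinct from *Aquabacterium/Burkholderiales*. Lookup
order is overrides → explicit table → first-token genus derivation, so a
user-supplied map can stay sparse.

One genuinely open point: *Erysipelotrichaceae* taxonomically forms its own
Firmicutes class (Erysipelotrichia), which would make a seventh PLOTU. The
study tallies its six high-level taxa with *C. innocuum* among the
Clostridia, and the default map follows that tally (Erysipelotrichaceae →
Clostridia) so the six-PLOTU grouping is reproduced literally; users who
prefer the strict classification can supply their own map.

## Scoring and dynamics

Band intensity is pre-classified at digitization into an ordinal scale
(+/++/+++ = 1/2/3); the pipeline does no densitometry. A sample's score for
an OTU is the intensity class of its band — the brightest, if one SLOTU
produced several bands (e.g. taxa with intragenomic 16S variability) — and
0, implicitly, when absent.

Weeks are binned as `ceil(day/7)`: the first samples (day 3) fall in week 1
and day 56 ends week 8, matching the eight-week study framing. Within-week
replicates are averaged, not maximized, for the weekly GLOTU score; the
within-week maximum feeds a separate mean-maximal-score statistic. The
weekly GLOTU score for an infant averages over that week's samples and over
the GLOTU's *detected* member OTUs: an OTU never seen in that infant
contributes nothing, while a detected-then-absent OTU contributes zeros — so
the score reflects the trajectory of the taxa the infant actually carries.
Samples with failed amplification are excluded from every denominator rather
than counted as all-zero. Cohort-level weekly summaries report two colonized
fractions, over infants sampled that week and over the whole cohort, because
discharge and death truncate sampling and the choice of denominator is a
genuine ambiguity.

Colonization by an OTU is **persistent** when strictly more than half of the
samples after the first positive one are positive, **transient** otherwise.
When the first positive sample is the last sample the subsequent set is
empty; the ratio rule is silent there, and the package classifies it as
transient (no evidence of persistence). The classifier is verified against
an exhaustive enumeration of all positive/negative series up to length 8.

## The synthetic cohort generator

No raw data accompany the study, so the generator is the package's
first-class substrate for end-to-end testing. It emulates the study design:
30 infants, samples on days 3–56 with one or two per week
(`pTwoPerWeek = 0.5`, giving ~12 samples per infant, the reported mean being
11.8), and a small per-week dropout (0.02) standing in for discharge or
death. Colonization is modeled per (infant, GLOTU): an onset week is drawn
from a categorical distribution over weeks 1–8 (remaining mass = never
colonized); the first sample at or after onset is positive — which makes the
onset week identifiable from the output — and each later sample is positive
with a persistence probability. One SLOTU is drawn per episode (multi-OTU
carriage within a genus exists in the real data but is off by default to
keep ground truth unambiguous). Scores start from a per-GLOTU initial
distribution and evolve by a lazy random walk on {1,2,3} (move probability
0.2), since no quantitative intensity dynamics are reported.

The default onset/persistence parameters encode the reported qualitative
dynamics — staphylococci nearly universal from week 1 (onset mass 0.8 in
week 1, persistence 0.9), enterococci accruing steadily to ~77%, clostridia
from week 2 to ~70%, enterobacteria delayed to weeks 5–8 (total mass 0.33),
*Veillonella* in about a quarter of infants.

Gel rendering draws one affine distortion per 16-lane gel (slope 0.9–1.1,
intercept ±2 units) and adds per-band Gaussian jitter (sd 0.15 units, well
inside the 0.5 matching tolerance). Standards render through the same
distortion exactly, so standardization must (and does) undo the affine part
exactly at the knots. Heteroduplex bands are generated only for lanes with
at least two co-amplified taxa — per pair with probability 0.55 — and placed
faint/thin in the top zone or adjacent to a bright parent; spurious faint
bands (Poisson mean 0.12 per lane) sit at off-ladder midpoints. The two
artifact rates are calibrated so the rendered band-category proportions
match the published band accounting (about a quarter artifact bands and a
few percent unassignable); the realism check accepts artifact fractions in
0.15–0.35. Amplification failures occur per sample with probability 0.04
(≈14/354). The ladder positions themselves are synthetic — the real ladder
is not published — spaced 1.6 units apart.

What the generator does *not* emulate: nonlinear (non-affine) gel warps,
detection-limit bias of TTGE against minority populations, sequence-level
chimera content, intragenomic multi-band profiles, and morphology noise in
the faint/thin flag (the simulated flag is perfectly informative). Passing
recovery tests therefore demonstrate that the pipeline's logic is correct
under the stated noise model, not that TTGE itself resolves everything; with
real gels the faint/thin call and manual distance measurement add error
modes the simulation leaves out.

## Numerical choices and degenerate inputs

* Warp fitting requires ≥ 2 shared standards and strict monotonicity;
  evaluation is total on non-negative reals.
* Ladder ties (exact equidistance) yield unmatched, never an arbitrary
  choice; determinism everywhere else is by construction.
* Alignment scoring uses match +1, mismatch 0 and an infinitesimal gap cost
  (10⁻⁶ per gap column): among alignments with maximal matches the one with
  fewest gap columns is selected, which is exactly the maximum of
  `matches / alignment_length`. The implementation is verified against a
  brute-force enumeration of all alignments for short sequences.
* Novel-SLOTU ids hash the representative sequence (32-bit polynomial
  rolling hash), so minting is reproducible across sessions.
* An empty ladder, an empty lane, an infant with no detections, and an
  empty cohort all produce empty-but-valid results rather than errors.
* All simulation randomness derives from one mandatory seed; rendering uses
  a stream derived from the same seed so cohort and gels are independently
  reproducible.

## Problem sizes

The test suite runs the full pipeline on default 30-infant cohorts
(~350 lanes, ~900 bands) and the parameter-recovery property on a
100-infant cohort; the exhaustive colonization oracle enumerates all 2⁸
series. The complete suite takes on the order of ten seconds on a single
CPU, and the acceptance script runs in under a second.

## Known limitations

TTGE resolution limits the method: distinct species can co-migrate (the
ladder match then reports the ladder's label), single taxa can produce
several bands, and the 0–3 score is ordinal, not a quantitative abundance.
The package reports what the fingerprints support — dominant-taxon
presence, ordinal load, and week-scale dynamics — and deliberately stops
short of inferential statistics on the trajectories, which the underlying
design (visual scoring, uneven sampling) does not support.
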