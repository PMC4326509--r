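# ttgedyn

Longitudinal analysis of gut-microbiota fingerprints from 16S rDNA
PCR-TTGE (temporal temperature gradient gel electrophoresis), built for the
follow-up of the *dominant* microbiota in very preterm infants, where serial
stool sampling over the first weeks of life produces hundreds of gel lanes
that must be turned into per-infant colonization trajectories.

In TTGE, same-length V2–V3 16S amplicons separate by melting behaviour, so a
band's migration distance is a sequence fingerprint. The pipeline implements
the full chain from digitized band tables to cohort statistics:

1. **Gel standardization.** Each lane carries three internal migration
   standards. A monotone piecewise-linear warp is fitted through the
   observed-vs-reference standard positions (linear terminal extrapolation,
   exactness at the knots) and applied to every band, putting all lanes on
   one coordinate system.
2. **Artifact exclusion.** Heteroduplexes — chimeric double strands with
   each strand from a different community member — appear as thin/faint
   bands at the top of the gel or as faint satellites next to an intense
   band. Bands matching that morphology-plus-position rule are flagged and
   excluded from all counts.
3. **Band affiliation.** Remaining bands are matched to a *diversity
   ladder* of reference positions for known species-level OTUs (unique
   nearest entry within a tolerance; symmetric ties are left unmatched).
   Off-ladder bands that were excised and sequenced are affiliated by
   global alignment: two phylotypes share a SLOTU when identity
   `100 · matches / alignment_length > 99%`; otherwise a new SLOTU is
   minted. Everything else is "not determined".
4. **Taxonomic roll-up.** SLOTU → GLOTU (genus/family) → PLOTU
   (phylum, with Firmicutes split into its classes), including the
   published override cases (*Escherichia*/*Klebsiella*/*Enterobacter*
   merged into *Enterobacteriaceae*; *Clostridium innocuum* to
   *Erysipelotrichaceae*).
5. **Dynamics.** Band intensity gives an ordinal 0–3 semi-quantitative
   score per (sample, OTU). Scores are binned by week of life
   (`week = ceil(day/7)`), averaged per GLOTU within and across infants,
   and each (infant, OTU) series is classified **transient** vs
   **persistent**: persistent iff more than 50% of the samples *after* the
   first positive one are positive.
6. **Simulation.** A synthetic cohort/gel generator reproduces the study
   design (30 infants, days 3–56, 1–2 samples/week, early staphylococcal
   and delayed enterococcal/clostridial/enterobacterial colonization,
   ~25% heteroduplex bands, occasional amplification failures) with full
   ground truth, enabling end-to-end recovery testing.

Data containers are S4 classes with validity checks: `Fingerprint` (one
lane), `DiversityLadder`, `TaxonomyMap`, `WarpFunction`, `CohortTimeline`.

## Worked example

Simulate a cohort under the default (study-like) conditions, render its
gels, run the pipeline, and look at staphylococcal dynamics:

```r
library(ttgedyn)

cfg    <- simConfig(seed = 20)
cohort <- simulateCohort(cfg)
gels   <- renderGels(cohort)
res    <- analyzeCohort(gels$fingerprints,
                        cohort$samples[, c("sample_id", "infant_id", "day_of_life")])

str(res$accounting)
#> List of 4
#>  $ n_detected  : int 897
#>  $ n_artifact  : int 237
#>  $ n_unassigned: int 33
#>  $ n_affiliated: int 627
```

Of 897 detected bands, 237 (26%) were flagged as heteroduplex artifacts and
33 could not be matched to the ladder — proportions comparable to a real
TTGE campaign — leaving 627 bands affiliated to species-level OTUs.

```r
head(cohortWeeklyDynamics(res$timeline, "Staphylococcus"), 3)
#>   week n_sampled n_colonized fraction_colonized fraction_cohort mean_score_colonized mean_max_score_colonized
#> 1    1        28          18               0.64            0.60                 2.50                     2.56
#> 2    2        27          23               0.85            0.77                 2.50                     2.57
#> 3    3        29          28               0.97            0.93                 2.30                     2.39
```

Staphylococci colonize most infants from the first week at high scores,
as in the real cohort. Because the simulator keeps ground truth, recovery
can be quantified:

```r
unlist(evaluateRecovery(res, cohort, gels))
#> affiliationPrecision    affiliationRecall  artifactSensitivity  artifactSpecificity
#>                1.000                1.000                1.000                1.000
#>               ndRate       scoreAgreement      statusAgreement
#>                0.037                1.000                1.000
```

The published per-OTU summary table ships as a machine-readable fixture
(`loadPaperTable1()`), and `defaultTaxonomyMap()` reproduces its roll-up:
50 SLOTUs → 19 GLOTUs → 6 PLOTUs.

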