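---
title: "Screening gluten peptides for immunogenic epitopes: methods and design"
author: "glutenscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening gluten peptides for immunogenic epitopes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glutenscreen)
options(glutenscreen.verbose = FALSE)
```

## The problem

Prolamins — the alcohol-soluble storage proteins of wheat (gliadins,
glutenins), barley (hordeins) and rye (secalins), collectively called
gluten — trigger coeliac disease through short, proline/glutamine-rich
epitopes. Regulatory gluten assays rely on the R5 monoclonal antibody,
which recognises five-residue motifs (QQPFP and variants); clinical
relevance rests on nine-residue HLA-DQ2.5/DQ8 core epitopes and longer
T-cell epitope regions with confirmed positive assays. In hydrolysed
matrices such as beer, proteins are reduced to peptides: an antibody may
lose its binding sites, and a peptide may or may not retain an immunogenic
core. This package implements the full screening chain — in silico
digestion, motif census at protein and peptide level, targeted-MS
(multiple reaction monitoring, MRM) abundance aggregation, and
antibody-versus-MS concordance — with a seeded synthetic-data layer so
that every stage can be tested against exact ground truth.

## Digestion model

Cleavage is modelled as a site set: trypsin cleaves C-terminal to K or R,
chymotrypsin (broad specificity) C-terminal to F, W, Y, L or M. With the
proline rule active (the default), a candidate site immediately followed
by P is removed from the site set entirely — it is neither cleaved nor
counted as a missed cleavage. Peptides are all maximal-boundary fragments
spanning at most `maxMissedCleavages` internal sites, with coordinates in
the parent; the ambiguous residue X never acts as a cleavage residue.

The proline rule is not optional in spirit: hordein/glutenin repeat
regions are full of KP/RP, and the behaviour of real monitored peptides
(an internal RP surviving in DVSPGCRPITVSPGTR, an internal K retained as a
genuine missed cleavage in other markers) is only reproduced with the rule
on. Chymotrypsin specificity is the broad F/W/Y/L/M set but the residue
set is a constructor argument, because narrow-specificity searches are
common and the correct set for a given experiment is an acquisition
choice, not a property of the enzyme alone. Defaults of
`maxMissedCleavages = 2` and `minLength = 5` are the community defaults
for targeted work and admit the marker peptides used throughout the
documentation. The protein N-terminal Met is never stripped: silent
sequence edits would desynchronise coordinates from the source FASTA.
Semi-specific digestion is out of scope; where a detected peptide has a
non-enzymatic terminus the package still accepts it as input (peptide
lists are taken as given), it simply will not be generated in silico.

## Epitope matching

Motifs carry a class and an intact-core threshold `min_core_match`:

* **R5** motifs (5-mers) require the full motif — a partial antibody
  motif is meaningless.
* **DQ_core** motifs are exactly 9 residues and require all 9.
* **immunogenic_Tcell** motifs may be longer (epitope regions) and
  require 9 contiguous residues.

At **protein level**, `scanSequence()` reports *every* occurrence at
*every* start position, overlapping occurrences included. Prolamin repeat
regions overlap heavily; deduplicating overlaps would undercount
instances, and the instance/carrier distinction (total occurrences versus
distinct carrying sequences) would become ambiguous. Matching is exact
residue identity: X matches nothing, and deamidation variants (Q→E) are
*not* matched — scanning is against unmodified database sequences, and
tissue-transglutaminase deamidation is biology downstream of the
analytical question. A user who wants Q/E-tolerant matching can supply an
expanded motif list.

At **peptide level**, `intactCoreHits()` implements the intact-core
criterion: for each motif it finds the longest contiguous substring of the
motif present in the peptide (ties broken deterministically: leftmost
motif substring, first position in the peptide) and emits a hit when that
length reaches `min_core_match`. This operationalises "retains at least
nine residues of the epitope region" for peptides whose termini were cut
inside an epitope. The search enumerates motif substrings from longest to
shortest, which is exact (not heuristic) and cheap at epitope scale
(motifs ≤ ~20 residues).

Censuses count instances and carriers per class. Carrier counting
optionally collapses accessions through a user-supplied protein → group
map, because bottom-up proteomics cannot distinguish homologous prolamins
sharing peptides; the package deliberately does not re-implement any
search engine's grouping algorithm, and defaults to one group per
accession so that grouping is never silently in effect. The carrier
overlap is reported both as the full subset lattice over
{R5, DQ_core, immunogenic_Tcell} and as the pooled R5-versus-(DQ or
T-cell) partition, so either pooling convention is recoverable.

The shipped motif list is a curated starter: the four R5 motifs, native
(non-deamidated) Q-form DQ2.5/DQ8 9-mer cores following the Sollid
nomenclature, and confirmed T-cell epitope regions including the
C-hordein repeat PQQPFPQPQQPFP (IEDB 226653). Published epitope
inventories are deamidation-aware and evolving; no static list can claim
completeness, which is why the list is a plain CSV loaded through
`readMotifList()` and every census records the motif list it used.

## MRM aggregation model

A transition is one precursor/fragment pair; three transitions are
monitored per peptide and their peak areas summed within each technical
replicate. Where a peptide contains Met, both the reduced and the
oxidised (+16 Da) precursor are targeted and their areas are *always*
merged — they are two measurement channels of one analyte, and reporting
them separately would double-count. The peptide abundance is the mean of
the replicate-level sums (n = 4 replicates in the emulated design) and
variability is the coefficient of variation with the n−1 sample SD.

Missing data are handled at two granularities. A missing *transition*
row contributes zero to its replicate sum (the instrument scheduled it
and saw nothing). A peptide absent from an *entire replicate* that exists
for the sample is zero-filled too, but flagged
(`n_missing_replicates > 0`) and logged, because silent zero-filling of
whole replicates deflates means invisibly. Blank or `#N/A` areas in the
input are treated as missing, never as zero. Detection is
`summed_area > detection_threshold` with threshold 0 by default: the
undetected state exists to draw grey cells in heatmaps and to drive
presence/absence panels, and any nonzero default would be an uncalibrated
claim about instrument noise.

Class summaries give mean, SD and net (summed) area per protein class and
sample; the net hordein total sums the B-, C-, D- and gamma-hordein
classes only. Avenin-like proteins (ALPs) are prolamin-family proteins
but not hordeins, so they are summarised as their own class and excluded
from the net total. Net areas sum peptide-level means over replicates;
summing per-replicate sums first and averaging after is equivalent in
expectation, and the mean-first form keeps the class table derivable from
the peptide table alone.

The concordance report rounds group means to 1 decimal (mg/kg) and
percentages to the nearest integer — the precision at which such surveys
are reported — while keeping unrounded values alongside. Rank mismatch
uses average ranks (rank 1 = highest gluten under each measure) and a
default margin of 3 ranks on 14 samples; the margin is configurable
because it is a reporting sensitivity, not a statistical threshold.

## What the simulators emulate — and what they do not

`simulateProteins()` emulates the *sequence statistics* that make epitope
counting hard: Q/P-rich composition, short repeat units, and epitope
occurrences at known multiplicity. Repetitive text spells epitopes
spontaneously, so the generator verifies itself with an independent naive
scanner (deliberately not the production scanner): accidental occurrences
of planted motifs in the background are scrubbed by single-residue
mutation, each insertion point is redrawn until it creates no boundary
artefacts, and the final count of every planted motif must equal the
planted number plus nested occurrences inside other planted motifs (each
planted PQQPFPQPQQPFP contains QQPFP twice, and the truth table accounts
for it). Repeat units that contain a planted motif are dropped from the
background pool, since exact planted counts would otherwise be
unreachable. The generator does *not* emulate real hordein gene families,
signal peptides, cysteine skeletons or length distributions of actual
isoforms — a census passing on synthetic proteins validates the counting
machinery, not any claim about a real proteome.

`simulateTransitions()` emulates the *measurement structure*: per-sample
scale factors, three transitions with fixed fractional responses, a
reduced/oxidised split for Met peptides, four replicates, multiplicative
lognormal noise (the standard model for MS intensities; no noise model is
claimed beyond that), and optional row dropout. It does not simulate
chromatography, interference, saturation or retention-time scheduling,
so recovery tests validate the aggregation arithmetic, not instrument
realism. With three transitions of fractions (0.5, 0.3, 0.2), the CV of
a replicate sum is about `sqrt(0.5² + 0.3² + 0.2²) ≈ 0.62` times the
per-transition sigma — at sigma 0.1 the observed replicate CVs
concentrate around 0.05–0.07, within the 0.02–0.25 band asserted in the
tests.

`simulateStudy()` wires both into a 5-control / 9-low-gluten survey
design with ELISA values generated as a *linear (hence monotone) function
of true net hordein content*, optionally multiplied by per-sample
suppression factors. This is deliberately not a mechanistic antibody
model: the only phenomenon the pipeline needs to exercise is a sample
whose MS rank is high while its ELISA rank collapses, and a monotone
transform plus suppression produces exactly that with known ground truth.

## Numerical and testing choices

All scanning, digestion and aggregation is deterministic; every
stochastic step takes an explicit seed, and reports are byte-identical
across reruns (manifests differ only in their timestamp, which the
determinism test excludes). Test oracles are independent
implementations: an all-start-positions substring scanner, a brute-force
digestion that enumerates every substring and filters by boundary
conditions, and an exhaustive longest-common-substring search. Problem
sizes in the default test run — 1,000 random Q/P-rich strings for the
scanner/oracle equivalence, 100 proteins × 5 motifs for planted census
recovery, 20 peptides across two orders of magnitude for abundance
recovery — were chosen as the smallest sizes at which the properties are
meaningfully exercised while keeping the suite fast to run routinely.

The shipped ELISA survey table gives a low-gluten group mean of
53.9/9 = 5.9889 mg/kg; note that at one decimal this rounds to 6.0,
while such values are conventionally quoted as 5.9 (truncation). The
concordance report stores both the raw and the rounded value so no
precision is lost.

## Known limitations

* The epitope starter list is curated, not exhaustive, and matches native
  (non-deamidated) sequences only; census results on real data are lower
  bounds with respect to a fuller, deamidation-aware inventory.
* Protein grouping is consumed, never computed: carrier counts without a
  supplied group map treat every accession independently.
* The wheat marker panel ships with seven curated wheat-specific
  peptides; a laboratory's own validated panel should be supplied for
  regulatory use.
* Abundances are relative peak areas; no mg/kg calibration from MS signal
  is attempted, so ELISA and MS are compared by rank, not by value.
* Semi-specific/non-specific digestion and PTM-aware cleavage are not
  modelled.

## Session

```{r}
sessionInfo()
```
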