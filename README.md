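# glutenscreen

Gluten protein fragments survive malting, fermentation and filtration, and
some of them still carry the epitopes that matter for coeliac disease. The
regulatory assays (R5 competitive ELISA) quantify gluten through a handful
of short antibody motifs, while targeted LC-MS quantifies specific hordein
peptides directly — and the two can disagree badly on hydrolysed samples
such as beer. `glutenscreen` is an R/Bioconductor-style package for exactly
this analysis gap: it screens prolamin sequences and detected-peptide lists
for immunogenic epitopes, aggregates multiple-reaction-monitoring (MRM)
peak areas into peptide-, protein-class- and sample-level gluten
abundances, and reports where antibody and mass-spectrometry estimates
part ways.

It is written for proteomics practitioners and food-safety analysts who
have (a) protein FASTA files and/or peptide lists from a database search,
(b) transition-level peak-area exports from MRM software, and optionally
(c) ELISA results, and who want a reproducible, scriptable screen rather
than spreadsheet arithmetic.

## What it computes

**In silico digestion.** Trypsin (cleave C-terminal to K/R) and
chymotrypsin (F/W/Y/L/M, configurable) with the proline-suppression rule: a
candidate site immediately followed by P is not cleaved and does not count
as a missed cleavage. This is why the wheat HMW-glutenin marker
DVSPGCRPITVSPGTR, with its internal RP, is a single fully tryptic peptide.

**Epitope scanning.** An epitope motif list combines three classes:

* `R5` — the antibody recognition 5-mers QQPFP, QQQFP, QLPFP, LQPFP;
* `DQ_core` — 9-residue HLA-DQ2.5/DQ8 cores (native Q-forms, Sollid
  nomenclature);
* `immunogenic_Tcell` — longer confirmed T-cell epitope regions, including
  the C-hordein repeat PQQPFPQPQQPFP (IEDB 226653).

Protein-level scans count every occurrence at every start position
(overlaps included — prolamin repeats make them common). Peptide-level
scans apply the *intact-core criterion*: a peptide is immunogenic-positive
when it retains at least `min_core_match` contiguous residues of an
epitope (9 for DQ cores and T-cell epitopes), i.e. when proteolysis failed
to destroy the core. Censuses report instances (total occurrences) and
carriers (distinct proteins/protein groups or distinct peptide
sequences), plus the R5-versus-DQ overlap partition.

**MRM aggregation.** Per (sample, peptide): the three transition peak
areas are summed within each technical replicate, oxidised- and
reduced-Met precursor forms are merged, the peptide abundance is the mean
of the four replicate sums, and variability is the coefficient of
variation (sample SD / mean). Class summaries give mean ± SD and net area
per protein class; the *net hordein* total sums the B-, C-, D- and
gamma-hordein classes and excludes avenin-like proteins (ALPs), which are
prolamins but not hordeins. A wheat-marker panel flags contamination, and
the concordance report compares ELISA mg/kg with net hordein area by
Spearman rank correlation and lists samples whose ranks disagree by more
than a margin — the signature of ELISA signal suppression.

**Simulators.** `simulateProteins()` builds Q/P-rich repetitive sequences
with planted epitope occurrences verified by an independent naive scanner;
`simulateTransitions()` builds transition tables with known true
abundances under multiplicative lognormal noise; `simulateStudy()` wires
both into a complete seeded study bundle with ELISA-like values that are a
monotone function of true hordein content (optionally suppressed for
designated samples). Everything downstream is therefore testable with
exact ground truth.

## Worked example

```r
library(glutenscreen)
ml <- defaultMotifList()

annotatePeptides(c("IIPQQPQQPFPL", "QPQQPFPQPQQPFPL", "ELQESSLEACR"), ml)
#>   peptide_sequence r5_positive immunogenic_positive
#> 1     IIPQQPQQPFPL        TRUE                 TRUE
#> 2  QPQQPFPQPQQPFPL        TRUE                 TRUE
#> 3      ELQESSLEACR       FALSE                FALSE
```

The two C-hordein peptides each contain a full QQPFP (so a competitive R5
ELISA could see them) *and* retain >= 9 contiguous residues of a confirmed
T-cell epitope (so they are clinically relevant); the D-hordein peptide
ELQESSLEACR carries neither.

```r
inSilicoDigest(c(B1 = "MKDVSPGCRPITVSPGTRAAK"),
               DigestParams("trypsin", maxMissedCleavages = 0, minLength = 5))
#>           sequence parent_accession start end missed_cleavages  enzyme
#> 1 DVSPGCRPITVSPGTR               B1     3  18                0 trypsin

censusPeptides(c("IIPQQPQQPFPL", "QPQQPFPQPQQPFPL", "SQQPQQPFPL",
                 "ELQESSLEACR"), ml)
#> CensusReport (peptide level): 4 targets, 10 hits
#>      epitope_class instance_count carrier_count
#>                 R5              3             3
#>            DQ_core              1             1
#>  immunogenic_Tcell              6             3
#> Carrier overlap (R5 vs DQ/T-cell):
#>            subset carrier_count
#>           R5_only             0
#>  DQ_or_Tcell_only             0
#>              both             3
```

ELISA arithmetic on the shipped 14-beer survey table:

```r
conc <- elisaConcordance(beerElisaTable())
conc$group_means
#>   label_group mean_mg_per_kg printed
#> 1     control      55.320000    55.3
#> 2  low_gluten       5.988889     6.0
conc$lg_percent_of_max_control$printed   # 4 (% of C2, the highest control)
```

For a full run, `runSimulate("demo", seed = 1)` writes a synthetic study
bundle plus `config.yaml`; `runAll("demo/config.yaml")` produces census
tables, peptide quant with CVs, class summaries, the annotated heatmap
matrix, the wheat panel, the concordance report and run manifests under
`demo/reports/`. The same stages are available from the shell via
`exec/glutenscreen {census|quant|all|simulate}`.

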