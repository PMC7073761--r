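# potevol

Dating and classifying recent segmental gene-family duplications, built
around the primate *POTE* family (14 human paralogs on seven
chromosomes, derived from *ANKRD26*). The package is aimed at molecular
evolutionists who want a tested, scriptable version of the classic
distance-based dating workflow for very young paralogs, together with a
transposable-element-signature classifier and a synthetic gene-family
generator that gives every stage a known ground truth.

## What it computes

Given an aligned set of paralog and ortholog sequences, the pipeline

1. removes every alignment column containing a gap or `N` in any
   sequence (*complete deletion*);
2. estimates pairwise distances under the Kimura 2-parameter model,
   `d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q))` with its analytic variance
   (`P`, `Q` = transition/transversion proportions; Jukes–Cantor and
   p-distance are also available);
3. builds a neighbor-joining tree (Saitou–Nei `Q`-criterion) and
   attaches bootstrap support plus an interior-branch test (bootstrap SE
   of each interior edge, one-sided normal confidence that its true
   length exceeds zero);
4. checks rate constancy with Tajima's relative rate test,
   `chi² = (m1 - m2)²/(m1 + m2)` on lineage-unique substitution counts
   against a named outgroup;
5. calibrates a per-lineage substitution rate `R = K/(2T)` from dated
   species splits (defaults: human–chimpanzee 6 Myr, human–orangutan
   16 Myr) and dates each duplication as `T = K/2R` with a propagated
   standard error;
6. classifies each paralog into *POTE* groups I–IV from its LINE
   content (L1PA invasion, intron-1 L1M5, the intron-9
   L1M5–L1PA15–L1M5 vs L1ME3G–L1PA15–L1ME3G cluster, and the duplicated
   exon 6–9 block), recording which rules fired; conflicting or empty
   rule sets yield `ambiguous`;
7. locates long inverted repeats (the stem-loop-forming LIR of the last
   intron) by constrained local alignment of a sequence against its own
   reverse complement, calling `full`/`half`/`none` arms.

A synthetic-data module simulates gene families under a K2P process
along duplication/speciation time-trees, with branch-specific repeat
insertions, so parameter recovery and classifier accuracy are checkable
end to end without any downloads.

## Worked example

Simulate a group III-style family in which two paralogs duplicated
1.9 Myr ago, with chimpanzee and orangutan orthologs for calibration,
and date the event:

```r
library(potevol)
sc  <- scenario_presets()$groupIII_EF
fam <- simulate_family(sc, seed = 42)
rep <- date_family(fam$alignment, sc$event_pairs, sc$calibrations,
                   outgroup = sc$outgroup)
rep[c("event", "K", "T_myr", "se_T_myr", "tajima_p")]
#>             event           K    T_myr  se_T_myr tajima_p
#> 1 groupIII_EF_dup 0.004011274 1.991729 0.3151763 0.630954
attr(rep, "rate")
#> per-lineage rate R = 0.00100698 +- 5.6e-05 subs/site/Myr (2 calibrations)
```

`K` is the K2P distance between the two duplicates after complete
deletion; the calibrated rate recovers the generating
0.001 subs/site/Myr, the date estimate brackets the 1.9-Myr truth
within one standard error, and the non-significant Tajima p-value says
the two paralog lineages are clock-like, as simulated. The same
family's repeat tracks classify back to group III:

```r
assign_group(extract_line_signature(fam$tracks$POTEE,
                                    fam$models$POTEE))$group
#> [1] "III"
```

## Analysis workflow

The numbered drivers under `analysis/` run the full study on simulated
families and leave their tables under `results/`:

```sh
Rscript analysis/01_simulate.R         # six scenario families + manifest
Rscript analysis/02_distances_trees.R  # K2P matrices, NJ trees, support
Rscript analysis/03_dating.R           # calibrated dates vs truth
Rscript analysis/04_classify.R         # group calls + feature table
```

Configuration-driven runs on arbitrary inputs go through
`run_config()` / `run_pipeline()` (or a flat `key = value` file via
`read_run_config()`); outputs are TSV tables with JSON mirrors, a
Newick tree with support labels, and a run report embedding the seed,
config hash and per-file checksums.

## Classifier rule ids

| rule | condition | group |
|------|-----------|-------|
| R1 | L1PA invasion ≥ 20% of locus bp AND L1M5 in intron 1 | I |
| R2 | L1M5 in intron 1 AND intron-9 cluster L1M5–L1PA15–L1M5 | II |
| R3 | no intron-1 L1M5 AND duplicated exon 6–9 block | III |
| R4 | no intron-1 L1M5, no duplication, cluster L1ME3G–L1PA15–L1ME3G | IV |

More than one rule (or none) firing yields `ambiguous` with the
conflict recorded — the behaviour the real *POTEKP* shows between
groups III and IV.
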