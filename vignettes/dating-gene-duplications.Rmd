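---
title: "Dating and classifying young gene duplications with potevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating and classifying young gene duplications with potevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(potevol)
```

## The problem

The human *POTE* family is a set of 14 paralogs spread over seven
chromosomes by segmental duplication, most of them pericentromeric and
more than 90% identical to one another. The youngest duplications are
human-specific and under ~2 Myr old, which puts them in the regime where
distance-based dating works well: divergence between duplicates is far
from saturation, so a simple substitution model with an externally
calibrated rate gives an essentially unbiased time estimate with a
tractable standard error. This package implements that workflow —
model-corrected distances, neighbor-joining with support, a relative
rate test, and `T = K/2R` dating — together with a rule-based classifier
that reads each paralog's group identity off its LINE (L1) content, and
a simulator that generates families with known histories so every claim
the pipeline makes can be checked against truth.

## Models and procedure

### Site filtering

All distance work happens after *complete deletion*: every alignment
column containing a gap or `N` in **any** sequence is removed once,
globally, before any pairwise comparison. This matches the option named
in the dating protocol the pipeline follows and makes all pairs use the
same sites. We treat `N` like a gap — the conservative reading, since an
ambiguous base cannot be scored as a match or mismatch. A `pairwise`
deletion mode exists for diagnostics; the two differ exactly when gapped
columns exist.

### Distances

For a pair of sequences with `n` compared sites, transition proportion
`P` and transversion proportion `Q`:

* Kimura 2-parameter: `d = -1/2 ln((1-2P-Q) sqrt(1-2Q))`, variance
  `[c1²P + c3²Q - (c1 P + c3 Q)²]/n` with `c1 = 1/(1-2P-Q)`,
  `c2 = 1/(1-2Q)`, `c3 = (c1+c2)/2`.
* Jukes–Cantor: `d = -3/4 ln(1 - 4p/3)`, variance
  `p(1-p)/(n (1-4p/3)²)`.

Both closed forms are the maximum-likelihood estimators of their models;
the test suite verifies them against direct numerical likelihood
maximization to 1e-6 rather than trusting the algebra. Saturated pairs
(`p ≥ 3/4`, or a non-positive K2P log argument) raise a classed error
that names the offending pairs: a silent `NaN` entering
neighbor-joining would corrupt the topology quietly, and halting with a
list is the only diagnosable behaviour.

The distance "standard errors" reported are the analytic (delta-method)
variances above. A site-bootstrap alternative is implicit in the
interior-branch machinery; for the pair distances themselves the
analytic form is what the dating SEs propagate, and the simulation tests
confirm it matches the sampling spread to ~10%.

### Neighbor-joining

Standard Saitou–Nei: join the pair minimizing
`Q(i,j) = (r-2) D(i,j) - Σ_k D(i,k) - Σ_k D(j,k)`, with the usual
two-point branch-length formulas. Two numerical choices are pinned down
because the algorithm is otherwise underspecified:

* **Ties** in the Q matrix are broken by the lowest `(i, j)` index pair
  in the current node ordering, making runs bit-reproducible; across
  taxon permutations the result is identical up to relabeling (tested on
  permuted inputs by comparing bipartition sets).
* **Negative branch lengths**, which NJ can produce on non-additive
  input, are clamped to zero with the deficit moved to the adjacent
  branch of the join, preserving path lengths — a common convention.
  The number of clamped branches is recorded on the tree
  (`attr(tree, "n_clamped")`) and surfaces as a pipeline warning.

On exactly additive matrices NJ provably recovers the generating tree;
the tests check topology and branch lengths to 1e-10 against 4- and
5-taxon trees and an exhaustive least-squares topology oracle.

### Support values

Bootstrap support resamples alignment columns with replacement, rebuilds
the NJ tree, and scores each original interior edge by the fraction of
replicate trees containing its bipartition. Support lives on [0, 1]
internally; percentages are presentation only. Replicates whose
resampled distances saturate are dropped and counted, and more than 20%
dropped aborts the run (at that point the support values no longer
estimate anything meaningful).

The interior-branch test reuses the same replicates: for each interior
edge the branch length is collected per replicate (zero where the split
is absent), its standard deviation is the branch SE, and the confidence
probability is `pnorm(length/SE)` — the one-sided normal probability
that the true length exceeds zero. A zero-length edge with zero SE gets
0.5 by convention (no information), a positive edge with zero SE gets 1.
The exact statistic behind the published interior-branch tests in the
standard desktop tools is not documented; this bootstrap-SE z-test is
our operationalization and is labelled as such in reports.

### Rate test and dating

Tajima's relative rate test counts sites where only one ingroup taxon
differs from the other two (`m1`, `m2`); under a clock
`chi² = (m1-m2)²/(m1+m2)` is asymptotically chi-square with 1 df. The
test is nonparametric in the sense that it needs no rate estimate, which
is why it is attached to every dated pair. `m1 + m2 = 0` returns
`p = 1`. The outgroup must be named explicitly — automatic outgroup
selection invites silent misrooting.

Dating uses `T = K/2R` exactly. The per-lineage rate `R` comes from
calibration pairs: each pair with split time `T_i` contributes
`R_i = K_i/(2T_i)`, and the headline `R` is their unweighted mean. The
protocol we follow names two calibrations (human–chimpanzee 6 Myr,
human–orangutan 16 Myr) without saying how they were combined; we
report per-calibration rates alongside the mean, and the rate SE
combines the delta-method propagation of each `Var(K_i)` with the
between-calibration spread: `se² = Σ Var(K_i)/(2T_i)²/k² + var(R_i)/k`.

`se_T` defaults to distance-variance-only propagation,
`sqrt(Var(K))/(2R)` — matching the convention that per-event "±" values
reflect the event's own distance uncertainty — and the rate-uncertainty
component `K·se_R/(2R²)` is reported separately plus in quadrature
(`se_T_total`). Reported uncertainties are 1 SE, not confidence
intervals. When one duplication node is spanned by several paralog
pairs, `K` is the arithmetic mean of the spanning pair distances and
its variance is approximated as `mean(var_i)/k` (independence
approximation; the pairs share sites, so this is a mild
underestimate — the recovery tests show the resulting intervals are
still honest at the simulated sizes).

### LINE-signature classification

Four rules, one per group, each firing independently on the signature
extracted from a RepeatMasker track and a gene model (see the README
table). Two thresholds had to be made operational because the source
description is qualitative:

* *"Massive" L1PA invasion* (group I) is defined as `L1PA*` elements
  covering ≥ 20% of the locus span, configurable. On the synthetic
  families the invaded loci carry ~25% and the others < 4%, so the
  default is far from both.
* The intron-9 cluster is matched as the **ordered subsequence of LINE
  names** overlapping canonical intron 9, ignoring interleaved non-LINE
  hits, because RepeatMasker fragments elements and interleaves SINE
  calls.

Conflicting rules (or none) yield `ambiguous` with the conflicting
groups listed — deliberately a value, not an error, mirroring the
genuinely unclassifiable paralog in the real family. Exon numbering
follows the 11-exon canonical scheme; paralog-specific extra exons are
annotations and never renumber introns.

### Inverted-repeat (LIR) detection

The detector runs Smith–Waterman local alignment (match +1, mismatch
-1, gap -2) of the sequence against its own reverse complement,
restricted to cells `i + j ≤ n` so the two aligned segments cannot
overlap — this removes the trivial self-diagonal and forces a genuine
arm/loop/arm geometry. The scan is compiled (Rcpp) and keeps a full
traceback matrix, hence the 10-kb input cap; longer loci should be
windowed. "Full" vs "half" LIR was never defined operationally in the
source material, so the thresholds are configuration with defaults
`full_arm = 500` bp and `min_arm = 200` bp at ≥ 80% arm identity, and
results report the measured arm length, identity and loop so users can
re-threshold. Note that the best-scoring arms may extend a few bases
beyond a "designed" perfect repeat when flanking sequence happens to
pair net-positively; the tests therefore compare coordinates against a
brute-force oracle on constructions whose flanks cannot pair, and
score-dominance on random flanks.

## The simulator: what it does and does not emulate

`simulate_family()` draws a uniform root sequence and evolves it along
an ultrametric event tree (speciations + duplications at stated Myr)
under a continuous-time K2P process: per branch of `t` Myr the total
expected divergence is `R·t` with transition/transversion rate ratio
`kappa`. Defaults are `R = 0.001` subs/site/Myr — a typical neutral
primate rate, chosen once because it reproduces ~1.2% human–chimp
divergence at a 6-Myr split — `kappa = 2` (typical mammalian transition
bias, and distinct enough from 1 that K2P and JC disagree measurably),
and 10,000 sites. Six scenario presets encode the family's dated
human-specific duplications (1.90, 1.57, 1.07, 1.06, 0.55, 0.44 Myr,
nested where the real events are nested) with both calibration splits.

Repeat insertions are **annotation-level**: each insertion places an
element in the named intron of every descendant of its lineage and
nowhere else, exercising exactly the presence/absence logic the
classifier consumes. Sequence-level TE insertion would require
indel-aware alignment, which is out of scope. Likewise the simulator
generates gap-free alignments (complete deletion is then a no-op); a
gap-injection option exists solely to exercise the deletion logic.

Consequently, passing tests demonstrate correctness of the estimators
under their own model assumptions — not robustness to alignment error,
rate heterogeneity across sites, gene conversion between paralogs, or
indel evolution, none of which are simulated. Real *POTE* data involve
all four, and gene conversion in particular can make duplicates look
younger than they are; the dating reported on real families should be
read with that caveat.

## Problem sizes and reproducibility

The statistical acceptance checks run at the study's stated sizes: the
relative rate test's type-I error is estimated from 1,000 clock-like
replicates of 10,000 sites (expected in [0.03, 0.07] at α = 0.05) and
its power from 200 replicates with one lineage tripled; each dating
preset is recovered over 200 replicates at 10,000 sites (median error
under 3 median SEs); NJ is checked on 100 random additive 5-taxon
matrices; unit tests use smaller alignments. All randomness flows from
explicit integer seeds — the simulator takes one per family, the
pipeline derives its bootstrap substream from the config seed — so
every table in `results/` is byte-reproducible, and the pipeline report
embeds the seed, a config hash, and an md5 per output file.

## Known limitations

* No gamma rate heterogeneity, Tamura–Nei/GTR, or codon models; for
  paralogs this young the K2P/JC difference is already marginal, but
  older families would need richer models.
* No ML or Bayesian topology search and no rate smoothing: the tree
  stage is NJ-based by design.
* The LIR scanner is O(n²) in time and memory and capped at 10 kb.
* `ambiguous` classifications are not further resolved; resolving the
  real family's ambiguous paralog needs evidence the LINE signature
  does not carry.
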