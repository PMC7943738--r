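---
title: "Estimating viral-human zwitter epitope candidates: models and design"
author: "zwitterscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating viral-human zwitter epitope candidates: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zwitterscan)
```

## The question

Proteasomes produce the bulk of the peptides presented on HLA class I
complexes, both by hydrolysis (contiguous, "non-spliced" fragments) and
by ligating two non-contiguous fragments of the same molecule
(*cis*-splicing, in normal or reverse order).  Because splicing is
combinatorial, the theoretical *cis*-spliced 9mer repertoire of a protein
is two to three orders of magnitude larger than its non-spliced
repertoire.  If many viral peptides were producible verbatim from human
proteins — *zwitter* peptides — then thymic negative selection against
the self copy would delete exactly the T-cell clones needed against the
virus.  This package quantifies how large that overlap can be, and how
quickly it shrinks once HLA binding, mTEC antigen expression, and the
measured scarcity of spliced peptides in immunopeptidomes are accounted
for.

## Enumeration model

A *cis*-splicing scheme on a protein of length $L$ is a pair of disjoint
fragments (splice-reactants) whose concatenation has length $k$ (default
9, the dominant HLA-I peptide length).  Coordinates are 1-based
inclusive throughout; fragment 1 always denotes the N-terminal fragment
of the *product*.  In normal order fragment 1 precedes fragment 2 in the
substrate; in reverse order it follows it.  The printed notation is
`<protein>.<s1>-<e1>/<s2>-<e2>`.

Tunable parameters (`enumerationConfig()`), all in residues:

| parameter | default | rationale |
|---|---|---|
| `peptideLength` | 9 | majority length of non-spliced and cis-spliced HLA-I peptides |
| `maxIntervening` | 25 | conventional cap on the intervening sequence between reactants |
| `minGapNormal` | 1 | gap 0 in normal order reproduces the contiguous sequence, which would not be a spliced product |
| `minGapReverse` | 0 | adjacent fragments ligated in reverse order do form a new sequence |
| `minReactantLength` | 1 | reactants of any length are allowed |
| `excludeNonstandard` | TRUE | peptides containing B, J, O, U, X, Z cannot be matched exactly |

The lower gap bounds are a design choice this package had to make: the
field convention fixes only the upper bound (25).  Gap-0 normal
ligation is excluded because it is indistinguishable from hydrolysis;
gap-0 reverse ligation is included because its product is genuinely
non-contiguous.  Both are configurable.

Closed-form counting (`countCisSchemes()`) sums placements over fragment
split and gap instead of enumerating, and is tested to agree exactly
with enumeration for $L \in [2, 60]$ under the default and randomized
configurations.  At $L = 500$ the default convention yields 195,536
schemes against 492 windows, a ratio of 397.43.  The literature reports
$\gamma = 398$ for proteins of 500 residues or longer; no stated gap
convention reproduces 398 exactly, so $\gamma$ stays a *configurable
constant* (default 398) in the PCPS stage, deliberately decoupled from
the closed form.  A boundary case worth recording: a 9-residue protein
admits exactly 8 cis schemes under the defaults — the gap-0 reverse
tilings that rotate the sequence — which the brute-force oracle in the
test suite confirms.

## Zwitter statistics

For each virus the four category pairs are counted on deduplicated,
per-virus peptide universes: `z_i` (viral-non × human-non), `z_j`
(cis × cis), `z_k` (non × cis), `z_l` (cis × non).  Matching is exact
string equality on uppercase sequences; no I/L equivalence.  Relative
frequencies divide by the cognate viral universe: `F_v_non` by the
non-spliced universe, `F_v_cis` (the unique union of the three
cis-involving pairs) by the cis universe, `F_v_all` by the union
universe.  Whether the cis denominator should be the cis universe or the
union is genuinely ambiguous in the field's usage; we chose the cognate
universe reading and report all denominators in the output so either can
be recomputed.

Group comparisons use the two-sided two-sample Kolmogorov–Smirnov test
(significance at 0.05), per-virus odds ratios on the zwitter/binder 2×2
table with a two-sided Fisher exact test, and Pearson correlation
between proteome size and zwitter count.  Fisher switches to a
chi-square test with continuity correction above `fisherMax = 10000`
total observations — the switchover is configurable and recorded in the
result, since "too large for Fisher" is a judgment call.  Odds ratios
with a zero margin or a zero denominator cell are reported as missing
with an explicit reason, never as ±infinity.

## Binding model

Binding predictions follow the position-scoring-matrix contract of
SMM-style predictors: $\mathrm{IC50} = 10^{b + \sum_p S[p, aa_p]}$ nM.
The real predictor's weights are not re-derived here; the package ships
a calibrated toy matrix generator for testing and an adapter
(`loadExternalPredictions()`) for IC50 tables produced externally.  The
binder cutoff comparison is inclusive (≤ 500 nM, or ≤ 50 nM for the
stringent analysis), and filtered sets provably nest across cutoffs.
Percentile ranks are not computed: they require the predictor's
background distribution, which only the external tool has.

## Presentation weighting

mTEC expression enters as either of two platforms:

* **microarray**: per gene, the mean log2 intensity over the technical
  replicates of each mTEC subset, then the maximum over subsets;
* **single-cell**: $x_{ij} = \log(10^5 \cdot \mathrm{UMI}_{ij} /
  \sum_i \mathrm{UMI}_{ij} + 1)$ per cell, then the mean over cells.
  The log base is not fixed by convention; we use the natural log, and
  it is configurable.

Weights are min–max scaled and normalized to sum 1; the gene(s) at the
minimum get weight 0.  A constant expression vector is degenerate (the
formula is 0/0); we fall back to uniform weights with a warning.  A
peptide's weight is the *sum* of its human source-gene weights —
presentation chances add over independent sources — with genes absent
from the expression table contributing 0 (counted and reported).
Sampling draws `round(sizeFraction * n_pool)` peptides with replacement,
probability proportional to weight, 60 repeats by default; a peptide
counts as presented in a repeat when drawn at least once (set counting,
because the counts are compared against unique-peptide denominators).
`sizeFraction` defaults to 1 ("100%") but is deliberately allowed above
1: in the limit of exhaustive oversampling with equal weights the
weighted estimate $M_v$ recovers the unweighted $F_v$ exactly, which is
both an invariant of the method and a test anchor.

## PCPS frequency propagation

From an in-vitro digestion table, `estimateFnon()` computes per
substrate the fraction of theoretical 9mer windows observed among
non-spliced products and takes the median across substrates (in-vitro
data put this near 0.27).  Given an assumed immunopeptidome cis share
$f$ (surveyed range 1–34%; the sweep grid default runs to 35, both ends
configurable), the presented fraction of theoretical cis peptides is
$f_{cis} = f \cdot f_{non} / (\gamma (100 - f))$.  The sweep subsamples
every universe without replacement at these rates — independently on the
viral and human sides, so a zwitter pair survives only if its sequence
survives on both — and re-runs the intersection, 600 repeats per $f$ by
default.  Binder restriction is applied *after* sampling.  Sample sizes
round half-even (R's default; the convention had to be picked).  Seeds
follow a ladder (master → per-$f$ stream → per-repeat substream) so
extending the $f$ grid never perturbs existing repeats; the whole sweep
is bitwise reproducible from the master seed.

## The synthetic-data module

Every input has a generator: i.i.d. uniform-composition proteomes
(uniform keeps accidental 9mer collisions rare at fixture scale; a
human-like composition is available), microarray and single-cell
expression tables, digestion tables with a target observed fraction, and
binding matrices whose intercept is calibrated by the empirical quantile
of scores over $10^5$ random peptides so a target binder rate at the
cutoff is met within about 1%.

Planting ground truth is the delicate part.  Writing the same 9mer into
both proteomes makes its substrings shared too, and under the default
enumeration convention that *necessarily* creates additional shared cis
products: any common single-letter partner within the 25-residue window
of a shared 8mer (present with probability ≈ 0.7 per letter per side)
reconstructs the same extended product on both sides, and gap-0 reverse
ligation turns every rotation of a contiguous planted 9mer into a shared
cis product.  No amount of re-drawing fixes this — it is structural.
Exact ground-truth recovery is therefore only *identifiable* under a
restricted fixture geometry, which `plantZwitter()` and
`zwitterFixture()` use by default: `minReactantLength = 4`,
`minGapReverse = 1`, planted peptides drawn from the 16-letter alphabet
excluding four reserved flanking letters (viral plants are flanked by
G/P, human plants by K/R, so a boundary extension on one side can never
equal pure peptide or the other side's boundary), and different split
points on the two sides of a cis × cis pair.  Residual coincidences
(a background 4mer near both copies, ~0.016 expected per plant) are
caught by the built-in verification — a full enumeration + intersection
run after planting — which regenerates the fixture on failure and fails
loudly with a diagnostic once retries are exhausted.

What the generator does *not* emulate: real amino-acid composition
biases, proteasome cleavage-site preferences, HLA motif structure, and
mass-spectrometry detectability.  Passing the planted-truth tests shows
the pipeline's bookkeeping is exact, not that real proteomes behave like
the fixture.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so
the full pipeline completes in seconds per run: human fixtures of 25–40
proteins × 80–300 residues, 1–5 viruses of 2–3 proteins each, sweeps of
200–600 repeats, oracle comparisons on 200 random proteins up to 40
residues, and Fisher-vs-enumeration checks over all 2×2 tables with row
sums ≤ 18 plus a randomized slice up to 30.  At full scale (a 2×10⁷
residue self proteome, ~4×10⁹ cis peptides) the same code paths apply
but the unique-universe step should be run per chromosome/batch and
merged; the enumerators stream schemes and never materialize more than
one at a time.

## Known limitations

* mRNA abundance is a crude proxy for presentation probability; the
  weighting stage inherits that assumption and no alternative model is
  implemented.
* The analysis is restricted to cis-splicing of two reactants;
  trans-splicing and ≥3-fragment ligation are out of scope.
* TCR cross-reactivity is ignored: one exact-match peptide, one clone.
* Binding is a single-allele filter; population-level HLA coverage is
  not modelled.
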