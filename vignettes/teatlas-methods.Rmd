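---
title: "Methods: LTR insertion dating, atlas statistics and gene-model selection"
author: "teatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LTR insertion dating, atlas statistics and gene-model selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teatlas)
```

This vignette documents the models behind the package, the choices made
where the methodology was genuinely open, the numerical conventions, and
what the simulators do and do not emulate.

## Dating LTR retrotransposon insertions

### Model

An LTR retrotransposon inserts with two identical long terminal repeats.
Each LTR then accumulates substitutions independently at a per-site rate
*r* per year, so after *T* years the expected divergence between the two
LTRs is *2rT* substitutions per site. Estimating the divergence *K* and
inverting gives the insertion age

$$T = \frac{K}{2r}.$$

*K* is the Kimura two-parameter (K2P) distance, which corrects observed
transition (*p*) and transversion (*q*) frequencies for multiple hits while
allowing the two substitution classes different rates:

$$K = -\tfrac12 \ln\!\left[(1 - 2p - q)\sqrt{1 - 2q}\right].$$

The negative sign and the natural logarithm are the standard form of this
estimator; without the sign the expression is negative for every valid
(*p*, *q*), so a distance interpretation forces it.

Assumptions: substitutions only (no indel clock), site independence,
homogeneous rates in time and across sites, and the same clock rate *r*
for both genomes being compared. The default
*r* = 1.3 × 10⁻⁸ subs/site/year is the plant nuclear rate used throughout
the dating stage; it is a parameter of `insertion_time()` and `date_ltrs()`
and every reported age scales as 1/*r*.

### Estimation pipeline and numerical conventions

- **Full-length filter.** Only elements whose annotation records all five
  retroelement protein domains (GAG, RT, RH, AP, INT) are dated; truncated
  elements often carry deleted or rearranged LTRs that violate the clock
  assumption.
- **Alignment.** The 5′ and 3′ LTRs are aligned end-to-end with a global
  affine-gap dynamic program (Gotoh algorithm, implemented in C++).
  Default scores: match +2, mismatch −1, gap open −5, gap extend −1; a gap
  run of length L costs `gap_open + L * gap_extend`. Ties in the dynamic
  program are resolved deterministically (diagonal state preferred, then a
  gap in the 3′ LTR, then in the 5′), so results are reproducible
  bit-for-bit. Two homologous LTRs are an easy alignment problem; the
  scoring defaults only matter near saturation.
- **Site frequencies.** Gap and N columns are pairwise-deleted; *p* and
  *q* are computed over the remaining compared sites; at the divergences
  where dating is meaningful the treatment of the rare gap columns is
  immaterial.
- **Saturation.** When 1 − 2p − q ≤ 0 or 1 − 2q ≤ 0 the logarithm is
  undefined: the pair is flagged `saturated`, excluded from age summaries,
  and counted in an `n_undatable` tally rather than silently dropped.
- **Recency.** An element is "recent" when *T* < 500,000 years, strictly.
  Because *K*/2*r* is computed in floating point, ages within one part in
  10⁸ of the threshold are treated as equal to it and classify as old:
  K = 0.013 at the default rate gives exactly the 0.5 My boundary and is
  not recent.
- **Cross-genome contrast.** Recent/old counts per genome form a 2×2
  table tested with a two-sided exact Fisher test. The two-sided p-value
  is the minimum-likelihood definition: the sum, over all tables with the
  observed margins, of hypergeometric point probabilities not exceeding
  the observed one (relative tolerance 10⁻⁷, matching the convention of
  standard implementations). The test suite verifies exhaustive agreement
  with brute-force enumeration for every table with total count up to 30.
- **Minus-strand elements.** GFF3 coordinates are 1-based inclusive; LTR
  sequences of minus-strand elements are reverse-complemented so that both
  LTRs are reported in the element's own orientation (the distance itself
  is strand-invariant).

## The substitution simulator

`mutate_sequence_k2p()` applies the exact closed-form site substitution
probabilities of the K2P process at total branch length
*d* = *r* × age, rather than iterating per-generation events: with
transition/transversion rate ratio κ and per-event rates normalized to one
expected substitution per unit branch length (α = κβ, α + 2β = 1),

$$P(\text{transition}) = \tfrac14 - \tfrac12 e^{-2(\alpha+\beta)d} + \tfrac14 e^{-4\beta d},
\qquad P(\text{transversion}) = \tfrac12\!\left(1 - e^{-4\beta d}\right).$$

This is exactly the model the estimator inverts, so round-trip tests
(simulate at known age, estimate, compare) are a sharp correctness check;
the test suite independently validates these probabilities against a
matrix exponential of the K2P rate matrix.

Choices: κ defaults to 2.0 — a typical plant nuclear
transition/transversion ratio; the dating method itself never uses κ, so
it is purely a simulation parameter. Ancestral sequences are uniform over
A/C/G/T (no GC bias). No indels are simulated by default, because the
distance uses substitutions only; the aligner's gap handling is exercised
directly by alignment tests instead. All generator randomness flows from
one integer seed per call (the RNG state is scoped, not leaked), and
outputs are byte-identical across runs with the same seed.

`simulate_ltr_library()` assembles the elements into one synthetic contig
(5′ LTR + random internal region + 3′ LTR, random spacers between
elements) with a GFF3-style feature table and a truth table of planted
ages. It does not emulate TE nesting, fragmentation, solo LTRs or
non-uniform base composition, so passing recovery tests demonstrate
estimator correctness under the clock model, not robustness to assembly
artefacts in real genomes.

## Transcriptome-atlas statistics

### Normalization

Library size factors use the median-of-ratios method: the reference for
each gene is its geometric mean across columns, computed over genes with
strictly positive counts everywhere; each column's factor is the median
ratio of its counts to the reference. Consequences worth noting: factors
are invariant to a global rescaling of the matrix (the reference rescales
identically), and normalized values therefore scale linearly — the
meaningful invariant is the ratio structure between columns. If no gene is
positive in every column the factors are undefined and the function stops
rather than falling back to a pseudo-reference.

### Expressed-gene calls, breadth, stability, clustering

- A gene is **expressed** in a sample when its normalized count is ≥ 5
  (inclusive, "5 or more") in *both* biological replicates. The summary
  reports genes expressed in ≥ 1 sample, in all samples, and in none;
  these partition the gene set.
- **Breadth** is the Shannon entropy, in bits, of the replicate-averaged
  sample means rescaled to a distribution: H = 0 for a single-sample gene
  and log₂(S) for uniform expression over S samples. Genes with zero
  total are reported NA, not 0 — "no expression" is not "maximally
  narrow". Base 2 makes the maximum log₂ 46 ≈ 5.52 bits for the 46-sample
  design.
- **Stability** is SD/mean (coefficient of variation). Default: population
  SD (divisor n) over replicate-averaged per-sample values — the measure
  is a descriptive dispersion of the observed sample means, not an
  inference about a superpopulation, and averaging replicates mirrors the
  clustering convention. Both the SD divisor and the replicate averaging
  are configurable; with sample SD (divisor n − 1) on two values
  (10, 30) the ratio is √2·10/20 ≈ 0.707 instead of 0.5. Counts below
  the 0.2 / 0.25 / 0.3 cutoffs are reported; zero-mean genes are excluded
  with a flag.
- **Sample distance** is 1 − r², with r the Pearson correlation of
  replicate-averaged profiles; squaring makes the measure indifferent to
  the sign of the association and maps perfect correlation to 0.
  Zero-variance samples make r undefined and raise an error. Clustering
  is agglomerative with average linkage (UPGMA) — the linkage was not
  specified in the source methodology; UPGMA is the common default for
  correlation distances and yields an ultrametric tree, written as newick.

### The count simulator

`simulate_count_matrix()` draws negative-binomial counts
(variance μ + φμ², default dispersion φ = 0.05) around class-determined
means scaled by per-column library size factors (default: lognormal,
geometric mean 1, sdlog 0.3). The default design mirrors the atlas: 46
samples × 2 replicates. Planted classes: **broad** genes are expressed in
every sample with between-sample lognormal mean variation (sdlog 0.5 —
large enough to make them unstable, small enough to keep between-sample
correlations high, as observed in organ atlases); **specific** genes have
nonzero mean in exactly one sample; **stable** genes have a constant mean
everywhere; **silent** genes are all zero. The default class mix
(0.77 / 0.15 / 0.05 / 0.03) reproduces an atlas-like regime in which ~97%
of genes are expressed somewhere and a small minority is silent.
Between-gene base means are lognormal (sdlog 1.2), spanning the orders of
magnitude typical of expression data.

The simulator plants no batch effects, no replicate-level biological
variation beyond NB noise, no gene-gene correlation and no count overdispersion
heterogeneity, so the recovery tests certify the statistics, not
robustness to those real-data features. Size-factor recovery is validated
on all-stable (constant-mean) matrices: there the planted factors are the
only column effect, which isolates the estimator; with biological
between-sample variation switched on, the median-of-ratios estimate
carries additional sampling noise of its own (of order
SD(log ratio)/√n_genes per column), which is a property of any
median-of-ratios procedure, not an implementation defect.

## Gene-model scoring and selection

Each candidate model's score is

score = b · (supported introns + supported exons) + Σ_hits w(tier) · s(hit)
+ P_repeat·[repeat overlap] + P_TE·[TE hit],

with defaults b = 1, tier weights 10/5/2 for arabidopsis/swissprot/nr,
and penalties −100. The magnitudes are configuration, not doctrine: the
methodology fixes only the signs ("small positive bonus", "proportional"
homology bonus, "large negative penalties") and the tier ordering, which
the constructor enforces. Hit significances are used as given; the helper
`evalue_significance()` maps blastp e-values to min(1, −log₁₀(e)/20), so
e ≤ 10⁻²⁰ saturates at 1.

Selection is greedy: candidates sorted by descending score (ties: longer
span, then lexicographic id — making selection order-invariant), accepted
unless they share ≥ 1 base with an already accepted model on the same
contig *and strand*; opposite-strand overlap is allowed, since the
methodology does not forbid it and plant genomes contain genuine
antisense gene pairs. Every rejection records the accepted model that
blocked it, which makes the "every rejected model is blocked by an
equal-or-better one" invariant directly checkable.

The candidate simulator designates one winner per locus and, at extreme
evidence rates, gives it strictly dominant evidence, so greedy selection
must recover 100% of winners — a construction-based oracle. At the
default (non-extreme) rates losers occasionally outscore winners, which is
intended: it produces realistic rejection logs.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run at desk scale, chosen so
the statistical bounds they assert are comfortably powered: age recovery
uses 200 pairs × 1 kb per planted age (relative SE of the mean ≈ 4% at
0.1 My, under 1% at 5 My — the 0.1 My point is the statistically tightest
check); the recency power study samples 1,000 ages per genome over 50
seeds; atlas recovery uses 2,000 genes × 46 samples × 2 replicates; Fisher
equivalence is exhaustive to N = 30; the sequence-level recency
demonstration uses 500 elements per genome with 300 bp LTRs (LTR length
trades alignment cost against estimator variance ∝ 1/length).

## Known limitations

- The clock rate is a single constant; rate variation among families or
  lineages translates linearly into age errors, and cross-genome contrasts
  assume a shared rate.
- Saturated pairs are reported but not dated; for very old or hypermutated
  elements the method is uninformative by design.
- The aligner is pairwise-global; it does not model the tandem repeats or
  internal deletions that real LTRs sometimes carry.
- Median-of-ratios requires at least one gene detected in every library;
  very sparse designs need a pseudo-reference variant that this package
  deliberately does not provide.
- Differential expression is out of scope; only normalization and
  descriptive atlas statistics are implemented.
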