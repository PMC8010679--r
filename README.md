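# teatlas

Dating LTR retrotransposon insertions, transcriptome-atlas statistics and
evidence-based gene-model selection — the three bespoke computational
stages of a plant genome/transcriptome-atlas analysis, reimplemented as a
tested R package with simulators that provide ground truth for every
stage.

## What it computes

**LTR insertion dating.** The two long terminal repeats (LTRs) of a
retrotransposon are identical when the element inserts and diverge
afterwards, so their divergence dates the insertion. For each full-length
element (one carrying GAG, RT, RH, AP and INT protein domains) the package
globally aligns the 5′ and 3′ LTRs, counts the transition frequency *p*
and transversion frequency *q* over compared sites, computes the Kimura
two-parameter distance

    K = −½ · ln[(1 − 2p − q) · √(1 − 2q)]

and converts it to an insertion time *T = K / 2r* with a substitution rate
*r* (default 1.3 × 10⁻⁸ substitutions/site/year). Elements younger than
0.5 My are "recent"; two genomes are contrasted with a 2×2 exact Fisher
test on recent/old counts, per-family copy-number fold ratios and
cumulative age curves. Repeatome read-cluster tables can be renormalized
after removing organelle clusters.

**Atlas statistics.** From a genes × (sample.replicate) read-count matrix:
median-of-ratios library size factors, normalization, expressed-gene calls
(normalized count ≥ 5 in both replicates of a sample), Shannon-entropy
expression breadth over samples, SD/mean expression stability (reference
gene candidates), and sample clustering under the distance 1 − r² on
replicate-averaged profiles (UPGMA, newick output).

**Gene-model selection.** Candidate models from several predictors are
scored — a small bonus per RNA-seq-supported intron/exon, homology bonuses
weighted by database tier (arabidopsis > swissprot > nr) and hit
significance, large negative penalties for repeat/TE overlap — and a final
non-overlapping annotation is chosen greedily, best score first, with a
rejection log naming each blocking model.

**Simulators.** Every stage has a generator with recorded truth: LTR pairs
diverged under the exact closed-form two-parameter substitution process
for known ages, negative-binomial count matrices with planted
broad/specific/stable/silent genes and known library size factors, and
overlapping candidate pools with a designated dominant-evidence winner per
locus.

## Worked example

```r
library(teatlas)

# simulate a genome in which 26.6% of elements inserted within 0.5 My,
# then date every element from sequence alone and recover that fraction
lib_a <- simulate_ltr_library(500, ltr_length = 300,
                              age_sampler = mixture_age_sampler(0.266),
                              seed = 2)
lib_b <- simulate_ltr_library(500, ltr_length = 300,
                              age_sampler = mixture_age_sampler(0.096),
                              seed = 3)
dat_a <- date_ltrs(lib_a$features, lib_a$genome)
dat_b <- date_ltrs(lib_b$features, lib_b$genome)
cmp <- compare_genomes(dat_a$elements, dat_b$elements)
cmp$contingency
#>          recent old
#> genome_a    132 368
#> genome_b     44 456
round(cmp$recent_fraction, 3)
#> genome_a genome_b
#>    0.264    0.088
signif(cmp$p_value, 4)
#> [1] 1.886e-13
```

The recovered recent fractions (26.4%, 8.8%) match the planted ones
(26.6%, 9.6%) up to binomial noise at n = 500, and the exact Fisher test
rejects equality of the two age structures decisively.

```r
# atlas statistics on a simulated 46-sample, 2-replicate count matrix
sim <- simulate_count_matrix(count_sim_spec(n_genes = 2000, seed = 4))
res <- atlas_stats(sim$counts)
res$expressed$summary
#>   n_genes expressed_any expressed_all expressed_none pct_expressed_any
#> 1    2000          1955          1393             45             97.75
res$stability$threshold_counts
#>  <0.2 <0.25  <0.3
#>    95    97    97
```

Genes expressed in ≥ 1 sample, in all samples and in none partition the
gene set; the threshold counts are the number of genes whose SD/mean falls
below each stability cutoff.

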