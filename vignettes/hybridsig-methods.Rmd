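---
title: "Genomic tests for homoploid hybrid speciation: models and design"
author: "hybridsig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic tests for homoploid hybrid speciation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridsig)
```

## The question and the model

Homoploid hybrid speciation (HHS) is the origin of a new, reproductively
isolated lineage from hybridization between two parental lineages without
a change in chromosome number. The genomic fingerprint of HHS differs
from both incomplete lineage sorting (ILS) and introgression: the hybrid
lineage carries an admixed genome in *all* of its descendants, fixed
variants inherited from *both* parents, and (when selection acted on
parental alleles) genes whose selected haplotypes trace to one parent or
the other.

`hybridsig` implements a four-part test of this scenario for a system of
four lineages: two putative parents `C` and `O`, the candidate hybrid
`D`, and an outgroup `A`. The underlying history is a species network:
the tree `(((C,D),O),A)` with split times `t_h < t_co < t_root`
(coalescent units, measured from the present), plus a hybrid edge by
which `D` draws a fraction `gamma` of its ancestry from the `O`-side
ancestor and `1 - gamma` from the `C`-side ancestor. With `gamma = 0`
the network collapses to the tree.

The four parts are:

1. **Topology census with an ILS null** (`topology_census`,
   `minor_topology_binomial_test`, `ils_null_ratio_test`). Among rooted
   gene trees the two "minor" arrangements (`D`+`O` sister; `C`+`O`
   sister) are equally likely under ILS alone; an excess of one of them,
   and a minor-topology ratio far outside the ILS-only simulation null,
   indicate hybridization or introgression.
2. **Site-pattern tests** (`dstat`, `hybrid_invariant_test`). The
   population-level ABBA-BABA D statistic detects excess allele sharing
   between `D` and `O`; the linear site-pattern invariant additionally
   estimates `gamma` from the two discordant pattern excesses.
3. **Long-indel PIV/AV classification** (`piv_census`,
   `piv_signal_test`). Indels of 5 bp or more are treated as
   homoplasy-free markers. Among inter-group *fixed* long indels, a
   variant shared by exactly two ingroups to the exclusion of the
   outgroup state is phylogenetically informative (PIV); sharing that
   includes the outgroup state is ancestral variation (AV). Significant
   PIV signal in *both* the `C`+`D` and `O`+`D` sharing classes is the
   signature of a hybrid `D`.
4. **Positive-selection scan** (`psg_scan`). Per gene, a gene-vs-genome
   HKA contrast (polymorphism `S` versus divergence `K`), the count of
   fixed non-synonymous differences, and a haplotype-tree origin
   assignment identify positively selected genes in the hybrid lineage
   and assign each to the parent that contributed the selected allele;
   genes passing the first two criteria under *both* groupings are
   hybrid-recombination candidates.

A coalescent simulator with a hybrid edge (`simulate_gene_trees`,
`simulate_variants`, `simulate_gene_alignments`) generates all the data
these stages consume, so every statistical property of the pipeline can
be exercised and calibrated at desk scale.

## The simulator

`simulate_gene_trees` draws independent gene trees from the structured
coalescent on the network: lineages coalesce within their population at
rate `choose(k, 2) / ne`; at `t_h` each remaining `D` lineage is routed
to the `O`-side ancestor with probability `gamma` (independently per
locus - admixture semantics; with one `D` lineage per locus this
coincides with routing the whole locus). `simulate_variants` drops
infinite-sites mutations on the branches as a Poisson process with rate
`theta` per unit branch length; each mutation becomes a biallelic SNP or
indel, with the ancestral allele defined by the outgroup side and
diploid genotypes formed by pairing the two haplotypes of an individual.
Markers are anchored on eight synthetic chromosomes (10 Mb each), with
the markers of one locus confined to a 10 kb span around the locus
anchor, so genomic marker order reflects genealogical linkage.

Default parameters, chosen once as a realistic emulation of an old,
well-differentiated system: `t_h = 4`, `t_co = 5`, `t_root = 8`
coalescent units and `gamma = 0.11` (the published minor-parent
estimate). Tip branches several coalescent units long mean that
within-lineage variation mostly fixes before the splits, as expected for
long-diverged genera; the internal branch `T = t_co - t_h = 1` produces
substantial but not overwhelming ILS (a third of gene trees are
discordant). The sampling default is 44 diploid individuals (16 `C`,
12 `D`, 12 `O`, 4 `A`); desk-scale analyses in the tests use 2-4
individuals per group, which the calibration results below refer to.

What the generator deliberately does *not* emulate: recombination within
a locus, sequencing error and missing genotypes, recurrent mutation
(infinite sites is assumed, which is also the premise of treating long
indels as homoplasy-free), selection outside the planted genes, and
calendar-time calibration (only the ordering of the split times
matters). Passing tests therefore demonstrate the statistical behaviour
of the methods under the model they assume, not robustness to artefacts
real data may carry.

## Numerical and design choices

**Topology census.** Trees are rooted on the outgroup edge; each ingroup
must be monophyletic after pruning `A`, otherwise the tree is discarded
(conservative; no majority vote). Support values, when present, are read
off the *input* tree at the sister-pair split, and trees below the
support threshold (default 50) are discarded and excluded from all
denominators. The minor-topology asymmetry test is the exact two-tailed
binomial (sum of outcome probabilities no larger than the observed
outcome's). The ILS null simulates the ratio `N_III / N_II`; its
internal branch is calibrated by inverting the closed-form concordance
probability `P(I) = 1 - (2/3) e^{-T}` at the observed topology-I
fraction. With one sampled lineage per group the null topology counts
are exactly multinomial in the closed-form probabilities, so the
`multinomial` engine draws them directly; the `trees` engine runs the
full simulate-and-classify loop. Both the empirical two-sided p (the
headline number) and a one-sample t test of the replicate ratios are
reported - the t test is kept for comparability but a ratio distribution
need not be anywhere near normal, so the empirical p is preferred.

**Block jackknife and the t reference.** Both site-pattern tests
estimate their standard error by a delete-one block jackknife over
contiguous blocks of 500 markers. P values use the t distribution with
`B - 1` degrees of freedom (`B` = blocks) rather than the normal: a
20,000-marker run has only 40 blocks, and treating the jackknife Z as
standard normal is anticonservative at that block count (about 8%
rejections at a nominal 5% in our calibration runs, against about 5%
under the t reference; the jackknife SE itself is unbiased - its ratio
to the empirical SD of D across replicates is 1.00). With hundreds of
blocks the two references coincide. The calibration simulations spread
their ~20,000 markers over 2,200 loci so that each block averages over
~55 independent genealogies (a short trailing block is folded into its
neighbour); heavy within-block linkage would otherwise break the
jackknife's independence assumption, and even moderate linkage leaves
the ratio statistic's block sums non-Gaussian enough to inflate
rejections by a percentage point.

**PIV/AV machinery.** "Fixed within a group" requires every called
genotype homozygous for the same allele *and* a call rate of at least
0.7 - small per-group samples need a completeness floor. Indel sharing
means the same biallelic marker, i.e. the identical ALT sequence at the
same position, the strictest homoplasy protection. The signal test
contrasts each focal class against `C`-`O` sharing (`[CD, CDA]` vs
`[CO, COA]`, and `[OD, ODA]` vs `[CO, COA]`) because `C` and `O` can
never be sisters under any placement of `D`, making their sharing the
natural ILS-plus-noise reference; the test is the Pearson chi-square
with Yates continuity correction (floored at zero). The chi-square
treats indels as independent, so its calibration holds when fixed
indels come from many loci; tightly linked indel clusters inflate it,
which is why the calibration suite simulates about one indel per locus
(3,400 loci for ~5,900 fixed indels per replicate).

**Admixture proportion.** With outgroup-polarized derived-allele
frequencies and quartet `(A, C, D, O)`, the three discordant
frequency-weighted pattern sums satisfy, under the network,
`E[f_ABBA - f_ABAB] = (1 - gamma) c` and
`E[f_AABB - f_ABAB] = gamma c` with a common constant `c` (both parental
populations are available to a `D` lineage over the same interval
`[t_h, t_co]`), so
`gamma = (f_AABB - f_ABAB) / ((f_ABBA - f_ABAB) + (f_AABB - f_ABAB))`
is estimated by plugging in the observed sums. The estimate is reported
clamped to `[0, 1]` with the raw value retained; a degenerate
denominator yields an undefined estimate while the Z statistic is still
reported.

**PSG scan.** The HKA test is realized in its operational gene-vs-genome
form: a 1-df chi-square on `[[S_gene, K_gene], [S_rest, K_rest]]`, with
genome totals summed over all genes tested (the focal gene is subtracted
in the second row); the classical multi-locus HKA likelihood is out of
scope. Haplotypes are taken as given (the simulator emits phased
haplotypes; unphased data would need external phasing). Origin
assignment builds a neighbour-joining tree on unique protein haplotypes
under p-distance - a deterministic, dependency-light stand-in for
per-gene ML trees - and assigns each `D` haplotype copy to the parent
with the nearer haplotype in patristic distance; a parent holding at
least 80% of copies is called the origin. Ties at the top-2.5%
non-synonymous cutoff are all included. The planted-signal generator
emulates what the scan is designed to detect: a completed sweep (the
hybrid+donor side collapses to one haplotype) plus `n_fix` fixed
non-synonymous differences; neutral genes carry only coalescent
variation.

## Calibration and problem sizes

The acceptance suite (and `scripts/acceptance.R`) validates, at sizes
chosen to keep a full run within minutes on one core:

- the closed-form MSC concordance probability at `T = 1` over 10,000
  loci (3 Monte-Carlo SEs);
- type-I calibration of `dstat` and `hybrid_invariant_test` over 500
  ILS-only replicates of ~20,000 markers (observed within 3-7%), and of
  the PIV OD-verdict over 200 replicates averaging >5,000 fixed long
  indels (within 2-8%);
- recovery of `gamma = 0.3` within 0.05 at ~50,000 markers, and strict
  monotonicity of the mean estimate over `gamma` in {0, 0.1, 0.25, 0.5};
- the qualitative hybrid-origin pattern under `gamma = 0.11` at ~100,000
  long-indel markers (positive D with Z > 3, `gamma`-hat within 0.05 of 0.11,
  CD > 1.5 OD > CO sharing counts, both PIV verdicts significant) in
  >80% of replicates;
- exact agreement of the sharing classifier with its 16-pattern truth
  table and of the binomial test with full enumeration for all n <= 20;
- recovery, against the planting record as oracle, of at least 13 of 15
  planted origin-`C` and 8 of 10 planted origin-`O` selected genes among
  1,000 in at least 90% of 50 runs.  The scan's full output lists are
  reported alongside: the top-2.5% criterion mechanically admits a fixed
  number of genes per grouping, so some neutral genes with extreme
  coalescent histories always accompany the planted ones (high fixed
  counts and small gene-vs-genome HKA p values are intrinsically
  correlated, and lineage-specific divergence can pull the hybrid's
  haplotypes toward the other parent in distance).  This is a property
  of the operational three-criterion pipeline itself, not of the
  simulator; candidate lists from it should be read as enriched, not
  pure.

## Known limitations

- The frequency-based hybrid test is an invariant estimator, not the
  published tool's exact internal statistic; it is validated here by
  parameter recovery rather than software concordance.
- The 2x2 construction of the PIV signal test is a reconstruction: the
  reference analysis names the test and the verdicts but not the table.
- Origin assignment uses NJ on p-distances, not ML trees.
- The binomial convention: for two-tailed p values the package sums all
  outcomes no more probable than the observed one; published values
  computed under other conventions (or other inputs) will differ.
- All calibration statements hold under the simulator's assumptions
  (no recombination within loci, no genotyping error, free indels);
  real data violating them - especially tightly linked indel clusters -
  will need block sizes or marker thinning chosen accordingly.
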