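---
title: "Detecting ghost ancestry with ancestry-specific IBD and quartet concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ghost ancestry with ancestry-specific IBD and quartet concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghostibd)
```

## The problem

Admixed human populations can carry genetic material from source
populations that no longer exist in unadmixed form and were never sampled —
"ghost" ancestries. A motivating case is the deeply divergent
autochthonous ancestry carried by small peripatetic communities of the
Namib region of southwestern Africa, detectable only *through* the admixed
genomes of its present-day carriers. `ghostibd` implements the statistical
machinery needed to find and characterise such a component:

1. **Ancestry-specific IBD (asIBD)** — decompose identity-by-descent
   segments by local ancestry, so that sharing can be attributed to one
   ancestral stratum at a time.
2. **Quartet genealogical concordance** — topology tests and divergence
   times for the masked ancestry relative to reference lineages.
3. **Admixture History Graph (AHG) ordering** — which two of three
   ancestries met first, from covariances of ancestry ratios.
4. **Masking and profile utilities** — ancestry masking with missingness
   filters, ancestry-specific pairwise differences with correlation-distance
   clustering, and total variation distances between chromosome-painting
   copy profiles.
5. **A synthetic cohort generator** with full ground truth, so every stage
   is testable without any external data.

## Ancestry-specific IBD

IBD/HBD segments (refinedIBD 9-column dialect) are consumed, never called.
Two post-processing paths exist on purpose:

* **Merged blocks** (`merge_ibd_blocks`) feed group-level sharing totals
  (`group_ibd_summaries`). Blocks of one haploid pair separated by a gap
  below 0.6 cM are merged transitively; when genotypes are supplied, a merge
  is vetoed if more than one discordant genotype lies in the combined
  region.
* **Raw blocks** feed the ancestry decomposition
  (`decompose_ibd_ancestry`): merging would lose the haplotype of origin
  that the local-ancestry overlay needs.

For a segment shared by haplotypes $a$ and $b$, the segment interval is
partitioned at the local-ancestry window boundaries. Sub-intervals where
both calls are defined and agree contribute their genetic length to that
ancestry; defined-but-different sub-intervals accumulate as *inconsistent*;
sub-intervals with an undefined call on either haplotype accumulate as
*undefined*. The three masses always sum to the segment's genetic length
(asserted to $10^{-6}$ cM throughout the test suite). A block is excluded
when its inconsistent fraction of the *defined* length exceeds 25% —
strictly: exactly 25% is kept, because the rule is "more than". Undefined
mass is excluded from both numerator and denominator of that fraction;
penalising masked windows as "inconsistent" would conflate missingness with
error.

Kept blocks are classed by total genetic length into half-open bins
$[1,5)$, $[5,10)$, $[10,\infty)$ cM (a 5.0 cM block falls in the middle
class; blocks under 1 cM are dropped and counted). Aggregation divides
per-ancestry sums by the number of haploid-genome pairs implied by the
metadata roster, *including* zero-sharing pairs, so that the reported
quantity is a mean over pairs rather than over observed blocks.
Within-population pairs are unordered haploid pairs excluding self-pairs,
which counts HBD (the two haplotypes of one individual) as within-group
sharing. Pooled proportions (`pool_sharing`) weight each population's mean
by its pair count, and `upgma_tree` summarises the Euclidean distances
between pooled profiles with average-linkage agglomeration (via
`stats::hclust` and `ape`).

All genetic lengths are recomputed from the genetic map; the cM column of
segment files is advisory (a deviation above 0.1 cM triggers a warning).
Physical coordinates are 1-based and closed, matching the consumed tool
dialects; positions beyond the map clamp to the terminal genetic position
rather than extrapolating recombination that was never observed.

## Quartet concordance and divergence times

For a quartet (outgroup, $P_1$; $P_2$, $P_3$) one allele is sampled per
population per site. AABB sites (the sampled $P_1$ allele siding with the
outgroup) support the topology placing $P_1$ external to $(P_2, P_3)$;
ABBA/ABAB sites are discordant. The support statistic is

$$C = \frac{N_{conc} - N_{disc1}}{N_{conc} + N_{disc1}},$$

where $N_{disc1}$ is the **more frequent** discordant class. Standard
errors come from a delete-one block jackknife over 50 contiguous blocks
holding equal numbers of informative sites (remainder sites go one per
block to the leading blocks):

$$SE_{jack} = \sqrt{\tfrac{n-1}{n} \sum_i (C_i - \bar C)^2}, \qquad
Z = C / SE_{jack}.$$

The discordant class is re-identified inside every delete-one replicate,
i.e. each $C_i$ is the full statistic of the reduced data. A zero SE with
non-zero $C$ is reported as an infinite $Z$ with a warning rather than an
error, since it legitimately arises from perfectly balanced blocks.

Sites enter these tests only if, within every population involved, they are
polymorphic, have minor allele frequency strictly above 10% and carry
strictly more than 10 nonmissing alleles; populations are first randomly
downsampled to a mean of 10–12 nonmissing alleles per site so that
polymorphism discovery is comparable across panels.

Divergence times between two populations use two in-group alleles and one
out-group allele per site (the chimpanzee allele polarises and gates
usability). With $P_{conc}$ the fraction of informative sites where the two
in-group alleles agree against the out-group, the internode time is

$$\hat T = -\log\!\left(\frac{3 - 3 P_{conc}}{2}\right)$$

in coalescent units, floored at 0 for $P_{conc} \le 1/3$ (the star-tree
point) rather than returning negative or complex values. The 95% CI is the
binomial profile likelihood of $P_{conc}$ propagated through the same
inversion; the elaborate maximum-likelihood machinery of the original
framework is deliberately not reproduced. Chronological dates use
$years = \hat T \times 2 N_e \times g$ with $g = 29$ years; the $2N_e$
diploid convention is a documented choice — the alternative ($N_e$
generations per coalescent unit) can be obtained by halving.

## AHG ordering

If ancestries $A$ and $B$ admixed before $C$ arrived, the ratio $A/B$
varies across individuals independently of $C$, while both other ratios
covary with their complementary ancestry. `ahg_order` computes the three
sample covariances (n−1 denominator) and picks the configuration with the
smallest absolute value. Individuals with a zero denominator ancestry are
excluded per configuration, not globally, which maximises usable data. A
margin below $10^{-12}$ between the two smallest absolute covariances is
returned as an explicit *unresolved* flag — identical proportions across
individuals are a real input (fully drifted or recently founded groups) and
must not produce an arbitrary winner.

## Masking and profiles

`mask_by_ancestry` keeps an allele only where the covering local-ancestry
window calls the target ancestry with posterior at or above the threshold
(default 1, i.e. only unambiguous assignments survive). Missingness
cutoffs downstream are strict inequalities matching their "less than"
phrasing: a haploid genome exactly at the core cutoff is projectable, not
core. Each haploid genome is an independent unit throughout — masking is
haplotype-specific, so treating diploids as units would mix ancestries
back together.

Ancestry-specific pairwise differences are the mean absolute allele
difference over co-observed sites, with a 100-site floor below which the
entry is flagged undefined (variance control; the statistic is otherwise
dominated by noise). Clustering uses the `as.dist(1 - cor(x))` idiom with
complete linkage. Copy-profile comparisons use the total variation
distance $TVD = \frac{1}{2}\sum_i |p_i - q_i|$ on row-normalised
chunk-count profiles, and donor-wise contrasts against a baseline
recipient on the unnormalised counts.

## The synthetic generator

The generator emulates the structure of a Human-Origins-style SNP array
cohort at desk scale (22 pseudo-chromosomes totalling 30 Morgans at 1
cM/Mb, 10–50k sites; defaults 12,000 sites, 8 diploids per population):

* **Frequencies** follow the Balding–Nichols model: per site a base
  frequency $p \sim U(0.05, 0.95)$, per ancestry a
  $\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ draw with drift $F$ (variance
  $F\,p(1-p)$), clamped away from 0/1 by $10^{-4}$ so MAF filters stay
  meaningful. Reference-like strata use $F = 0.05$; the ghost stratum uses
  $F = 0.35$ to stand for deep divergence.
* **Tracts**: ancestry along each haploid genome switches at Poisson rate
  $g$ per Morgan ($g$ = generations since admixture, default 25 — the
  value assumed for the local-ancestry inference being emulated), each
  switch redrawing from the individual's proportions, self-transitions
  allowed. This makes the stationary ancestry law *exactly* the target
  proportions and the recorded inter-switch tracts exponential with mean
  $100/g$ cM simultaneously; a forced-switch chain would bias the
  stationary law for unequal proportions. Truth tracts are therefore
  recorded per inter-switch interval without merging same-ancestry
  neighbours.
* **Planted IBD** copies the source haplotype's alleles and ancestry
  tracts onto the target over a random interval of the requested genetic
  length, so the pair is exactly identical there. Placements are
  rejection-sampled so a later plant never overwrites a haplotype inside an
  earlier planted segment. In the bundled ghost scenario, within-group
  segments descend from the full ancestry mosaic while cross-group segments
  are sourced from the non-carrier member — ghost-ancestry IBD is private
  to the carrier group, as it must be for ancestry inherited from an
  unsampled source.
* **Quartet sites** are drawn directly from the multispecies-coalescent
  law $P_{conc} = 1 - \frac{2}{3}e^{-t}$, discordant mass split equally
  between ABBA and ABAB by coalescent symmetry.
* **Two-pulse proportions** hold the first-pair ratio constant up to
  log-normal noise (`spread` = sd of the log ratio) while the third
  component varies uniformly on $[0.05, 0.5]$ — wide enough that the
  covarying configurations are clearly non-zero at realistic sample sizes.

What the generator does **not** emulate: linkage disequilibrium within
ancestral strata, genotyping error, phase-switch error, local-ancestry
miscalls (truth posteriors are 1), mutation since admixture inside planted
segments, and coalescent-realistic IBD length/age joint distributions.
Passing tests therefore validate the *interval algebra, estimators and
decision rules*, not robustness to upstream inference error; with truth
local ancestry the inconsistency filter should and does fire at exactly
zero.

## Numerical and design choices

* Per-site allele sampling in the concordance tests is vectorised from a
  single seeded uniform stream (one draw per site and population), so
  results are reproducible and independent of iteration order.
* Length-class edges are half-open at the left; exclusion and missingness
  thresholds are strict, as documented above; ties in the AHG test are
  unresolved, never broken arbitrarily.
* The rank-sum comparison of group IBD means uses the exact two-sided
  distribution up to a combined n of 20 and the normal approximation with
  continuity correction beyond.
* Standard components ride on established packages: VCF parsing via
  `vcfR`, trees via `stats::hclust` + `ape`, rank-sum via
  `stats::wilcox.test`. VCF output is written as plain text so that
  artifacts remain diffable and round-trippable.
* Pipeline runs (`run_pipeline`) refuse to start unless every stochastic
  stage has an explicit seed, and write a manifest of per-stage outputs
  with checksums; reruns with the same config are byte-identical.

Test problem sizes are chosen to keep the full suite in the low minutes on
one core while leaving no estimator under-sampled: 1,000 random instances
for the decomposition oracle, a 20,000-site / 100-haplotype cohort for
truth recovery, five seeds for the end-to-end ghost signature, and 100
replicates for estimator-consistency and recovery-rate checks.

## Known limitations

* Divergence CIs are binomial profile likelihoods; they ignore linkage
  between sites (the concordance topology test, by contrast, uses the
  block jackknife precisely to absorb linkage).
* The AHG result records only the inferred order; dating the pulses is out
  of scope.
* `decompose_ibd_ancestry` assumes both haplotypes share one window grid
  (true of the consumed msp dialect and of the generator's truth output).
* Copy profiles are consumed, not computed: chromosome painting itself is
  out of scope.
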