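---
title: "LD decay, persistence of LD phase and haplotype blocks: methods"
author: "ldphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LD decay, persistence of LD phase and haplotype blocks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package computes

`ldphase` characterises linkage disequilibrium (LD) in a diploid SNP panel
from phased haplotypes, the way population-level LD maps for livestock are
usually built. Four quantities are central:

* **Two-locus LD.** For markers $i < j$ with alternate-allele frequencies
  $p_i$, $p_j$ and two-marker haplotype frequency $p_{ij}$, the
  disequilibrium coefficient is $D = p_{ij} - p_i p_j$ and

  $$r^2 = \frac{(p_{ij} - p_i p_j)^2}{p_i(1 - p_i)\,p_j(1 - p_j)},$$

  the squared correlation of the allele indicators, in $[0, 1]$.
  $D' = |D| / D_{\max}$ normalises $D$ by its frequency-constrained
  maximum: $D_{\max} = \min\{p_i(1-p_j),\,(1-p_i)p_j\}$ when $D > 0$ and
  $\min\{p_i p_j,\,(1-p_i)(1-p_j)\}$ otherwise. *Signed r* is
  $\sqrt{r^2}$ carrying the sign of $D$; it is comparable across
  populations only under one fixed allele orientation.

* **LD decay.** Pairs within 500 kb (the cap beyond which pairwise
  $r^2$ is low and enumeration becomes wasteful) are binned by physical
  distance — 2.5-kb bins to 10 kb, 10-kb bins to 100 kb, 100-kb bins to
  500 kb — and each bin is summarised by its pair count, mean, sample SD
  and exact median of $r^2$. Bins are half-open $[low, high)$ with the
  final bin closed at the cap, so every distance maps to exactly one bin;
  the SD uses the $n-1$ denominator and the median averages the two
  central values for even counts (the usual presentation leaves all three
  conventions implicit; these are the package's fixed choices).

* **Persistence of LD phase (PL).** For two genetic groups genotyped at
  shared markers, PL in a distance bin is the product-moment correlation
  of signed r between the groups over the shared pairs in the bin. High
  PL means marker–QTL phase transfers across the groups, the condition
  for pooling them in genomic evaluation. The correlation is
  **uncentered** by default, $\sum x y / \sqrt{\sum x^2 \sum y^2}$:
  flipping the (arbitrary) reference allele of a marker negates signed r
  for that marker's pairs in *both* groups, and the uncentered form is
  exactly invariant under such joint flips, while a centered Pearson
  correlation shifts slightly because the bin means move. Within a bin,
  signed r is symmetric around zero genome-wide, so the two forms agree
  closely at scale; `persistence_profile(center = TRUE)` gives the
  strictly centered variant for comparison with reports that use it.
  Only pairs present in both groups enter (inner join), and the join is
  refused outright if the two groups' allele orientations disagree at any
  shared marker — signs would be meaningless.

* **Haplotype blocks.** The Gabriel confidence-interval definition (the
  Haploview default): a pair is in *strong LD* when the 90% likelihood
  bounds on $D'$ satisfy lower $\ge 0.70$ and upper $\ge 0.98$, and shows
  *strong historical recombination* when the upper bound is $< 0.90$. An
  interval of markers is a candidate block when its endpoint pair is in
  strong LD and at least 95% of the informative pairs inside it are in
  strong LD (uninformative pairs count in neither numerator nor
  denominator). Overlaps are resolved greedily — longest span in bp
  first, ties to more markers, then leftmost — and blocks of fewer than
  three markers are discarded, two-SNP blocks being prone to spurious
  formation. Haploview's undocumented refinements (marker-count-dependent
  fraction tweaks, short-span pair skipping) are deliberately not
  reproduced; the clean published definition is what the code implements
  and what the exhaustive-oracle tests pin down.

The $D'$ confidence bounds are computed by scanning a uniform grid of 101
$D'$ values in $[0, 1]$ (marginal frequencies held at their observed
values, sign of $D$ fixed at its observed sign), evaluating the
multinomial likelihood of the observed gametic counts at each grid point,
normalising to a discrete posterior under a flat prior, and reading off
the central 90% interval. Grid resolution, prior and mass are exposed as
parameters because the block literature fixes none of them numerically;
the defaults are the package's choice and the classification thresholds
are parameters of `gabriel_params()` so sensitivity can be examined.

## Input, phase and quality control

LD is computed by direct gamete counting on phased haplotypes ("paternal
and maternal haplotypes"), with pairwise-complete deletion of missing
entries; pairs with a monomorphic margin are skipped, never zero-filled,
because $r^2$ is undefined there. Phased VCF (`|` separators) is the
native input; PLINK PED/MAP text loads as unphased and a per-pair EM over
the double-heterozygote ambiguity (`em_haplotype_freqs()`) is provided so
unphased genotype tables remain usable. The EM restarts from linkage
equilibrium, near-coupling and near-repulsion states and keeps the best
likelihood, because the profiled likelihood in the one free haplotype
frequency can be bimodal and a single start can converge to the minor
mode. Population-scale phasing itself (BEAGLE-style) is out of scope:
the package consumes phased input or simulates it.

Quality control mirrors standard SNP-array practice: samples with call
rate < 0.90 are removed first; then, on the surviving samples, SNPs are
filtered in the fixed order call rate < 0.90, exact Hardy–Weinberg test
p < 1e-4, minor allele frequency < 0.05, each SNP attributed to the first
filter it fails so reports are deterministic. The HWE test is the exact
conditional test on collapsed genotypes — two-sided, no mid-p — summing
the probabilities of all heterozygote counts no more probable than the
observed one; it is applied per group for group-specific panels and on
the pooled samples for the joint panel (both modes are available, since
practice varies). Note the exact test is conservative: its realised
rejection rate sits at or below the nominal level, which is what the
calibration test asserts.

## The synthetic two-group generator

No public genotypes accompany the analyses this package targets, so the
generator produces panels with the statistical structure the pipeline
assumes: a composite breed formed from two diverged founder populations
in 5/8 : 3/8 proportions and then split into two genetic groups.

The machinery is a discrete Wright–Fisher simulation with recombination.
All variation is standing founder polymorphism: marker alleles are
assigned by the infinite-sites rule on a random coalescent genealogy of
the starting haplotypes (each marker's derived allele is a clade, drawn
with probability proportional to branch length), so every marker is
biallelic and, in the zero-recombination limit, no pair can ever show
four gametic types — which is exactly why that limit must yield a single
block. Mutations are placed only on branches subtending 5–95% of
haplotypes, emulating a common-SNP genotyping array; markers fixed in
the sampled output are dropped and the survivors subsampled to the
requested count (`oversample` controls the simulation margin — with
standing variation only, drift fixes a large share of markers over the
simulated history).

Default history, chosen once for qualitative realism at desk scale:
founder effective size $N_e = 100$ per population, burn-in $4 N_e$
generations to approximate drift–recombination equilibrium, 80
generations of founder divergence (differentiation comparable to related
cattle breed pairs at this $N_e$), admixture in 5/8 : 3/8 proportions, 12
generations of breeding inter se (a composite formed mid-20th century),
8 generations of independent drift between the two output groups, 100
diploids sampled per group, 2,000 markers over 5 Mb. The recombination
rate defaults to $10^{-7}$ per bp per generation so that $4 N_e c$ spans
roughly 0.1 at 2.5 kb to 20 at 500 kb — the range over which mean $r^2$
falls from near its small-sample ceiling to below 0.1, matching the
qualitative shape of high-density cattle LD maps. Optional hotspots
multiply the rate inside windows (default width 25 kb), which at 50×
makes a window an effective recombination barrier at this $N_e$.

What the generator does *not* emulate: genotyping error, pedigree
structure within groups, selection, sex chromosomes, recurrent mutation,
and the very large ancestral effective sizes of real cattle. Consequently
absolute levels of $r^2$ at short range are higher than field studies
report (small $N_e$ and $n$ inflate the $r^2$ floor), and passing
structural tests demonstrates correctness of the statistics and the
pipeline's behaviour on data with realistic LD *shape* — not numerical
agreement with any particular breed.

## Numerical and design choices

* Positions are 1-based internally (VCF convention); BED output converts
  to 0-based half-open at the boundary. Sex chromosomes, markers without
  positions and duplicate positions (first kept) are dropped at load.
* Allele orientation comes from VCF REF/ALT; for PED the first-observed
  allele is the reference unless an explicit allele table is supplied.
  Every LD table carries an orientation digest so cross-group signed-r
  comparisons cannot silently mix orientations.
* Pair enumeration is a sliding window over position-sorted markers —
  linear in emitted pairs; gamete counting is vectorised by lag.
  Candidate-block counting uses 2D prefix sums over the classified-pair
  matrices, so each candidate interval is evaluated in O(1) after an
  O(M²) setup; per-chromosome marker counts in the low thousands use a
  few tens of MB. Exact bin medians require keeping per-bin $r^2$
  values; the pair dump is optional output for the same reason.
* The EM convergence tolerance is 1e-10 on the frequencies with a
  1,000-iteration cap; D' grids use 101 points; a distance equal to a bin
  boundary falls in the upper bin; a distance equal to the 500-kb cap is
  kept (closed last bin).
* Degenerate inputs: empty bins report `NA` summaries (SD already at a
  single pair); bins with fewer than three shared pairs or a zero-variance
  margin report undefined PL; chromosomes with no blocks summarise to
  zeros; an all-missing marker has undefined MAF and is removed by QC.
* Problem sizes in the shipped tests — 2,000 markers / 5 Mb for the
  decay and persistence checks, 1,500 markers for the equilibrium (Sved)
  check, a few hundred markers for structural block tests — are the
  package's chosen desk-scale study conditions: large enough for every
  distance bin to be populated, small enough to run in minutes.

## Verification strategy

Each statistic is checked against an independent route: gamete counting
against correlation of allele indicator vectors; the exact HWE p-value
against full enumeration over all tables up to 50 genotypes; EM
likelihoods against a dense grid search over the one free haplotype
frequency; D' intervals against a scalar transcription of the grid
likelihood; candidate blocks against an exhaustive interval checker; bin
summaries against flat recomputation. Structural expectations — decay of
$r^2$ and PL with distance, a single block under zero recombination, no
block across a strong hotspot, equilibrium $r^2$ within ±50% of Sved's
$1/(1 + 4 N_e c)$ in the bins where $1 \lesssim 4 N_e c \lesssim 15$
(outside that range the approximation itself degrades) — are asserted on
the generator's default conditions with fixed seeds.

## Known limitations

* $D'$ intervals are posterior-grid intervals under a flat prior, one
  defensible reconstruction of the confidence bounds the block
  literature describes loosely; other reconstructions shift borderline
  pair classifications.
* The greedy overlap resolution is deterministic but not guaranteed to
  maximise coverage; Haploview's own resolution differs in undocumented
  ways.
* PL between groups of very different sizes inherits the noisier group's
  sampling error; the package reports shared-pair counts per bin so that
  uncertainty is visible.
* The forward simulator's chromosomes are single continuous segments; it
  does not model varying marker density along real assemblies beyond
  uniform placement.
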