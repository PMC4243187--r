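# ldphase

Population-level linkage-disequilibrium (LD) analysis of phased SNP
panels, written for the kind of question a livestock geneticist asks of a
high-density genotyping array: how fast does LD decay with physical
distance, does marker–QTL phase transfer between two genetic groups of a
composite breed, and how does the genome partition into haplotype blocks?

The package covers the full pipeline:

* **Quality control** — sample call rate, SNP call rate, exact
  Hardy–Weinberg test (two-sided conditional test, no mid-p), minor
  allele frequency, applied in a fixed order with per-filter attribution
  (`apply_qc()`).
* **Two-locus LD from phased haplotypes** — for markers *i*, *j* with
  allele frequencies *p_i*, *p_j* and haplotype frequency *p_ij*:
  `D = p_ij − p_i p_j`,
  `r² = D² / (p_i (1 − p_i) p_j (1 − p_j))`,
  `D′ = |D| / D_max`, and *signed r* = √r² carrying the sign of D
  (`pair_ld()`, `ld_pair_table()`), plus likelihood-grid confidence
  bounds on D′ (`dprime_ci()`) and a multi-start EM fallback for
  unphased genotype tables (`em_haplotype_freqs()`).
* **LD-decay profiles** — pairs within 500 kb binned by distance
  (2.5-kb bins to 10 kb, 10-kb bins to 100 kb, 100-kb bins to 500 kb)
  and summarised by pair count, mean, SD and median r² per group
  (`build_decay_profile()`).
* **Persistence of LD phase (PL)** — per-bin product-moment correlation
  of signed r between two groups over shared pairs
  (`persistence_profile()`); uncentered by default so the statistic is
  exactly invariant to the arbitrary per-marker choice of reference
  allele (see the methods vignette).
* **Haplotype blocks** — the Gabriel confidence-interval definition
  (strong-LD pair: D′ CI ≥ (0.70, 0.98); strong recombination: upper
  bound < 0.90; a block needs an endpoint pair in strong LD and ≥ 95%
  of informative internal pairs in strong LD), greedy overlap
  resolution, two-SNP blocks discarded, per-chromosome summaries
  (`find_blocks()`, `summarize_blocks()`).
* **Synthetic data** — a forward Wright–Fisher simulator of a composite
  population: two diverged founder breeds admixed 5/8 : 3/8, bred inter
  se, then split into two drifting groups (`sim_config()`,
  `simulate_panels()`), so the whole pipeline runs without any external
  genotypes.

Input: phased VCF plus a two-column sample→group TSV, or PLINK PED/MAP
text (unphased). Output: TSV tables, a BED of blocks, and a JSON run
manifest (`run_pipeline()`).

## Worked example

```r
library(ldphase)

# simulate the default composite-breed panel: 2,000 SNPs over 5 Mb,
# two groups ("CA", "MA") of 100 diploids each
panels <- simulate_panels(sim_config(seed = 1))

qa <- apply_qc(panels$CA)$panel     # 1,907 of 2,000 SNPs pass QC
qb <- apply_qc(panels$MA)$panel     # 1,927 pass

lda <- ld_pair_table(qa)            # 337,269 pairs within 500 kb
ldb <- ld_pair_table(qb)

prof <- build_decay_profile(lda, scope = "CA")
pp   <- persistence_profile(shared_pairs(lda, ldb))

head(prof[, c("bin_label", "n_pairs", "mean_r2", "median_r2")], 4)
#>   bin_label n_pairs   mean_r2 median_r2
#> 1     < 2.5   10750 0.9675539 1.0000000
#> 2   2.5 - 5    9511 0.9243104 1.0000000
#> 3   5 - 7.5    9080 0.8829320 1.0000000
#> 4  7.5 - 10    8221 0.8325818 1.0000000

pp$pl[c(1, 17)]                     # PL at "< 2.5" kb and at "400 - 500" kb
#> [1] 0.99908648 0.01007505
attr(pp, "overall_mean_pl")
#> [1] 0.8336973
```

Mean r² falls monotonically from 0.97 in the shortest bin to 0.05 at
400–500 kb, and the phase correlation between the two groups decays from
≈ 1 at short range (the groups split only a few generations ago, so
short-range phase is shared) towards 0 at 500 kb, where independent
drift has scrambled the weaker long-range associations. At this
simulation scale (Ne = 100, n = 100 per group) the absolute r² level is
higher than field studies report — the decay *shape* and the
cross-group phase structure are the reproducible content.

Blocks on the pooled panel:

```r
joint <- apply_qc(
  haplotype_panel(rbind(panels$CA$haplotypes, panels$MA$haplotypes),
                  panels$CA$markers,
                  c(panels$CA$sample_ids, panels$MA$sample_ids),
                  c(panels$CA$groups, panels$MA$groups)))$panel
blocks <- find_blocks(joint)
summarize_blocks(blocks, joint)[, c("n_blocks", "pct_snps_in_blocks",
                                    "mean_block_bp", "max_block_bp")]
#>   n_blocks pct_snps_in_blocks mean_block_bp max_block_bp
#> 1       28           99.78791      48452.39       203954
```

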