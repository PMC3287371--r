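# founderflow

Invasion genetics in R: who founded an introduced population, from
where, and — above all — **how many of them were there?**

When a population is established outside its native range, the founding
event leaves a genetic signature: allelic and haplotype richness drop,
the new population drifts away from its source, and (unless the founder
group was tiny) heterozygosity barely moves.  Given diploid
microsatellite genotypes from the introduced population and a panel of
candidate sources, plus aligned mtDNA haplotypes, founderflow runs the
standard analysis chain for that situation:

* **Diversity** — per-population summaries: proportion of polymorphic
  loci *P*, allele counts, observed/expected heterozygosity (Nei's
  unbiased estimator), rarefied allelic richness
  `A_R(g) = Σ_a [1 − C(N−N_a, g)/C(N, g)]` and rarefied private allelic
  richness at a standard sample of *g* gene copies; haplotype diversity
  *h* and nucleotide diversity *π* for the mtDNA.
* **Source assignment** — pairwise Weir–Cockerham θ (summed
  variance-component convention) with genotype-permutation tests;
  Cavalli-Sforza chord distances; a neighbor-joining tree with
  locus-bootstrap supports; and a ranked source table.
* **Nuclear founder number** — a maximum-likelihood estimate of the
  effective number of founders *N₀* under a founding-bottleneck +
  logistic-growth Wright–Fisher model: the founder gene pool is 2·N₀
  copies drawn from the source, followed by *t* generations of
  multinomial resampling along
  `N(g) = K·N₀·e^{rg} / (K + N₀(e^{rg} − 1))`.
  The per-locus likelihood of the observed introduced-sample counts is
  computed by an unbiased sequential Monte Carlo scheme (forced
  retention of observed alleles, guided founder draws, tempered
  lookahead resampling), maximized over a grid of *N₀* with 2-log-unit
  support limits, and swept over assumed (K, r) and candidate sources.
* **Mitochondrial founder number** — the probability that *N* founders
  drawn from a source haplotype pool carry exactly the *k* haplotypes
  observed in the introduced population, by 100,000-trial simulation
  cross-checked against the exact inclusion–exclusion formula
  `P(k|N) = Σ_{|S|=k} Σ_{T⊆S} (−1)^{k−|T|} (Σ_{i∈T} p_i)^N`.
* **Synthetic data** — a generator with planted ground truth
  (Balding–Nichols source divergence, a known founding event, clade-
  structured mtDNA pools) used throughout the test suite for
  recovery-based validation.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` for fitted objects, `autoplot()` for the likelihood surface,
the (K, r) sweep and the mitochondrial founder curve.

## Worked example

```r
library(founderflow)

ds <- sample_dataset(sim_scenario(), seed = 3)   # truth: SRC9 founded INTRO with N0 = 10

nuclear_diversity(ds$genotypes, g = 26)
#> # A tibble: 10 × 11   (columns abridged)
#>    pop       n     P     A_p   A_R     A    Ho    He
#>  1 SRC1     28     1 0.570    4.95  5.86 0.658 0.637
#>  2 SRC2     27     1 0.263    4.18  5    0.461 0.508
#>  ...
#>  9 SRC9     66     1 0.109    4.57  6.14 0.595 0.615
#> 10 INTRO    71     1 0.00139  3.58  3.86 0.594 0.552
```

The introduced population shows the classic bottleneck signature: the
lowest rarefied richness (3.58 vs 3.96–4.95) and essentially no private
alleles, but undiminished heterozygosity.

```r
assign_source(fst_matrix(ds$genotypes), "INTRO",
              mito_diff_matrix(ds$haplotypes))
#> # A tibble: 9 × 4
#>   source    fst mito_diff  rank
#> 1 SRC9   0.0255      3.40     1
#> 2 SRC8   0.278      26.3      2
#> 3 SRC1   0.280      26.7      3
#> ...
```

The true source is unambiguous: θ = 0.026 against ~0.28+ for every
other candidate, echoed by the mtDNA differences (3.4 vs ~26).

```r
founder_likelihood(ds$genotypes, "SRC9", "INTRO",
                   K = 2000, r = 1.5, t = 10, grid = 2:40, M = 1000, seed = 2)
#> <founder_fit> SRC9 -> INTRO | K = 2000, r = 1.5, t = 10, M = 1000
#>   MLE founder number: 10 (2-unit support 6-12)

src <- subset(ds$haplotypes$counts, pop == "SRC9")[c("haplotype", "count")]
mito_founder_estimate(src, k_observed = 4, trials = 1e5, seed = 3)
#> <mito_founder_fit> k_observed = 4, source haplotypes = 6, trials = 100000
#>   most likely (female-equivalent) founder number: 6 (2-unit support 4-16)
```

The nuclear estimate recovers the planted ten founders; the
mitochondrial estimate counts female-equivalent founders, ignores
post-founding drift, and is read as a lower bound.  `run_full_analysis()`
chains all stages (diversity → distances/tree → source ranking →
founder estimation for the top-ranked sources) from one `run_config()`
and `write_results()` emits CSV/Newick/JSON.

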