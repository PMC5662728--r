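# gsimix

Genetic stock identification (GSI) and mixture analysis for diploid
microsatellite baselines, aimed at studies of introduced or mixed-origin
salmonid populations: which source lineages founded a naturalized
population, in what proportions, and how much of the apparent signal could
be an artifact of admixture?

`gsimix` is for population geneticists and fishery scientists who assign
unknown-origin individuals against a hierarchical reference baseline
(populations nested in reporting groups).  It provides, as tidy
tibble-in/tibble-out functions:

* **Individual assignment** by the Rannala–Mountain conditional likelihood:
  per locus, the genotype probability in population *j* is the
  Dirichlet-multinomial posterior predictive under a symmetric Dirichlet
  prior with mass 1/k per allele class,

  P(aa | j) = (n_a + 1/k)(n_a + 1 + 1/k) / ((n+1)(n+2)),
  P(ab | j) = 2(n_a + 1/k)(n_b + 1/k) / ((n+1)(n+2)),

  multiplied over loci in log space; posteriors under equal population
  priors, aggregated to reporting groups, with a leave-one-out jackknife
  for self-assignment benchmarking.
* **Mixture-proportion estimation**: mean posterior and EM conditional
  maximum likelihood (π_u ← (1/M) Σ_i π_u L_iu / Σ_v π_v L_iv), with
  max-a-posteriori individual counts and a major-contributor report at a
  configurable threshold (default 10%).
* **Population-genetic summaries**: allele frequencies, unbiased expected
  heterozygosity H_S, rarefied allelic richness AR(g), Weir–Cockerham θ
  and f (ratio-of-sums over loci and alleles), pairwise F_ST, and
  seedable permutation tests for genic differentiation, heterozygote
  deficit and linkage disequilibrium, plus Bonferroni correction.
* **A mixed-origin founding simulation**: an ideal admixed population with
  allele frequencies intermediate between two baseline sources, sampled at
  Hardy–Weinberg equilibrium, assigned against the full baseline, and
  tabulated as true / sister / unrelated assignments with the share of
  high-confidence (P ≥ 0.8) unrelated assignments — alongside pure-origin
  control cohorts that benchmark ordinary misassignment.
* **A synthetic baseline generator** (Balding–Nichols Dirichlet hierarchy)
  with truth tables, so every stage is testable without access to any
  proprietary reference baseline.
* **I/O** in GENEPOP format (2- or 3-digit alleles, 0 = missing) plus
  TSV hierarchy/sister tables, and a `run_study()` orchestrator that writes
  a reproducible, seed-stamped artifact bundle.

## Worked example

Generate a 4-group baseline, a 150-fish mixture drawn 55/25/20 from
populations in three of the groups, and estimate its composition:

```r
library(gsimix)
library(dplyr)

b <- generate_baseline(baseline_spec(n_groups = 4, pops_per_group = 2,
  f_between = 0.06, f_within = 0.01, n_loci = 13, alleles_per_locus = 10,
  n_per_pop = 60, seed = 42))
mix <- generate_mixture(b$truth_freqs,
  setNames(c(0.55, 0.25, 0.20), unique(b$hierarchy$population)[c(1, 3, 5)]),
  n = 150, seed = 43)

post  <- assignment_posteriors(mix$geno, b$geno)
gpost <- aggregate_to_groups(post, b$hierarchy)
est   <- estimate_mixture(gpost, method = "em")
report_major_contributors(est, threshold = 0.10)
#> # A tibble: 4 × 4
#>   unit              pi n_map major
#>   <chr>          <dbl> <int> <lgl>
#> 1 Group01 0.583           88 TRUE 
#> 2 Group02 0.259           38 TRUE 
#> 3 Group03 0.158           24 TRUE 
#> 4 Group04 0.0000000284     0 FALSE
```

The EM estimate recovers the generating 55/25/20 split (within sampling
error of 150 fish); `n_map` counts the individuals allocated to each group
by maximum a posteriori, and `major` flags groups at or above the 10%
contribution threshold.  The baseline itself:

```r
glance(weir_cockerham(b$geno))
#> # A tibble: 1 × 5
#>    theta       f n_pops n_loci undefined
#>    <dbl>   <dbl>  <int>  <int> <lgl>    
#> 1 0.0633 0.00824      8     13 FALSE    

glance(self_assignment_confusion(b$geno, b$hierarchy, level = "group"))
#> # A tibble: 1 × 3
#>   accuracy     n level
#>      <dbl> <int> <chr>
#> 1    0.969   480 group
```

Multilocus θ of 0.063 reflects the generating between-group differentiation
(0.06), f is near zero as expected under Hardy–Weinberg sampling, and
leave-one-out self-assignment places 96.9% of baseline fish in their true
reporting group.  `run_founding_simulation()` then measures how fish from
an *admixed* population founded by two of these sources would assign —
including how often they land, sometimes with high confidence, in groups
unrelated to either source.  `autoplot()` methods are available for mixture
estimates, confusion matrices and founding reports.

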