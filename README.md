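# colonystruct

Population genetics for colony-structured (social-insect) microsatellite
surveys. In species such as subterranean termites, genetic variation is
organised hierarchically — among regional clusters, among colonies, among
individuals within colonies, and within individuals — and the colony
breeding system (one outbred royal pair, inbred neotenic lines, or several
unrelated reproductives) leaves a readable signature in worker genotypes.
`colonystruct` implements the complete analysis stack for such surveys and
a seeded colony-pedigree simulator to validate every stage end to end.

## What it computes

* **Data model & I/O** — long-tibble genotype tables (`gen_tbl`), GENEPOP
  reader/writer (2- and 3-digit dialects), colony metadata CSV, per-colony
  allele frequencies, mtDNA haplotype summaries.
* **Colony breeding systems** — `classify_colony()` labels colonies
  *simple* / *extended* / *mixed* via Mendelian parental-pair enumeration
  and a combined-locus G-test: more than four alleles at a locus proves more
  than two unrelated reproductives (mixed); no compatible single parental
  pair, or a G-test rejection at α = 0.05, indicates inbred neotenic
  breeding (extended).
* **Classical statistics** — observed and Nei unbiased expected
  heterozygosity; Weir–Cockerham F-statistics
  (F<sub>IS</sub>/F<sub>ST</sub>/F<sub>IT</sub> as ratios of summed variance
  components, permutation significance); exact/Monte-Carlo tests of
  heterozygote deficiency; genotypic LD scans with Bonferroni correction;
  hierarchical AMOVA (among colonies / among individuals within colonies /
  within individuals) on gene-copy mismatch distances with Φ-statistics.
* **Spatial structure** — Edwards' chord distance, Mantel tests, 2-D kernel
  density of the isolation-by-distance scatter, K-nearest-neighbour
  connection networks, Moran's I, and spatial PCA (eigenanalysis of the
  spatially lagged covariance, exact λ = var × Moran identity, global/local
  permutation tests, allele loadings).
* **Bayesian clustering** — an admixture-model Gibbs sampler (Rcpp) on
  one-worker-per-colony resamples, Evanno ΔK model selection across K, and
  label-switching-safe consensus assignments.
* **Pipeline** — `run_study()` sequences the whole workflow (20
  one-per-colony resamples, full-sample statistics, IBD, sPCA, clustering,
  per-cluster statistics, family classification) under one seed with a
  stage-fault-tolerant report.

The core quantities, in the field's notation: Weir–Cockerham
F<sub>IS</sub> = 1 − c/(b+c), F<sub>ST</sub> = a/(a+b+c) with a, b, c the
among-group / among-individual / within-individual components summed over
alleles and loci; Edwards' distance
D = √(1 − (1/L) Σ<sub>l</sub> Σ<sub>a</sub> √(p<sub>la</sub> q<sub>la</sub>));
sPCA eigenvalues λ<sub>i</sub> = var(s<sub>i</sub>) · I(s<sub>i</sub>);
Evanno ΔK = |mean L(K−1) − 2 mean L(K) + mean L(K+1)| / sd(L(K)).

## Worked example

```r
library(colonystruct)

sim <- sim_dataset(sim_config(seed = 7))     # 52 colonies x 10 workers x 6 loci
calls <- classify_dataset(sim$gt)
family_summary(calls)
#> # A tibble: 2 × 4
#>   group verdict      n proportion
#>   <chr> <chr>    <int>      <dbl>
#> 1 all   extended    18      0.346
#> 2 all   simple      34      0.654

glance(wc_fstats(sim$gt, group = "colony"))[, 1:3]
#> # A tibble: 1 × 3
#>      fis   fst   fit
#>    <dbl> <dbl> <dbl>
#> 1 -0.206 0.469 0.359

tidy(amova(sim$gt, n_perm = 99, seed = 1))[, c("level", "percent")]
#> # A tibble: 3 × 2
#>   level                             percent
#>   <chr>                               <dbl>
#> 1 among_colonies                       46.9
#> 2 among_individuals_within_colonies   -11.0
#> 3 within_individuals                   64.1

net <- knn_graph(sim$geo, k = 10)
x   <- freq_matrix(colony_allele_frequencies(sim$gt))[sim$geo$colony_id, ]
fit <- spca(x, net)
head(tidy(fit), 2)
#> # A tibble: 2 × 4
#>    axis lambda variance moran_i
#>   <int>  <dbl>    <dbl>   <dbl>
#> 1     1 0.232     0.308   0.754
#> 2     2 0.0198    0.169   0.117
```

Here the worker-level F<sub>IS</sub> within colonies is negative (workers
are sibs of few parents), F<sub>ST</sub> among colonies is high (colonies
are families), the AMOVA among-colony share reflects family structure plus
cluster divergence, and the first sPCA eigenvalue combines high score
variance with strong positive spatial autocorrelation — the north–south
cluster split. `autoplot(fit, sim$geo)` maps the scores;
`autoplot()` on a `gibbs_admixture()` fit draws the admixture barplot.

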