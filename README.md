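# pleiomap

Pleiotropy testing and phenotype maps from GWAS summary statistics.

`pleiomap` is for statistical geneticists who want to explore the shared
genetic basis (pleiotropy) of many phenotypes using nothing but publicly
released GWAS association p-values — no genotypes. Starting from an
M SNPs x K phenotypes p-value matrix it:

1. **tests pleiotropy for every phenotype pair.** For a pair, the p-value
   vectors are modeled as a four-group Beta-Uniform mixture over latent
   association states Z in {00, 10, 01, 11}: null p-values are Uniform(0,1),
   associated p-values are Beta(alpha_k, 1) with 0 < alpha_k < 1, and
   mixing proportions pi_00..pi_11 are estimated by EM. The null hypothesis
   of independent signals, `H0: pi11 = (pi10 + pi11)(pi01 + pi11)`, is
   tested by a likelihood ratio (the null likelihood factorizes exactly into
   two marginal two-group fits) referred to chi-squared with 1 df, giving a
   pleiotropy p-value `y_ij` per pair;
2. **draws a phenotype map.** The p-value matrix is turned into distances by
   a Box-Cox transform `s_ij = (y_ij^lambda - 1)/lambda` (log at
   `lambda = 0`; lambda is a zoom knob), min-max normalized to [0, 1], and
   embedded in 2-D by isomap: epsilon-neighborhood graph, Floyd-Warshall
   geodesics, classical MDS via the tau operator
   `tau(D) = -1/2 H (D o D) H`;
3. **clusters phenotypes** on the embedded coordinates (k-means or
   hierarchical); and
4. **explains the map at SNP level.** For a chosen pair, each SNP's local
   FDR `1 - Pr(Z_m11 = 1 | p_m1, p_m2)` is computed from the fitted
   posteriors and the largest set whose running-mean local FDR stays below a
   user global FDR level is reported.

A simulator with known latent association structure (scenario presets A-D:
20% associated SNPs per trait, designated pairs with 25%/75% extra overlap,
Beta(0.4, 1) signals) makes the whole pipeline testable offline.

## Worked example

```r
library(pleiomap)

# five phenotypes, 20% signal each, pairs (1,2) and (3,4) share 75% extra
# overlap, phenotype 5 independent; 20,000 SNPs
res <- simulate_gwas(scenario_preset("A", n_snps = 20000, seed = 1))

run <- run_pipeline(res, pipeline_config(
  lambda = 0, epsilon = "auto", n_clusters = 3,
  assoc_pairs = list(c(1, 2)), global_fdr = 0.05, seed = 1))

run$pleio
#> Pairwise pleiotropy tests: 5 phenotypes, 20000 SNPs
#>          GWAS_1   GWAS_2   GWAS_3   GWAS_4 GWAS_5
#> GWAS_1 1.00e+00 7.53e-52 8.52e-01 3.90e-01 0.9520
#> GWAS_2 7.53e-52 1.00e+00 5.30e-01 5.10e-01 0.1620
#> GWAS_3 8.52e-01 5.30e-01 1.00e+00 4.79e-57 0.0132
#> GWAS_4 3.90e-01 5.10e-01 4.79e-57 1.00e+00 0.3700
#> GWAS_5 9.52e-01 1.62e-01 1.32e-02 3.70e-01 1.0000

run$map
#> Phenotype map: 5 phenotypes in 2 dimensions (epsilon = 0.99, lambda = 0)
#>               dim1 dim2 cluster
#> GWAS_1  1.05243447    0       1
#> GWAS_2  0.96013227    0       1
#> GWAS_3 -0.99319109    0       2
#> GWAS_4 -0.99319109    0       2
#> GWAS_5 -0.02618456    0       3
```

The designed pairs are overwhelmingly significant (p ~ 1e-52 and 1e-57, vs
0.16-0.95 for chance-overlap pairs), the map separates the two shared pairs
from the independent control, and k = 3 clustering recovers exactly
{1,2}, {3,4}, {5}. The joint association table for the (GWAS_1, GWAS_2)
pair at global FDR 0.05:

```r
run$assoc[["GWAS_1:GWAS_2"]]
#> Joint association table: 112 SNP(s) at global FDR 0.05 (pattern "11")
#>       snp_id   local_fdr
#> 1  snp_13257 0.002112296
#> 2  snp_08889 0.002628831
#> 3  snp_17830 0.003459030
#> ...
```

Of those 112 SNPs, 95.5% are truly shared in the simulation's latent states
— the realized false discovery proportion (4.5%) respects the 5% target.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pleiomap.R", package = "pleiomap"))')
Rscript $CLI simulate --scenario A --n-snps 20000 --seed 1 --out-prefix sim
Rscript $CLI all --pmat sim_pvalues.tsv --n-clusters 3 --assoc-pairs 1,2 \
    --out-dir out --plot
```

Subcommands: `simulate`, `fit`, `map`, `assoc`, `all`. The exit code is
nonzero exactly when a stage fails.

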