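---
title: "Methods: pleiotropy testing and phenotype maps from GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pleiotropy testing and phenotype maps from GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Pleiotropy — a shared genetic basis between distinct phenotypes — is usually
assessed by intersecting lists of genome-wide-significant hits. That approach
discards most of the signal in polygenic traits, where thousands of variants
fall short of genome-wide significance individually but carry information
collectively. `pleiomap` instead models the *full* vectors of GWAS
association p-values for a pair of traits, estimates how much signal they
share, and turns the resulting pairwise evidence into a low-dimensional map
of the phenotypes. Only summary statistics (a SNP-by-phenotype p-value
matrix) are needed; no genotypes.

# The pairwise mixture model

For SNP $m$ and a pair of traits, let $p_{m1}, p_{m2}$ be the two association
p-values, and let a latent indicator $Z_m \in \{00, 10, 01, 11\}$ say which
traits the SNP is truly associated with. Emissions are products of
Beta/Uniform densities:

$$
\begin{aligned}
Z_m = 00 &: p_{m1} \sim U[0,1], \; p_{m2} \sim U[0,1] \\
Z_m = 10 &: p_{m1} \sim \mathrm{Beta}(\alpha_1, 1), \; p_{m2} \sim U[0,1] \\
Z_m = 01 &: p_{m1} \sim U[0,1], \; p_{m2} \sim \mathrm{Beta}(\alpha_2, 1) \\
Z_m = 11 &: p_{m1} \sim \mathrm{Beta}(\alpha_1, 1), \; p_{m2} \sim \mathrm{Beta}(\alpha_2, 1)
\end{aligned}
$$

with mixing proportions $\pi_{00}, \pi_{10}, \pi_{01}, \pi_{11}$ and
$0 < \alpha_k < 1$. A Beta$(\alpha,1)$ density $\alpha p^{\alpha-1}$
decreases monotonically on $(0,1]$, so smaller p-values are more likely under
association, and $\alpha$ controls the mass near zero: stronger studies yield
smaller $\hat\alpha$. As $\alpha \to 1$ the component degenerates to the
Uniform null. `fit_pair_em()` maximizes the likelihood by EM:

* E-step: $w_{mc} \propto \pi_c f_c(p_{m1}) g_c(p_{m2})$, computed in log
  space with log-sum-exp normalization;
* M-step: $\pi_c = \bar w_{\cdot c}$ and the complete-data shape MLE
  $\hat\alpha_1 = -\sum_m (w_{m,10}+w_{m,11}) \big/ \sum_m (w_{m,10}+w_{m,11}) \log p_{m1}$
  (analogously $\hat\alpha_2$).

## Numerical conventions

The original description leaves initialization and stopping unstated; the
package's conventions are:

* initialization $\pi = (0.7, 0.1, 0.1, 0.1)$, $\alpha = 0.5$ — a
  null-dominant start matching the reality that most SNPs are null;
  configurable via `em_control()`, with optional extra starts;
* convergence when the relative log-likelihood change falls below `1e-6`, cap
  of 2000 iterations (non-convergence is flagged and warned, never silent);
* p-values clipped to $[10^{-30}, 1]$ before logs; $\hat\alpha$ clamped to
  $[10^{-4}, 1 - 10^{-4}]$.

On *null-only* data the two-group marginal model is unidentifiable along a
ridge: $\alpha \to 1$ makes the "signal" component uniform, so
$\hat\pi_1$ is arbitrary while the effective signal mass
$\hat\pi_1(1-\hat\alpha)$ vanishes. Tests assert the identifiable quantity.
The likelihood-ratio test below is unaffected because simulated and real
traits carry genuine signals, which pin $\alpha$ down.

# The pleiotropy test

Independence of the two traits' signals is the null hypothesis
$H_0: \pi_{11} = (\pi_{10}+\pi_{11})(\pi_{01}+\pi_{11})$. Under $H_0$ the
joint density factorizes *exactly* into the product of two two-group
mixtures, so the null log-likelihood is the sum of two marginal fits
(`fit_marginal_em()`) — simpler and numerically stabler than a constrained
joint EM, and exact at the optimum. The statistic
$T = \max\{0,\, 2(\ell_{\text{alt}} - \ell_{\text{null}})\}$ is referred to a
$\chi^2_1$ upper tail (five free parameters against four). The alternative
EM is multi-started from the default initialization and from an
independence-informed start built from the marginal fits; negative $T$
(a local-optimum artifact of nested-model fitting) is clamped to zero with a
warning. The $\chi^2$ reference is asymptotic in the number of SNPs; the
acceptance suite verifies a mean null statistic of $\approx 1$ and nominal
type-I error already at $M = 10^4$, an order of magnitude below the
$2\times10^5$–$10^7$ SNPs of real applications. Shape parameters are refit
independently under each hypothesis (whether the original profiles them
jointly is unstated; refitting keeps both likelihoods exact maxima).

`pairwise_pleiotropy()` assembles the $K \times K$ symmetric matrix of test
p-values $y_{ij}$ with unit diagonal — self-pleiotropy is undefined, and the
diagonal is excluded from every downstream transform.

# From p-values to a map

Small pleiotropy p-values carry most of the information, so using $y_{ij}$
directly as a distance wastes the visual range. The Box-Cox family

$$ s_{ij}(\lambda) = \begin{cases} (y_{ij}^\lambda - 1)/\lambda & \lambda \neq 0 \\ \ln y_{ij} & \lambda = 0 \end{cases} $$

gives a tunable zoom: $\lambda$ below 0 stretches the neighborhood of zero
(strong pleiotropy) apart — a bird's-eye view — while $\lambda$ above 0
compresses it for a close-up. Natural log is used at $\lambda = 0$; a log10
variant differs by a positive factor that the subsequent normalization
cancels, so the two are equivalent here. `transform_distance_matrix()` then
min–max rescales the off-diagonal $s_{ij}$ to $[0, 1]$ with a zero diagonal.
The source description never says how the (negative, unbounded) transformed
values become non-negative distances; min–max normalization is this
package's resolution — it preserves rank order, makes the default
neighborhood radius $\epsilon = 0.15$ meaningful on an absolute scale, and is
the single largest interpretive choice in the package. A matrix whose
off-diagonal p-values are all identical has no scale and is rejected as
degenerate.

The embedding is isomap: connect phenotypes $i, j$ when their normalized
distance is at most $\epsilon$ (the $\epsilon$-ball rule only; the k-nearest
-neighbor variant is not implemented since no k is ever specified for this
use), weight edges by the distance, compute all-pairs shortest paths by
Floyd-Warshall, and embed the geodesic matrix $D_G$ with classical MDS: the
$\tau$ operator $\tau(D) = -\tfrac12 H (D \circ D) H$ converts distances to
inner products, and the top-$d$ eigenvectors scaled by the square roots of
their eigenvalues minimize $E = \lVert \tau(D_G) - \tau(D_X)\rVert_{L^2}$.
A disconnected graph raises a "fragmented data" error; `auto_epsilon()`
returns the smallest radius on a grid (default step 0.01) that connects,
mirroring how $\epsilon = 0.15$ was chosen in the original application.
Determinism details: eigenvector signs are fixed by forcing each axis's
largest-magnitude loading positive (classical MDS is otherwise sign-ambiguous
and maps would flip between runs — the stated reason isomap was preferred
over repeated stress-based MDS); axes with non-positive eigenvalues are
padded with zeros and warned about; ties break by index. Note that because
normalized p-value distances are generally non-metric, shortest paths may
legitimately shortcut direct edges even on a complete graph, so
isomap-equals-MDS holds exactly only for metric inputs (the test suite checks
it on Euclidean-derived matrices).

Clustering (`cluster_phenotypes()`) operates on the embedded coordinates,
not the raw distances: seeded k-means with 10 restarts (best within-cluster
sum of squares kept), or agglomerative hierarchical clustering with complete
linkage by default (the linkage is unspecified in the source; complete is the
default of the classic R routine and is configurable). Labels are renumbered
by first occurrence so equal partitions compare equal.

# Joint association mapping

For a chosen pair and pattern (default `"11"`, shared by both traits), each
SNP's local false discovery rate is
$\mathrm{locfdr}_m = 1 - \Pr(Z_{m,11} = 1 \mid p_{m1}, p_{m2})$,
computed from the fitted posteriors. `joint_assoc()` sorts SNPs by ascending
local FDR and keeps the largest prefix whose running mean stays at or below
the user's global FDR level — the direct posterior probability control rule,
the standard conversion from local to global FDR for posterior-based methods
(the source names both FDRs without giving the conversion). The selected
set's mean local FDR estimates its global FDR, selection counts are monotone
in the level, and tables at nested levels are nested. All four patterns are
supported; only `"11"` is exercised by the original workflow.

# The simulator: a stated world

`scenario_preset()` reproduces the four simulation designs used to validate
the method: five phenotypes, $M = 20{,}000$ SNPs by default, 20% associated
SNPs per phenotype (5% for phenotypes 3-4 in scenario D), extra overlap of
75% and/or 25% within the designated pairs (1,2) and (3,4), phenotype 5 an
unpaired negative control, and associated p-values from Beta$(0.4, 1)$
(drawn as $u^{1/\alpha}$), nulls Uniform. $M$ is never stated in the source;
20,000 is large enough for the $\chi^2$ asymptotics and small enough for
seconds-scale tests.

"$\rho\%$ extra overlap" is not defined operationally in the source. The
package's convention interpolates the joint association mass linearly
between chance and full sharing, preserving both marginals:
$$ p_{11} = q_i q_j + \rho\,(\min(q_i, q_j) - q_i q_j), $$
drawn as $Z_i \sim \mathrm{Bern}(q_i)$, then
$Z_j \mid Z_i{=}1 \sim \mathrm{Bern}(p_{11}/q_i)$ and
$Z_j \mid Z_i{=}0 \sim \mathrm{Bern}((q_j - p_{11})/(1 - q_i))$.
For equal marginals the $Z_i{=}1$ branch reduces to the intuitive
$\rho + (1-\rho)q_j$ ("with probability $\rho$ share, otherwise by chance");
the $Z_i{=}0$ branch compensates so that the marginal proportion of
associated SNPs is *exactly* $q_j$ — without that compensation the paired
phenotypes would carry inflated marginals and the generator's own
calibration checks (20% per phenotype, 4% chance overlap) would fail.
$\rho = 0$ reduces to exact independence; $\rho = 1$ makes equal-marginal
pairs share one signal set.

What the generator does *not* emulate: linkage disequilibrium between SNPs
(the mixture assumes independent SNPs), effect-size heterogeneity beyond the
single-$\alpha$ Beta emission, confounded (non-Uniform) null p-values from
population stratification, and case-control sampling. A green end-to-end
test therefore establishes correctness of the pipeline under the model's own
assumptions, not robustness to their violation.

# What the acceptance suite establishes

With everything above in place: the EM recovers $\alpha = 0.4$ within
$\pm 0.05$ (10 seeds, $M = 20{,}000$); chance overlap calibrates to
$0.2 \times 0.2 = 0.04$ within 3 binomial SEs at $M = 10^5$; the null LRT
mean sits within $1 \pm 0.25$ with nominal type-I error (200 replicates,
$M = 10^4$); generator marginals hit 20% within 3 SEs; and the end-to-end
maps reproduce the designed structure — scenario A clusters
$\{1,2\},\{3,4\},\{5\}$, scenario C embeds the 75%-overlap pair closer than
the 25% pair, and scenario D keeps that structure when the paired phenotypes
drop to 5% signal density (the test responds to the *degree* of sharing, not
signal abundance). Oracle checks pin the E-step to a direct Bayes
enumeration ($10^{-12}$), Floyd-Warshall to exhaustive path enumeration, and
classical MDS to exact round-trips of Euclidean-realizable inputs
($10^{-8}$).

# Known limitations

* The pleiotropy p-value measures statistical sharing of signal, not shared
  causal variants; LD can inflate it locally.
* The min-max normalization ties distances to the current phenotype set:
  adding a phenotype rescales all distances (as in the original tool, the
  map is relative, not absolute).
* The marginal two-group fit is unidentifiable on pure-null data (ridge
  $\alpha \to 1$); only ridge-invariant functionals of that fit are
  meaningful there.
* Manifest timestamps and PDF plot metadata are not byte-reproducible; all
  data outputs (TSV/CSV/JSON fit parameters) are.
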