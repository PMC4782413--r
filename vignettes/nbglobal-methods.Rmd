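---
title: "Global score tests for overdispersed counts: model, inference, design"
author: "nbglobal authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global score tests for overdispersed counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbglobal)
```

## The problem

RNA-Seq expression of a single gene is a vector of counts
$y = (y_1, \dots, y_n)$, one per sample. We want to know whether a whole
*set* of covariates — SNP dosages in a window around the gene, local copy
numbers, methylation levels — is associated with that expression. Two
obstacles make the obvious regression approach fail: the counts are
overdispersed (their variance exceeds their mean), and the covariates
usually outnumber the samples ($p \gg n$), so individual coefficients
cannot be estimated.

`nbglobal` addresses both. The response is modelled as negative binomial,
$y_i \sim \mathrm{NB}(\mu_i, \phi)$ with
$\mathrm{Var}[y_i] = \mu_i + \phi \mu_i^2$, and the covariate effects are
treated as *random*: in the GLM
$\mathrm{E}[y_i \mid r_i] = h^{-1}(\alpha + r_i)$ with
$r_i = \sum_j X_{ij}\beta_j$, the coefficients $\beta_j$ have mean zero
and common variance $\tau^2$. The global null hypothesis of no
association is then the single parameter constraint $\tau^2 = 0$, testable
whatever the dimension of $X$.

## The score statistic

The score test of $\tau^2 = 0$ (locally most powerful near the null)
leads, after replacing $\alpha$ and $\phi$ by their maximum-likelihood
estimates under the null, to

$$
u \;=\; \tfrac12 \sum_{i,k} R_{ik}\, e_i e_k \;-\;
        \tfrac12 \sum_i R_{ii}\, w_i,
\qquad
e_i = \frac{y_i - \hat\mu_i}{1 + \hat\phi \hat\mu_i},
\qquad
w_i = \frac{\hat\mu_i + y_i \hat\phi \hat\mu_i}{(1 + \hat\phi \hat\mu_i)^2},
$$

where $R = (1/p) X X^\top$ is the $n \times n$ covariate-similarity
kernel. The implementation uses the matrix form
$u = \tfrac12 e^\top R e - \tfrac12 \operatorname{diag}(R)^\top w$, which
is $O(n^2)$ per evaluation; its exact agreement with the literal double
sum is a standing test, not an assumption. Setting $\phi = 0$ gives the
Poisson statistic, and a null fit on the dispersion boundary
($\hat\phi = 0$) makes the two statistics identical — the NB test
degrades gracefully to the Poisson test when overdispersion is absent.

The statistic decomposes exactly: per-sample contributions
$s_i$ (`sample_contributions()`) and per-covariate contributions $c_j$
(`covariate_contributions()`) each sum to $u$, and $p \, c_j$ is exactly
the statistic that testing covariate $j$ alone would give. The statistic
of a covariate group is the mean of its members' single-covariate
statistics (`group_statistic()`).

## Null model fit

Under the null, all samples share one intercept; with library sizes
$m_i$ the mean is $\mu_i = (m_i/\bar m)\exp(\alpha)$, where $\bar m$ is
the *geometric* mean, so the offset multipliers have product one. Data
already depth-adjusted should disable the offset
(`count_response(..., offset = FALSE)`).

Maximisation is by profiling: for fixed $\phi$, the intercept solves
$\sum_i (y_i - \mu_i)/(1 + \phi\mu_i) = 0$ by damped Newton iteration
(converged when the score falls below $10^{-12} \sum_i y_i$; this
stationarity condition is itself asserted in the tests at
$10^{-6}\sum_i y_i$), and the profile likelihood is maximised over
$\log\phi$ by golden-section search on
$[\log 10^{-8}, \log \max(10^3, 10\,\hat\phi_{\mathrm{MM}})]$ with
tolerance $10^{-8}$, started from the method-of-moments value
$\hat\phi_{\mathrm{MM}} = \max\{0, (s^2-\bar y)/\bar y^2\}$. An interior
optimum below $10^{-7}$, or a profile likelihood that never beats the
Poisson fit, is clamped to the boundary $\hat\phi = 0$. A response that
is zero everywhere has no finite intercept and raises a typed
degenerate-response error; the scan driver skips and flags such genes
rather than producing NaNs.

## Permutation inference

The null distribution of $u$ is unknown, so p-values come from
permutation: the pair $(y, \hat\mu)$ is permuted jointly while $R$ stays
fixed. Because the ML fit is order-invariant, $\hat\alpha$ and
$\hat\phi$ need not be re-estimated per permutation — only $e$ and $w$
are reindexed, which is what makes genome-wide use cheap. The test is
one-sided (large $u$ is evidence against the null), permutations are
sampled uniformly *with replacement* from the permutation group, and the
observed configuration counts as one of the $k$ draws, so the smallest
attainable p-value is exactly $1/k$ and ties count as exceedances. With
known sample groupings (e.g. two populations), `strata` restricts every
permutation to shuffle within groups, which removes confounding by
stratum-level differences in both expression level and covariate
distribution.

### Control variates

The crude estimator needs many permutations for precise small p-values.
The control-variates estimator uses the Gaussian-response quadratic form
$q = \tilde z^\top R \tilde z$ (with $\tilde z$ the centred, unit-variance
transform of $y$) as a control:
$\hat p_{\mathrm{cv}} = \frac1k\sum_i \mathbf 1[u_i \ge u_0] -
\frac1k\sum_i \mathbf 1[q_i \ge q_0] + p^*$, both sums over the *same*
permutations. When $u$ and $q$ are strongly correlated the indicators
cancel and the Monte-Carlo variance collapses. The reference value $p^*$
is the permutation tail of $q$: its first two moments under uniform
permutation have closed forms (derived by set-partition pattern sums over
the kernel and power sums of $\tilde z$, and verified in the tests
against exhaustive $n!$ enumeration), and the tail is approximated by a
Satterthwaite moment-matched scaled chi-square; for $n \le 8$ an exact
enumeration option exists. The exact construction of the control is this
package's own (the original software's is not published); its residual
bias equals $p^*$ minus the true permutation tail of $q$, which is why
the crude estimator stays the default and the raw (unclipped) CV value is
retained alongside the reported one. Kernels that make $q$
permutation-invariant (all-ones, identity) carry no signal; they raise a
degenerate-set condition and trigger a fallback to the crude estimator
with a warning.

Note one deliberate asymmetry: the reported p-values include the
observed draw (minimum $1/k$), which adds an $O(1/k)$ offset relative to
the pure permutation-only estimators; the unbiasedness identity between
crude and CV estimators holds for the pure forms, and that is how the
test suite checks it.

### Early stopping

For genome-wide scans most genes are clearly null. With
`early_stop = alpha`, permutations are processed in batches and the run
halts once the exceedance count alone already forces the final p-value
above `alpha`; the p-value is then reported at the reduced draw count.
The rule can only stop runs whose full-length decision would also be
"not significant", so decisions at level `alpha` never flip — a property
the tests check against full runs. Stopping early *for* significance is
impossible by construction, since reaching $1/k$ requires all $k$ draws.

## Multiple molecular profiles

To test several covariate sets (say SNPs $X$ and methylation $Z$)
simultaneously, each set's statistic is standardised by its estimated
permutation moments and the z-scores are summed:
$u(X,Z) = \frac{u(X) - \hat E[u(X)]}{\sqrt{\widehat{\mathrm{Var}}[u(X)]}}
        + \frac{u(Z) - \hat E[u(Z)]}{\sqrt{\widehat{\mathrm{Var}}[u(Z)]}}$,
extended additively to any number of sets; cross-set correlation is
deliberately ignored (it costs little power). One shared permutation
stream drives all sets; moments are estimated from those same permuted
statistics *including the observed draw*, and every permutation's joint
statistic is standardised with the same global moment estimates, avoiding
circular re-standardisation. Two consequences are exact and tested: a
single-set joint test reproduces that set's crude p-value, and
duplicating a set doubles its standardised contribution. Whether the
original software includes the observed draw in the moments is unstated;
including it is this package's choice, pinned down by the single-set
equality.

## The synthetic-data generator

The generator emulates the structure the method assumes, not any real
dataset:

* **Genotypes** (`synthetic_genotypes()`): latent standard normals,
  equicorrelated within consecutive blocks (`block_size = 10`,
  `rho = 0.5` by default) and independent across blocks, thresholded at
  Hardy–Weinberg quantiles for a per-SNP minor allele frequency drawn
  from `maf_range = (0.1, 0.4)`. This reproduces the positive local
  correlation (linkage disequilibrium) that makes set-based testing
  worthwhile, but not long-range LD decay, population admixture, or
  empirical allele-frequency spectra — so passing simulations demonstrate
  calibration and power under idealised LD, not on any particular cohort.
* **Coefficients** (`draw_coefficients()`): all zero except one
  uniformly placed run of `r` consecutive entries, each `s` with
  probability 0.8 and `2s` with probability 0.2.
* **Response** (`simulate_response()`): $\mu = X\beta$ on the *identity*
  scale, then $y_i \sim \mathrm{NB}(\mu_i, \phi)$. The identity link is
  kept although the test uses a log link — this generator/analysis
  mismatch is intentional and preserved, as a mild robustness stressor.
  $\mu_i = 0$ yields $y_i = 0$; an optional additive `baseline` avoids
  zero means where unwanted, but is off by default. Null data are made
  by shuffling $\mu$ before sampling, which preserves the marginal count
  distribution exactly, so any calibration failure implicates the test,
  never the generator.

Default study conditions: $n = 50$ samples, $p = 20$ SNPs, run length
$r = 5$, dispersion $\phi = 0.5$, $k = 200$ permutations per test, and
200 + 200 replicates per condition (1000 null replicates for the
calibration check) — sizes chosen so a full study is minutes of CPU while
binomial noise stays well below the effects being asserted. Effect-size
levels for the monotonicity study are $s \in \{0.05, 0.1, 0.25\}$: a
pilot showed that with block-correlated dosages and a 5-SNP run,
$s \ge 0.5$ already saturates the AUC near 0.98, leaving no room to
observe strict ordering; the chosen levels span weak to moderate signal
(AUC roughly 0.75 to 0.95) and were fixed before the confirmatory runs.

## Scan driver and file conventions

`genomewide_scan()` tests one gene at a time against the covariates in a
window around it, then applies Benjamini–Hochberg FDR correction across
tested genes. Conventions, stated here because they are genuinely open
choices:

* Coordinates are 0-based half-open (BED-native) everywhere; a covariate
  at position $x$ is in the window when $\text{start} - w \le x <
  \text{end} + w$ (`anchor = "gene_body"`) or $\text{start} - w \le x <
  \text{start} + w$ (`anchor = "gene_start"`, the
  promoter-centred variant). The left edge is closed.
* Strand is ignored; "start" is the smaller coordinate.
* Samples are aligned across count, covariate and strata inputs by id,
  never by column position.
* Each gene's permutation stream is seeded by a deterministic hash of
  the master seed and the gene id, so results are invariant to gene
  order and amenable to parallel fan-out.
* Genes with all-zero or constant counts, empty windows, or unknown
  chromosomes are flagged and skipped, not silently dropped.
* SNP dosages (0/1/2 minor-allele counts) are treated as plain
  quantitative covariates; VCF parsing is out of scope (pre-converted
  dosage TSVs are the input format).

## Numerical choices and limitations

* Covariate columns are used as supplied; `center = TRUE` on
  `covariate_set()` opts into column centering (which changes $R$ and
  hence the test). Scaling all of $X$ by $c > 0$ rescales $u$ by $c^2$
  uniformly across permutations and leaves p-values untouched; adding an
  all-zero covariate *does* change the p-value, because the $1/p$
  averaging in $R$ changes — both behaviours are tested.
* The overall $\tfrac12$ scaling of $u$ is taken as printed; any other
  constant would rescale all permuted statistics alike and leave
  p-values unchanged.
* Dispersion is estimated per gene with no information sharing across
  genes; at small $n$ the estimate is noisy, and an empirical-Bayes
  variant is out of scope.
* No asymptotic null distribution for $u$ is provided (its permutation
  moments would allow one; left open deliberately), so p-values cannot
  undercut $1/k$.
* The simulation studies report the rank-based (Mann–Whitney) AUC of
  alternative-arm versus null-arm p-values, with ties counted half —
  checked against a brute-force pairwise count.
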