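---
title: "Latent-context eQTL discovery with surgelite: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-context eQTL discovery with surgelite: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The effect of a regulatory variant on its target gene's expression is rarely
constant: it can depend on cell type, developmental stage, stimulation state,
or other cellular contexts, many of which are not known in advance. Standard
interaction-eQTL analysis requires the analyst to pre-specify the context to
interact with genotype. `surgelite` implements the SURGE model (Single-cell
Unsupervised Regulation of Gene Expression), which removes that requirement:
it learns, directly from paired expression and genotype data, the continuous
latent contexts whose interaction with genotype explains the most expression
variance — together with the context-specific eQTL effect sizes themselves.

## The generative model

Let $n$ index RNA samples (bulk samples or pseudocells), $t$ index
genome-wide *representative variant-gene pairs* (one variant per gene, one
gene per variant), and $i$ index genotyped individuals, with $n \in i$
meaning sample $n$ was drawn from individual $i$. With standardized
expression $y_{nt}$, standardized genotype $G_{nt}$, covariates $X_{nl}$ and
$K$ latent contexts:

$$
y_{nt} \sim N\!\Big(\mu_t + \textstyle\sum_l X_{nl} W_{lt}
 + \sum_i I[n \in i]\,\alpha_{it}
 + G_{nt} F_t + G_{nt} \sum_k U_{nk} V_{kt},\; \sigma^2_t\Big)
$$

$U_{nk}$ is the value of latent context $k$ in sample $n$; $V_{kt}$ the
eQTL effect of test $t$ specific to context $k$; $F_t$ the shared
(context-independent) eQTL effect; $\mu_t$, $W_{lt}$ and $\alpha_{it}$
intercept, covariate and per-individual random-intercept terms. Priors:

* $U_{nk} \sim N(0, \gamma_k^2)$ with $1/\gamma_k^2 \sim
  \mathrm{Gamma}(\alpha_0, \beta_0)$ — an automatic relevance determination
  (ARD) prior. When a context carries no genotype-interaction signal its
  $\gamma_k^2$ collapses toward zero and the context switches itself off, so
  the effective number of contexts is learned: initialize $K$ generously and
  prune afterwards.
* $V_{kt}, F_t \sim N(0, 1)$.
* $\alpha_{it} \sim N(0, \psi_t^2)$, $1/\psi_t^2 \sim
  \mathrm{Gamma}(\alpha_0, \beta_0)$;
  $1/\sigma_t^2 \sim \mathrm{Gamma}(\alpha_0, \beta_0)$.
* $\mu_t, W_{lt} \sim N(0, 1)$. No prior is dictated for these two by the
  model description, only their variational factors; we give them the same
  standard-normal prior as the other location effects. Because expression is
  standardized to mean zero and covariates are expected on a comparable
  scale, this prior is effectively non-informative for the intercepts while
  keeping every coordinate update conjugate.

$\alpha_0 = \beta_0 = 10^{-3}$ by default: near non-informative while
keeping the precision updates proper.

**Input scaling.** Each expression column is standardized to mean 0,
variance 1 (population variance, so "variance 1" is exact; an optional
`cap` clips extreme z-scores, e.g. at 10, to limit outlier leverage). Each
genotype column is centred and then divided by the standard deviation of the
elementwise ratio $y_{nt} / G^{c}_{nt}$ (centred genotype): this equalizes
how much variance the low-rank interaction term can explain across tests.
The ratio is ill-defined where the centred genotype is numerically zero, so
entries with $|G^c| \le 10^{-8}$ are excluded, the scale is floored at
$10^{-6}$, and fewer than 3 usable entries (or an exactly constant ratio) is
an error. Whether the ratio denominator uses centred or raw dosage is an
open choice; centred is the default and `ratioOnCentered = FALSE` exposes
the alternative. Monomorphic variants cannot be standardized (or be eQTLs);
`preprocessDataset()` drops such tests with a message.

## Mean-field variational inference

The posterior over $Z = (U, V, F, \mu, W, \alpha, \gamma^2, \psi^2,
\sigma^2)$ is approximated by a fully factorized family: an independent
Gaussian $q$ for every scalar location latent and an independent Gamma $q$
for every precision. Inference maximizes the evidence lower bound
$\mathrm{ELBO} = E_q[\log p(Y, Z)] - E_q[\log q(Z)]$ by coordinate ascent:
each block update is the closed-form conjugate optimum given all other
factors, so the ELBO is non-decreasing by construction. All expectations are
exact Gaussian/Gamma moment identities (no Monte Carlo); mean-field
independence gives $E[U_{nk} V_{kt}] = \mu_U \mu_V$ and
$E[(U_{nk}V_{kt})^2] = (\mu_U^2 + \sigma_U^2)(\mu_V^2 + \sigma_V^2)$.

Within one sweep the blocks are updated in the fixed order
$V, F, \mu, W, \alpha, U$, then the precisions $\gamma, \psi, \sigma$.
The order is a free choice (any fixed order preserves the ascent
guarantee); loadings are updated before the precisions so the ARD variances
react to the current factorization. The engine maintains the residual
matrix incrementally, making a full sweep $O(NTK)$; it is implemented in
RcppArmadillo with an R front end.

* **Initialization.** $U$ means are drawn from a standard normal (breaking
  the symmetry between contexts), all other means start at 0, all
  variational variances at 1, Gamma factors at their prior parameters.
  The initialization distribution is another free choice; a unit-scale
  start matches the scale of the standardized data.
* **Restarts.** Coordinate ascent only finds local optima, so `fitSurge()`
  runs `nRestarts` (default 3) independent seeded initializations and keeps
  the restart with the largest final ELBO. Restart seeds are derived
  deterministically from the configured seed.
* **Convergence** is declared when the ELBO changes by less than
  `elboTol = 1e-2` between sweeps (iteration cap 1000). A non-finite ELBO
  marks a diverged restart; if every restart diverges, fitting errors.

## Proportion of variance explained and pruning

The signal attributed to context $k$ is summarized with posterior means as
plug-ins:

$$
s_k = \sum_{n,t} \big(G_{nt}\, \hat U_{nk} \hat V_{kt}\big)^2,
\qquad
\mathrm{PVE}_k = \frac{s_k}{\sum_k s_k + N \sum_t \hat\sigma_t^2},
\qquad
\mathrm{PSMVE}_k = \frac{s_k}{\sum_k s_k},
$$

with $\hat\sigma^2_t$ the variational posterior mean of the residual
variance. A natural alternative definition of $s_k$ is the signed sum
$\sum_{n,t} G \hat U \hat V$, but that can be negative and would put PVE
outside $[0,1]$; since PVE is a variance share, we square the terms by
default and expose the signed sum behind `strict = TRUE`. Contexts
with $\mathrm{PVE} \le 10^{-5}$ are pruned; survivors are reported in
descending PVE order with PSMVE renormalized over them. Because the factors
are not orthogonal, "variance explained" is a signal measure, not an exact
ANOVA decomposition.

## The simulation framework

`simulateEqtlData()` is first-class, tested code: it defines the study
conditions and doubles as the fixture generator for the whole test suite.
Per test: allele frequency $\sim U(0.05, 0.95)$, dosages
$\sim \mathrm{Binomial}(2, af)$, and

$$
y_n \sim N\Big(\mu + \beta G_n + \textstyle\sum_k G_n U_{nk} V_k \theta_k,\, 1\Big),
$$

with $\mu, \beta, U_{nk} \sim N(0,1)$, $V_k \sim N(0, \gamma^2)$ and
activity indicators $\theta_k \sim \mathrm{Bernoulli}(p)$ per test and
context. `gamma` is the standard deviation; the "interaction variance"
scale is $\gamma^2$ (variance $0.25$ means `gamma = 0.5`). Simulated data
pass through the same standardization as real data before fitting, since
the likelihood assumes standardized inputs. The reference evaluation uses 5
simulated contexts, $N = 250$, $T = 1000$, interaction variance 0.25 and
fraction $p = 0.3$, 10 replicates: the modal retained-context count should
equal 5, and recovery (mean $R^2$ of each simulated context regressed on
all learned contexts jointly, with intercept — invariant to permutation and
sign flips of the learned contexts) grows with $N$.

What the simulator emulates: genotype-dependent effect-size modulation by
several overlapping continuous contexts, unit residual noise, and optional
repeat structure (`nIndividuals < N`, round-robin, shared dosages within an
individual — used to exercise the random-intercept and permutation
machinery; the generative description itself has one sample per
individual). What it does not emulate: linkage disequilibrium between
variants, covariate effects on expression, non-Gaussian counts, library-size
or batch artefacts, or discrete cell-type structure. Passing the recovery
tests therefore demonstrates correctness of the inference under the model's
own assumptions, not robustness to real single-cell noise.

## Interaction-eQTL testing

Model fitting uses at most ~2000 representative pairs; testing covers *all*
variant-gene pairs. Treating the posterior-mean contexts $\hat U$ as
observed, each pair is tested with the linear mixed model

$$
y_n \sim N\Big(\mu + \alpha_{i(n)} + \textstyle\sum_l W_l X_{nl} + \beta_g g_n
 + \sum_k \beta_k \hat U_{nk} + \sum_k \beta_{g\times k}\, g_n \hat U_{nk},\,
 \sigma^2\Big), \quad \alpha_i \sim N(0, \psi^2),
$$

fit with `lme4` (REML). Each of the $K$ interaction coefficients gets a
two-sided Wald p-value against a normal reference (the exact finite-sample
reference for LMM Wald statistics is not settled; the normal is the
large-sample choice and is what the calibration test checks). With the
random intercept disabled — or when every individual contributes one sample,
where the intercept variance is unidentifiable — the model reduces to OLS
and p-values come from the exact t reference. Gene-level significance is
the Bonferroni-corrected minimum over a gene's variants
($\min(1, m_g \cdot \min p)$), per context.

Expression-PC interaction testing (`expressionPcContexts()`) is identical
except the contexts are the first $K$ principal-component scores of the
expression matrix — the pre-specified-context benchmark.

## Permutation calibration (empirical FDR)

Because the contexts are learned from the same data later used for testing,
nominal interaction p-values are anti-conservative ("double dipping").
Calibration uses one genotype permutation drawn at the *individual* level
and applied identically at every variant (preserving cross-variant
correlation and repeat structure), with the permuted genotype entering
*only* the interaction terms — the genotype main effect keeps the original
dosages — both when re-learning contexts on permuted data and when testing.
If $Z$ real contexts survive pruning, the top $Z$ permuted contexts by PVE
are tested (permuted contexts essentially never pass the PVE threshold
themselves; "top" is by PVE, the natural ranking).

Given observed and permuted gene-level p-values, the empirical FDR at a
candidate threshold $p^*$ is
$\#\{\text{permuted} \le p^*\} / \#\{\text{observed} \le p^*\}$. Candidates
are the observed p-values (so the denominator is never zero); the curve is
made monotone non-decreasing in $p^*$ by a running minimum over larger
candidates (so a stricter level always yields a subset of calls), and the
significance threshold is the largest candidate with adjusted eFDR at or
below the target level. The recommended mode calibrates each context
independently (`per-context`); `all-context` pools all (gene, context)
pairs. Under a simulated global null the pipeline should — and in tests
does — call essentially nothing at level 0.05.

## Context-dependent effect sizes and heritability annotations

From a joint interaction fit, the expected eQTL effect at context value
$U^*_k$ is $\beta^* = \hat\beta_g + U^*_k\, \hat\beta_{g\times k}$, using
the full joint fit's $\hat\beta_g$ and the context-$k$ interaction
coefficient (no per-grid-point refitting: $\beta^*$ presumes a single fit).
For stratified LD-score regression, `annotateAcrossGrid()` evaluates
$\beta^{*2}$ at 200 equally spaced positions spanning the observed range of
a latent context, sums squared effects over all genes a variant maps to
(variants mapping to no gene get 0), and writes standard `.annot` files
(CHR, BP, SNP, CM, one annotation column). Running S-LDSC itself, and the
baseline annotation sets it is run with, are outside this package's scope.

## Numerical choices and conventions

* Population (divide-by-$n$) variance throughout standardization and the
  ratio-scale computation.
* Representative-pair selection: genes significant at BH FDR 0.05 ranked by
  gene-level p (ties broken lexicographically by gene id — the tie rule is
  this package's choice), capped at 2000 genes; each gene contributes its
  most significant variant; a pair whose variant is already claimed by a
  more significant gene is dropped outright (the gene is *not* given its
  second-best variant).
* `useRandomIntercept = NA` (default) enables the per-individual intercept
  exactly when repeat structure exists; with one sample per individual the
  extra variance parameter is unidentifiable and the block is dropped
  ($\alpha \equiv 0$, $\psi$ not updated).
* eFDR with an empty candidate set, or nothing passing the level, returns
  an `NA` threshold and zero calls; an empty permuted table is an error.
* Zero retained contexts is a valid model outcome; downstream testing then
  refuses with a clear message rather than testing nothing silently.

## Problem sizes used by the test suite

The packaged checks run, as this package's choices: the reference
recovery evaluation at its stated conditions ($N=250$, $T=1000$, 10
replicates, `kInit = 10`, 3 restarts); parameter recovery at $N=500$,
$T=1000$, interaction variance 0.5, $K_{sim}=3$ with `kInit = 5` and one
restart (signal this strong does not need restart insurance); the
sample-size trend at $T=300$ with `kInit = 8`; null calibration with 500
replicate Wald tests at $N=400$ (two samples per individual) and ten
pipeline replicates at $N=150$, $T=200$. ELBO/oracle identities are checked
on instances small enough for quadrature and derivative-free optimization
($N \le 12$, $T \le 8$).

## Known limitations

* Coordinate ascent over a non-convex objective: different seeds can find
  different optima; restarts mitigate but do not eliminate this.
* The model assumes complete matrices — missing values are refused, not
  imputed (imputation is a preprocessing concern).
* Posterior-mean contexts are treated as observed in testing; residual
  uncertainty in $\hat U$ is ignored (the permutation calibration absorbs
  the resulting optimism).
* The dense batch engine targets cohort-scale data (tens of thousands of
  samples at most), not atlas-scale stochastic optimization.
* Only the most significant variant per gene enters model fitting;
  secondary signals per gene are not modelled.
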