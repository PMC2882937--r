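---
title: "Module discovery with beem: models, calibration, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module discovery with beem: models, calibration, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science inside `beem`: the statistic, the
three-step p-value calibration, the two comparator screens, the simulation
models behind the benchmark, the numerical conventions, and the design
choices that were genuinely open. It states no measurement that the test
suite and `scripts/acceptance.R` do not themselves recompute.

## The problem

A gene set library assigns biological hypotheses to sets of genes —
"these genes share a promoter motif", "these genes responded to CEBP". In
a homogeneous experiment a functional set betrays itself by coherent
expression across all samples. In a heterogeneous compendium (many
tissues, mixed cohorts) a transcriptional program may be active only in a
subgroup of samples, so the right footprint is a *bicluster*: a gene
subset coherently shifted in a sample subset. `beem` screens each input
set for exactly that footprint.

## The BEEM statistic

For an input set $G$ in a preprocessed matrix $E$ ($N$ genes × $M$
samples, rows z-scored):

1. `coherent_subset()` extracts from $E_G$ a maximal coherent core $C$ —
   the largest stable set of member genes lying within a Euclidean radius
   $r$ of their own centroid. No significance is attached to $|C|$; a core
   below 3 genes falls back to $G$ itself as the seed.
2. `run_isa()` seeds the Iterative Signature Algorithm with $C$ on the
   *full* matrix pair: row-normalised $E^r$ for sample scores
   $s_j = \frac{1}{|g|}\sum_{i \in g} E^r_{ij}$ and column-normalised
   $E^c$ for gene scores, with percentile thresholds — a sample survives
   if its score exceeds the $(1-t_c)$ quantile of the score vector, a gene
   if it exceeds the $(1-t_g)$ quantile — iterated to a fixed point of the
   gene set. Down-regulated biclusters are found by negating both
   matrices. On convergence the bicluster holds $\approx t_g N$ genes $B$
   and $\approx t_c M$ samples.
3. The statistic is $k = |G \cap B|$; $G \cap B$ is the reported module.

Searching the full matrix rather than $E_G$ matters twice over: ISA on a
small submatrix is unstable and often fails to converge, and on $E_G$ the
bicluster size would be an almost deterministic function of $|G|$, leaving
$k$ uninformative. On the full matrix, $|B|$ is pinned by $t_g$ while the
*overlap* $k$ measures how strongly $G$ is tied to a genuine bicluster.

## Three-step p-value

**Step 1 — hypergeometric screen.** $p_1 = P(X \ge k)$ with
$X \sim \mathrm{Hypergeom}(N, |B|, |G|)$. This is deliberately liberal:
even for a random $G$, the seeded pipeline couples $B$ to $G$ (the core of
$G$ seeds the search), so null overlaps exceed the hypergeometric
expectation $|G||B|/N$ — a property the test suite checks directly. The
screen only removes clearly insignificant sets (default threshold
$p_1 < 10^{-2}$, configurable) before the expensive step.

**Step 2 — empirical null.** For each screened set, $R$ null statistics
are computed by the *full* pipeline (core extraction → seeded ISA →
overlap) on random gene sets of size $|G|$ drawn from the matrix's genes,
and $p_2 = (1 + \#\{k_{null} \ge k\})/(R + 1)$. Null draws are cached and
shared across sets of equal size within a setting; the null size is tied
to the *input* set (not the core), because the liberality being corrected
arises from the full chain starting at a random $G$. Default $R = 1000$.

**Step 3 — regression extrapolation.** $p_2$ cannot fall below
$1/(R+1)$. Across a screened library (fixed matrix, fixed setting),
$-\log_{10} p_2$ is close to linear in $-\log_{10} p_1$; an OLS fit on the
sets whose $p_2$ sits above the floor predicts $p_2$ for the saturated
ones. With fewer than `min_points = 10` usable pairs the fit is abandoned
and the prediction falls back to $\max(\text{floor}, p_1)$, flagged in the
output. The acceptance script measures the Pearson correlation of the two
log-scales on a null screen.

**Setting grid and correction.** The screen runs over
$t_g \in \{0.05, 0.1, 0.15\} \times t_c \in \{0.1, 0.2, 0.3\} \times
\{\text{up}, \text{down}\}$ (18 settings) by default. Which threshold
fraction plays the gene role and which the sample role is configurable;
the default mapping above makes the stated bicluster dimensions hold by
construction. Per set, a setting's p-value is its $p_2$ when screened and
1 otherwise; $p_{best}$ is the minimum and
$p_{final} = 1 - (1 - p_{best})^n$ (Šidák; Bonferroni available). Šidák
matches the best-of-$n$ selection under independence and is the milder of
the two corrections.

## Comparators

**EEM-style coherence screen.** Statistic $|C|$ from the same sphere
search, null from random same-size sets, empirical p-value. The exact
radius is the method's one tunable: it is expressed through an equivalent
correlation floor, $r = \sqrt{2(M-1)(1-\rho_0)}$ with $\rho_0 = 0.6$ by
default, because on z-scored rows squared distance and Pearson correlation
are affinely related — the sphere is "genes correlating at least
$\rho_0$ with the core centre". The sphere search starts from every member
gene *and* from the full-set centroid. The latter is essential: members of
a module with anchor-correlation $\rho$ sit within
$\sqrt{(M-1)(1-\rho^2)}$ of the centroid but $\sqrt{2(M-1)(1-\rho^2)}$ of
each other, so for radii between those two scales no single-gene start can
nucleate the core while the shrinking start finds it immediately.

**SSA.** Rows are z-scored, each sample contributes an up tail and a down
tail of its $\lfloor 0.05 N \rfloor$ most extreme genes, and each set gets
$2M$ hypergeometric tail p-values, combined by Fisher's
$X = -2\sum \ln p$. Because samples are correlated, $X$ is not
$\chi^2_{2 \cdot 2M}$; Brown's approximation refers $X/c$ to $\chi^2_f$
with $c = \widehat{\mathrm{Var}}(X) / (2 \cdot 2(2M))$ and
$f = 2 (2(2M))^2 / \widehat{\mathrm{Var}}(X)$, the variance estimated from
the Fisher statistics of 1000 null gene sets whose sizes follow the input
library's size distribution (one shared calibration per matrix and
fraction, as a per-set calibration would be prohibitively expensive; the
residual size-dependence of the variance is a known approximation). We
estimate the variance of $X$ directly from the null statistics rather than
summing $\binom{2M}{2}$ pairwise covariance terms: the target quantity is
identical ($\mathrm{Var}\,X = 2\,df + 2\sum\sum \mathrm{cov}$) and the
direct estimate is far more stable.

Two structural facts about this statistic are worth knowing, and the test
suite pins both down. First, per-sample hypergeometric p-values are
discrete and therefore conservative ($P(p \le t) \le t$); the
per-component variance of $-2\ln p$ is below the continuous value 4 (≈3.7
even at generous overlap support). Second, the components are *negatively*
cross-correlated through the fixed set size, which halves
$\mathrm{Var}(X)$ again. Consequently the Brown scale $c$ sits well below
1 even for perfectly independent samples — Fisher's combination is then
conservative, and Fisher and Brown p-values do **not** coincide in
distribution in any practical regime; they diverge in the opposite
direction (Fisher anticonservative, Brown calibrated) once samples are
strongly correlated. The acceptance suite demonstrates the correlated case
with duplicated samples and documents the independence case as a known
deviation from the idealised continuous-component picture.

## Simulation models

Both models emulate a compendium of $4000$ genes × $100$ samples (scales
are arguments).

* **Coherent model** — 20 non-overlapping modules of 200 genes. A module's
  anchor gene is standard normal over samples; each other member is
  $\rho \cdot \text{anchor} + \sqrt{1-\rho^2}\,\varepsilon$. This
  correlation-mixture form keeps every member marginally standard normal
  and makes $\rho$ the literal signal-strength dial.
* **Bicluster model** — 50 modules of 200 genes drawn uniformly (gene
  overlap allowed), each with $\lfloor q \cdot 100 \rfloor$ uniformly
  drawn samples. Entries inside any module's block are $\mu + N(0,1)$,
  drawn once even when blocks overlap (shifts do not add); everything else
  is $N(0,1)$. At the default density this shifts roughly 40% of all
  entries — the planted programs dominate the matrix, as intended.
* **Labelled library** — 10 positive sets (a fraction $r$ of each drawn
  from one module, modules without replacement, the rest random fill) and
  10 negative random sets, all of size 200.

`benchmark_methods()` scores each method by $-\log_{10} p$ against the
labels with a midrank Mann–Whitney AUC, averaging Monte Carlo trials.

What the generators do *not* emulate: heavy-tailed and count-like
expression noise, gene–gene correlation outside modules, batch structure,
and unequal module sizes. Passing benchmarks therefore demonstrate the
machinery under its own model assumptions, not performance on any
particular real platform.

## Problem sizes used by the tests and the acceptance script

The full-scale protocol (4000 × 100, 20 trials, $R = 1000$) is available
through the function arguments; the packaged checks run a reduced protocol
chosen once: ISA recovery on 200 × 50 matrices with a 20 × 10 planted
block over 20 instances; null calibration on a label-permuted 2000 × 60
noise matrix with 100 sets of sizes 20–300, $R = 200$, and a 4-setting
grid; benchmarks at 2000 × 100 with 5 trials and a 4-setting grid — the
bicluster model halves the full protocol in the gene dimension only (25
modules of 200 in 2000 genes), preserving its block density; calibration
linearity on a 1000 × 50 null screen with 150 same-size sets and
$R = 500$, where the shared-null design makes both log-p-values monotone
functions of $k$ and the correlation is expected high.

## Numerical conventions and degenerate inputs

* Quantiles are type-7 (linear interpolation); threshold selection is
  strict (`>`), so an all-tied score vector selects nothing and the ISA
  run reports non-convergence rather than erroring.
* ISA cycles (oscillations) are detected by hashing visited gene sets and
  reported as `converged = FALSE`; `max_iterations = 100`.
* A non-converged ISA run contributes $k = 0$ and an empty module.
* Variance uses denominator $n-1$ throughout; probe collapse keeps the
  first probe on variance ties; preprocessing drops zero-variance rows
  with a warning (erroring only if nothing remains); the log base is
  configurable (natural log by default).
* Empirical p-values are add-one smoothed, so they live in
  $[1/(R+1), 1]$ and multiplicity correction never receives 0.
* Tail sets break ties at the boundary by row order; tail size is
  $\lfloor 0.05 N\rfloor$ and must be at least 1.
* All stochastic functions take a seed and derive independent substreams
  (per setting, per null-set size, per trial) from it, so enlarging one
  loop does not shift another's draws.

## PWM redundancy clustering

Post-screening, motif gene sets that survive often carry near-identical
position weight matrices. `pwm_kl_cluster()` greedily clusters a
significance-sorted motif list: the most significant motif opens a
cluster and absorbs every remaining motif within a Kullback–Leibler
distance cutoff (default 15). The distance between two PWMs is the
minimum over ungapped offsets (at least 4 aligned columns) of the *total*
symmetric KL divergence $\sum_{\text{columns}} KL(p\|q) + KL(q\|p)$ on
pseudocount-smoothed columns (0.01, renormalised, natural log). The total
— not the per-column mean — is the scale on which the default cutoff is
meaningful: two sharply opposed 6-column motifs score ≈29 on the minimal
4-column alignment (far above 15), while cognate motifs score near 0. Any
other distance definition would require recalibrating the cutoff.

## Known limitations

* The EEM comparator implements a documented greedy sphere search; the
  original method's exact search and its analytic p-value are not public,
  so its empirical-null screen here is a faithful stand-in, not a
  re-implementation.
* Percentile-threshold ISA needs enough continuous spread in the scores;
  matrices with massive ties (e.g. unnormalised counts) should be
  preprocessed first.
* The Brown calibration is shared across set sizes; for libraries mixing
  very small and very large sets the per-size variance differs and the
  combined p-values are correspondingly approximate.
* SSA's power grows strongly with set size (large sets accumulate many
  mildly significant samples); at strong planted signal it saturates the
  benchmark AUC, so method orderings at such settings compress toward
  ties.
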