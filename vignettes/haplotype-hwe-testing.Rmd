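---
title: "Likelihood models and algorithms for haplotype-based HWE testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood models and algorithms for haplotype-based HWE testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplohwe)
library(dplyr)
```

## The problem

Case-control haplotype association methods typically assume Hardy-Weinberg
equilibrium (HWE) of *haplotype* frequencies in at least part of the sample,
and the EM haplotype-frequency estimator itself is biased when HWE fails. The
classical goodness-of-fit test over all multilocus genotype classes spends
degrees of freedom exponentially in the number of SNPs, so its power decays
quickly. `haplohwe` instead tests HWE against two *one-parameter* departures,
giving a pair of 1-df likelihood-ratio tests.

Throughout, a block of $L$ tightly linked biallelic SNPs (recombination
fraction zero within the block) carries haplotypes $h_1, \dots, h_H$,
$H = 2^L$, with frequencies $p = (p_1, \dots, p_H)$. An individual's unphased
genotype $g$ with $s$ heterozygous SNPs is compatible with
$\max(1, 2^{s-1})$ unordered haplotype pairs; the observed-data likelihood of
a sample of $n$ unrelated individuals is
$\prod_i \sum_{j} P(z_{ij})$, the inner sum running over the pairs
compatible with genotype $g_i$.

## The three pair-probability models

For an unordered pair $(h_k, h_l)$:

* **HWE** — $P = p_k^2$ if $k = l$, $2 p_k p_l$ otherwise.
* **Excess-homozygosity (Niu) model, NM** — homozygous pairs are up-weighted
  by a factor $\theta > 0$ and everything renormalized:
  $P = \theta p_k^2 / C$ (homozygous), $2 p_k p_l / C$ (heterozygous), with
  $C = 1 + (\theta - 1) S$ and $S = \sum_h p_h^2$. The closed form of $C$
  follows from summing the unnormalized weights over all pairs, and the
  package verifies it against the explicit pair sum in its tests.
  $\theta = 1$ recovers HWE.
* **Inbreeding model, IM** — with probability $f$ the individual's two
  haplotypes are identical by descent (one founder draw), otherwise they are
  independent: $P = f p_k + (1 - f) p_k^2$ (homozygous),
  $(1 - f)\, 2 p_k p_l$ (heterozygous). $f = 0$ recovers HWE.

Both alternatives inflate the total homozygous-pair mass, which is the
signature the tests exploit; they are nonetheless distinct families for
$H \ge 2$, so each test has its own favourable regime.

We deliberately leave $\theta$ unconstrained on $(0, \infty)$ rather than
truncating at 1: the sampling distribution of $\hat\theta$ under HWE is
centred at 1 with substantial spread, and truncation would bias the null
fit and distort the LRT. $f$ is clipped to $[0, 1)$; the $f \ge 0$ boundary
is real (negative "inbreeding" is not part of this model family) and is what
makes the inbreeding LRT conservative under the null.

## Fitting algorithms

All three fitters share the same E-step machinery: posterior weights
$w_{ij} \propto P(z_{ij})$ over the pairs compatible with $g_i$, normalized
within individual. Expectation sums are computed over *distinct genotype
classes* with multiplicities rather than per individual — with three SNPs
there are at most 27 classes, which is what makes thousand-replicate
simulation studies cheap without changing any number.

* **EM (HWE)** — the Excoffier-Slatkin gene-counting update
  $p_h \leftarrow \frac{1}{2n} \sum_{ij} w_{ij}\, n_{ij}(h)$, where
  $n_{ij}(h) \in \{0, 1, 2\}$ counts occurrences of $h$ in pair $z_{ij}$.
* **ECM (NM)** — one E-step, then conditional maximizations: first $\theta$
  at fixed $p$, whose stationary point is
  $\theta = m (1 - S) / \{S (n - m)\}$ with $m$ the expected number of
  haplotype-homozygous individuals; then each free frequency $p_h$ in turn,
  with a designated absorbing haplotype carrying the simplex constraint
  $p_H = 1 - \sum_{h \ne H} p_h$. The stationarity condition in
  $x = p_h$ is a cubic; the package derives its coefficients analytically
  (multiplying the derivative by $x (T - x) C(x)$, $T = p_h + p_H$) and
  solves with `polyroot()`, choosing among in-range real roots the one
  closest to the previous value, with a Q-increase safeguard and, should the
  root finder ever fail, a bounded numeric maximization fallback. The test
  suite pins this update against an independent bounded maximizer of the
  conditional objective on random instances.
* **IEM (IM)** — EM on data augmented with the haplotype pair and an
  identity-by-descent indicator. For a homozygous pair $(k, k)$ the
  posterior IBD probability is $b = f / \{f + (1 - f) p_k\}$ (0 for
  heterozygous pairs); the M-step sets $f$ to the mean posterior IBD
  probability, and frequencies to expected draw counts (one draw for IBD
  mass, two otherwise) divided by $2n - \sum w b$.

**Initialization and stopping.** Frequencies start uniform over the
haplotypes appearing in at least one compatible pair of the sample (all
others have MLE 0 under every model and are excluded); $\theta_0 = 1$,
$f_0 = 0.01$. Iteration stops when the observed log-likelihood changes by
less than `tol` ($10^{-6}$ by default, configurable) or after `max_iter`
(1000) iterations. Each algorithm is an (E)CM scheme, so the observed
log-likelihood trace is nondecreasing — a property the suite checks on
hundreds of random data sets. The absorbing haplotype for ECM is the one
with the largest expected count after the first E-step (the initialization
is uniform, so "the most frequent haplotype" needs this one-step
disambiguation); this keeps the constraint carrier away from the simplex
boundary.

**Degenerate inputs.** A genotype whose every compatible pair has
probability zero under user-supplied frequencies is a hard error (support
collapse) naming the offending genotype. If the expected homozygote count
reaches $n$, $\theta$ is unbounded and is capped at $10^3$ with a flag;
$f$ is clipped to $[0, 1)$. Individuals with any missing SNP in a block are
excluded from that block (and counted): enumerating pairs for a partially
missing genotype would require guessing, which the package never does.

## The two tests

$\mathrm{LRT} = 2(\ell_1 - \ell_0)$ comparing the HWE null fit against the
NM fit (`LRT_NM`) or the IM fit (`LRT_IM`), each referred to
$\chi^2_1$. For the IM alternative the $f \ge 0$ boundary means the
asymptotically correct reference is the mixture
$\tfrac12 \chi^2_0 + \tfrac12 \chi^2_1$; the plain $\chi^2_1$ reference is
retained as the default — it is the original proposal, and its conservatism
under the null is part of the published operating characteristics this
package reproduces — with `mixture = TRUE` available. Because the models
are nested, the true statistic is nonnegative; tiny negative values (the
boundary fits converge linearly, so stopping leaves $O(\text{tol})$ slack)
are clamped to zero.

## The simulation engine

`sim_genotypes()` draws each individual's unordered pair exactly from the
model's pair distribution (no rejection step) and emits the induced
genotype; the stratification model draws two independent haplotypes from
subpopulation I with probability $\lambda$, else from subpopulation II.
The built-in generating distributions are a five-haplotype table over three
SNPs ($S = 0.37369$) for the single-population models and a pair of
seven-haplotype tables for the stratification model. `run_study()` crosses
a parameter grid with sample sizes, fits all three estimators per
replicate, and records parameter means/SDs, rejection rates at level
$\alpha$, and the accuracy measure below. One master seed yields
deterministic per-replicate child seeds, so every study is exactly
reproducible.

**Accuracy (SAD).** The sum of absolute differences
$\mathrm{SAD} = \sum_h |p_h - \hat p_h|$ over the union of the generating
and estimated supports, *without* a $\tfrac12$ factor. The unscaled form is
the calibrated one: under HWE at $n = 1000$, phase-known estimation gives
$\mathbb{E}\,|\hat p_h - p_h| \approx \sqrt{2 p_h (1 - p_h) / (2 n \pi)}$,
which sums to $\approx 0.028$ for the built-in distribution — matching the
simulated EM value of $\approx 0.029$ (phase uncertainty adds the sliver),
whereas a half-scaled definition would sit near $0.014$.

**What the generator does and does not emulate.** It produces exactly the
study conditions: unrelated individuals, zero recombination within the
block, no missing genotypes, no genotyping error, and at most two
subpopulations. Passing the reproduction suite therefore demonstrates
correctness of the estimators and tests under those conditions — not
robustness to genotyping error, to related individuals slipping through
founder selection, or to more complex admixture.

## A worked example

```{r example}
g <- sim_genotypes(1000, model = "inbreeding", f = 0.05, seed = 42)
tidy(hwe_lrt(g, alternative = "inbreeding"))
tidy(hwe_lrt(g, alternative = "niu"))
glance(fit_inbreeding(g))
```

A small power study (kept tiny here; the full published grid is
`param = seq(1.0, 1.5, by = 0.05)` by `n = c(500, 1000, 1500)` at 1000
replicates and runs in minutes):

```{r study}
st <- run_study("niu", param = c(1.0, 1.25, 1.5), n = 500,
                n_reps = 100, seed = 7)
select(st, param, n, theta_mean, sad_em, sad_ecm, reject_nm, reject_im)
```

```{r plot, fig.width = 6, fig.height = 3.5}
autoplot(st)
```

## Choices a user may want to revisit

* `tol = 1e-6`, `max_iter = 1000` — stopping rule on the observed
  log-likelihood; tighten `tol` when comparing log-likelihoods across fits
  at finer than $10^{-5}$.
* `report_threshold = 1e-3` — haplotypes below this estimated frequency are
  hidden from block reports (never from the fit itself).
* `min_individuals = 20` — blocks with fewer usable founders are skipped:
  below this the asymptotic $\chi^2_1$ reference is not trustworthy.
* Bonferroni adjustment across blocks is on by default in
  `analyze_blocks()`; the per-test p-values are always reported unadjusted.

## Known limitations

* P-values are asymptotic; no exact or permutation option.
* No standard errors for $\hat p$ (no supplemented-EM machinery).
* Missing genotypes are handled by complete-case exclusion per block, not
  imputation; blocks with heavy missingness lose sample size accordingly.
* Multiallelic markers and X-linked inheritance are out of scope; PED input
  is the supported path (convert VCF upstream).
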