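---
title: "Comparing treatment variances with a control: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing treatment variances with a control: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimvar)
```

## The model and its assumptions

We observe independent samples from $k+1$ normal populations: a control
$N(\mu_0, \sigma_0^2)$ with $n_0$ observations and treatments
$N(\mu_i, \sigma_i^2)$ with $n_i$ observations, $i = 1, \dots, k$.  The
question is one-sided and tree-ordered — every treatment is compared with
the same control, with no ordering among the treatments:

$$H_0: \sigma_i^2 = \sigma_0^2 \;\forall i
  \qquad vs \qquad
  H_1: \sigma_i^2 \le \sigma_0^2 \text{ with at least one strict inequality.}$$

Everything rests on normality: the sample variances $S_i^2$ (divisor
$n_i - 1$) are then the minimal sufficient scale statistics and
$(n_i - 1) S_i^2 = \sigma_i^2 V_i^2$ with $V_i^2 \sim \chi^2(n_i - 1)$
independent.  The group means are ancillary for scale and are discarded;
`normality_screen()` offers a Shapiro–Wilk check of the assumption, but
only advisorily — with the small groups typical of these designs a passing
test is weak evidence, so the screen warns and never blocks.

## The marginal inferential model

Reparameterize through $\theta = \min_i \sigma_i^2 / \sigma_0^2$, so the
hypothesis pair becomes $H_0: \theta = 1$ vs $H_1: \theta < 1$ over the
tree-ordered parameter space.  Under the null's partial information
($\sigma_1^2 = \dots = \sigma_k^2$) the minimum sample variance aligns with
the minimum of the scaled chi-squares, which collapses the $k+1$ auxiliary
variables to a single scalar:

$$\frac{S_0^2}{\min_i S_i^2}\,\theta
  = \frac{V_0^2/(n_0-1)}{\min_i V_i^2/(n_i-1)} =: R .$$

$R$ is free of both the data and the parameters; call its CDF $F$.  An
optimal one-sided predictive random set for the uniform auxiliary variable
$u = F(R)$ yields the plausibility

$$\mathrm{pl}(\theta) = 1 - F(T\theta), \qquad
  T = S_0^2 / \min_i S_i^2,$$

and the decision rule *reject iff* $\mathrm{pl}(1) \le \alpha$.  Because
$F(T)$ is exactly Unif(0,1) under $H_0$, the type I error rate is exactly
$\alpha$ — for any sample-size pattern.  Inverting the plausibility gives
the exact upper confidence bound
$\theta_U = F^{-1}(1-\alpha)/T$ (`mim_upper_bound()`), and the duality
*reject at* $\alpha \iff \theta_U < 1$ holds identically.

For $k = 1$, $R$ is an $F(n_0-1, n_1-1)$ variate and the plausibility is
the classical one-sided F-test p-value; for equal treatment sizes it
coincides with Spurrier's exact p-value
$p = P(F_{(1)} \le c)$, $c = 1/T$.  Both reductions are asserted in the
test suite at 1e−7 and 1e−6 respectively.

## Numerical choices

**Quadrature.**  $F(x)$ is the one-dimensional integral
$\int_0^\infty \prod_i [1 - H_{d_i}(d_i v /(d_0 x))]\, g_{d_0}(v)\, dv$
($H_d$, $g_d$: $\chi^2(d)$ CDF and density).  We do not use a fixed-node
Gauss–Laguerre rule as the production route: with small degrees of freedom
the integrand is sharp and 128–160 Laguerre nodes deliver only ~1e−5
absolute accuracy (the rule is retained internally as a cross-check).
Instead the lower probability half is integrated after the substitution
$u = H_{d_0}(v)$ — which absorbs the chi-square weight and the $d_0 = 1$
endpoint singularity (the $\chi^2(1)$ density is unbounded at 0 but the
substitution removes it, so $n = 2$ groups are supported) — and the upper
half directly on the $v$ scale out to $\infty$, where QUADPACK's
infinite-range transform handles the exponential tail.  Both halves are
split at the integrand's transition region $v \approx d_0 x$ and at deep
chi-square tail quantiles (down to mass 1e−12), so narrow boundary layers
at extreme $x$ cannot be missed; survival factors are always computed on
the upper-tail log scale, never as $1 - \mathrm{pchisq}$.  The certified
absolute error is 1e−8; an error is raised (not silently absorbed) if the
error estimate exceeds it.

**Quantiles.**  $F^{-1}(p)$ starts from ordinary F-distribution quantiles
(which bracket the single-treatment case), expands the bracket
geometrically (factor 8) until it straddles $p$, and finishes with Brent's
method to 1e−10 in $x$ — slightly stronger than plain bisection but with
the same round-trip contract $|F(F^{-1}(p)) - p| \le 10^{-8}$.

**Batch evaluation.**  The uniformity diagnostic needs $10^4$ CDF values
per configuration.  `pl_null_distribution()` therefore uses a fixed
graded-panel Gauss–Legendre rule on the $u$ scale, vectorized across all
replicates, and falls back to the adaptive route for replicates landing in
the far tails (batch estimate outside $[10^{-3}, 1-10^{-3}]$), where a
fixed rule cannot chase the boundary layer.  Agreement with the adaptive
route is asserted at 1e−8 in the tests.

**Degenerate inputs.**  A group with zero sample variance (all values
identical) is rejected at validation: the scale association degenerates
and no plausibility is meaningful.  Ties in $\min_i S_i^2$ need no
tie-break — only the minimal value enters the statistic.

## The simulation harness and what it emulates

`simulation_spec()` + `run_study()` generate replicate studies of
independent normal samples with user-chosen sizes, variances and means.
Defaults follow the stated world of the evaluation: $\alpha = 0.05$,
10,000 replicates (so a valid test should land in the binomial 95% band
(0.0457, 0.0543) around 5%), variance patterns that set the control at 2
and reduced treatments at 1, and size grids between 5 and 32.  Means
default to 0 and are configurable only to demonstrate location invariance
— the statistic is a variance ratio, so shifting means with the same seed
reproduces the identical rejection sequence (tested).

Within a scenario the null distribution $F$ is fixed, so `run_study()`
computes each method's critical value once ($F^{-1}(1-\alpha)$ for the
MIM; inversion of the p-value in $c$ for Spurrier, kept on its own route
so the rep-by-rep equivalence check stays meaningful) and compares the
simulated statistics against it — one quadrature call per scenario rather
than per replicate.  Child seeds are drawn in a single batch under the
master seed and indexed by replicate, making replicates order-independent
and bit-reproducible.

What a green simulation establishes: exact type-I-error control and the
published power levels *under correctly specified independent normal
data*.  What it does not establish: behavior under non-normality, serial
dependence, outlier contamination, or unbalanced heteroscedastic nuisance
structure — none of which the generator emulates.  The real-data screen
exists precisely because the normality assumption is the method's main
vulnerability.

## Design decisions that were genuinely open

- **Direction of the nested-$k$ monotonicity.**  Adding a treatment group
  deepens the minimum in the denominator of $R$, making $R$ stochastically
  larger; hence $F(x)$ is *nonincreasing* in $k$ (equal-df closed form:
  $F(1) = 1/(k+1)$).  The property test asserts this direction.
- **Spurrier integrand scaling.**  The printed form
  $H(x c (m-1)/(n-1))$ admits two readings of where the constant sits; we
  adopted the printed one and pinned it three independent ways: the
  worked-example p-value 0.0117, direct Monte-Carlo simulation of the
  multivariate-F minimum, and the exchangeability identity
  $p(c{=}1, m{=}n) = k/(k+1)$.
- **Plausibility grid.**  Curves default to 400 log-spaced $\theta$ values
  between $F^{-1}(0.001)/T$ and $F^{-1}(0.999)/T$, covering
  $\mathrm{pl} \in (0.001, 0.999)$ whatever the data.
- **Naming.**  The evidence measure is reported as "plausibility" and also
  labelled "p-value (MIM)" in printed output, since the decision rule uses
  it exactly as a p-value.

## Known limitations

- Normality is assumed, not robustly protected against; the Shapiro–Wilk
  screen is advisory only.
- Only the lower one-sided, tree-ordered alternative is covered: no
  two-sided assertions, no simultaneous prediction of several auxiliary
  variables, no mean comparisons.
- Spurrier's route requires equal treatment sample sizes by construction
  and is refused otherwise.
- Monte-Carlo results are reproducible only given the package's own
  seeding scheme; published simulation tables are matched to binomial
  Monte-Carlo error, not digit-for-digit.

## A complete analysis

```{r example}
path <- system.file("extdata", "blood_counts.csv", package = "mimvar")
tab <- read_long_table(path, control = "Control")
summarize_groups(tab)
normality_screen(tab)
st <- as_study(summarize_groups(tab))
mim_test(st, alpha = 0.05)
mim_upper_bound(st, 0.05)
plot(plausibility_curve(st))
```

The unequal group sizes (6, 4, 5) rule out Spurrier's test
(`spurrier_from_study(st)` raises an informative error); the MIM
plausibility of 0.6803 leaves the null standing.

```{r diagnostic, eval = FALSE}
# exact validity, empirically: plausibility is Unif(0,1) under the null
d <- pl_null_distribution(
  simulation_spec(c(5, 6, 7, 8), c(1, 1, 1, 1), reps = 10000, seed = 1))
d$ks
plot(d)
```
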