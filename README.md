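# mimvar

Testing whether any of *k* normal treatment groups is **less variable** than
a control group.

## The problem

In medicine, economics and environmental studies one often compares the
variability of several treatments with that of a control: do smokers show
less spread in testosterone levels than non-smokers; does a drug reduce the
spread of blood counts relative to untreated animals?  With independent
normal samples from a control population (variance σ₀²) and *k* treatment
populations (variances σ₁², …, σ_k²) the hypothesis is the lower one-sided,
tree-ordered pair

    H0: σi² = σ0² for all i   vs   H1: σi² ≤ σ0² with at least one strict <

Equivalently, with θ = min(σ₁², …, σ_k²)/σ₀²: H0: θ = 1 vs H1: θ < 1.

## The methods

**MIM test** (the package's main tool).  A marginal inferential model built
on the associations (nᵢ−1)Sᵢ² = σᵢ²Vᵢ², Vᵢ² ~ χ²(nᵢ−1).  The observed
statistic is T = S₀²/min(S₁², …, S_k²) and the evidence measure is the
*plausibility*

    pl(θ) = 1 − F(T·θ),

where F is the data-free null CDF of the ratio
[V₀²/(n₀−1)] / minᵢ[Vᵢ²/(nᵢ−1)], a one-dimensional chi-square-weighted
integral evaluated by adaptive quadrature to 1e−8.  Reject when
pl(1) ≤ α.  Under H0 the plausibility is *exactly* Unif(0,1), so the type I
error rate is exactly α for any sample sizes — equal or not — and
{θ : pl(θ) > α} is an exact 100(1−α)% one-sided confidence region, giving
the upper bound θ_U = F⁻¹(1−α)/T.

**Spurrier's test**.  The classical optimal test for the equal-sample-size
design (n₁ = … = n_k = m): p = P(F₍₁₎ ≤ c) for the minimum of a
multivariate-F vector, with c = minᵢ sᵢ²/s₀².  For equal sizes the two tests
give numerically identical answers; for unequal sizes Spurrier's test is
undefined and the package refuses it with a pointer to the MIM test.

## Worked example

Testosterone levels (µg/dl) of four groups of ten men — non-smokers
(control), former, light and heavy smokers — ship with the package:

```r
library(mimvar)
path <- system.file("extdata", "testosterone.csv", package = "mimvar")
tab  <- read_long_table(path, control = "Non-smokers")
summarize_groups(tab)
#>           group      role  n  mean variance
#>     Non-smokers   control 10 0.718   0.0520
#>  Former smokers treatment 10 0.663   0.0389
#>   Light smokers treatment 10 0.576   0.0250
#>   Heavy smokers treatment 10 0.432   0.0075

st <- as_study(summarize_groups(tab))
mim_test(st, alpha = 0.05)
#> MIM test of H0: all treatment variances equal the control
#>   statistic T = S0^2 / min Si^2 = 6.967838
#>   plausibility / p-value (MIM) = 0.0117
#>   decision at alpha = 0.05: reject H0 (some treatment variance is smaller)

mim_upper_bound(st, 0.05)
#> [1] 0.6431691
```

The control variance is 6.97 times the smallest treatment variance (the
heavy smokers'), the plausibility of "no treatment is less variable" is
0.0117 ≤ 0.05, and with 95% confidence the smallest treatment-to-control
variance ratio is below 0.64: at least one smoking group is genuinely less
variable.  `spurrier_from_study(st)` gives the same 0.0117.  The second
bundled dataset (`blood_counts.csv`, group sizes 6, 4, 5) is a design
Spurrier's test cannot handle; the MIM test gives plausibility 0.6803 —
no evidence of reduced variability.

Also available: `plausibility_curve()` + `plot()` for the full pl(θ) curve,
`run_study()` for Monte-Carlo type-I-error/power studies,
`pl_null_distribution()` for the uniformity diagnostic, and a CLI:

```sh
Rscript -e 'quit(status = mimvar::run_cli())' test \
  --data inst/extdata/testosterone.csv --control Non-smokers --method both
```

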