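---
title: "Optimal trend tests under heterogeneous genetic effects: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal trend tests under heterogeneous genetic effects: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optrend)
```

## The testing problem

A case-control genetic association study compares genotype frequencies of a
biallelic marker between `r` diseased cases and `s` unaffected controls.
With genotypes aa, Aa, AA indexed by the number of copies `i = 0, 1, 2` of
the A allele, the data are a 2×3 table of counts `r_i` and `s_i` with
genotype margins `n_i` and total `n = r + s`.

The package's central object is the score-based trend chi-square with
scores `(0, c, 1)`:

$$Z(c) = \frac{n\,[\,n\sum_i x_i r_i - r\sum_i x_i n_i\,]^2}
  {r\,s\,[\,n\sum_i x_i^2 n_i - (\sum_i x_i n_i)^2\,]},
  \qquad (x_0, x_1, x_2) = (0, c, 1),$$

asymptotically $\chi^2_1$ under the null of no association for any fixed
real `c`. The familiar Cochran-Armitage test is `Z(0.5)`; `c = 0` and
`c = 1` are the recessive and dominant contrasts. The statistic is invariant
under affine rescaling of the scores, so `(0, c, 1)` is a normalization, not
a restriction: every linear trend contrast corresponds to some `c`, with the
heterozygote-versus-homozygotes contrast `(0, 1, 0)` arising as the limit
`|c| \to \infty`. Testing is two-sided via the upper chi-square tail, with
no continuity correction anywhere; p-values are floored at the smallest
positive double and flagged rather than ever reported as exactly zero.

## The effect model

Five parameters describe the marker's effect and the population it sits in:

| parameter | meaning | range | default |
|---|---|---|---|
| `q` | A-allele frequency among the non-diseased | (0, 1) | — |
| `delta` | Hardy-Weinberg disequilibrium (HWD) coefficient of the non-diseased | admissible for `q` | 0 |
| `rr` | mean allele relative risk RR | > 0 | — |
| `cv_rr` | coefficient of variation of the per-person allele relative risk | ≥ 0 | 0 |
| `gamma` | genetic-model parameter; genotype relative risks `(1, RR^{2γ}, RR²)` | [0, 1] | 0.5 |

`gamma` is accepted on the whole interval: 0 (recessive), 0.5 (gene
dosage) and 1 (dominant) are landmarks of a continuum, not the only choices.

Control genotype frequencies are the HWD-shifted quadratics
$q_i = ((1-q)^2 + \Delta,\; 2q(1-q) - 2\Delta,\; q^2 + \Delta)$.
On the case side, the allele parameter has mean
$\bar p = qRR/(1 - q + qRR)$ and — by a first-order Taylor propagation of
the heterogeneous RR — variance
$\delta = [\bar p(1-\bar p)\,\mathrm{CV_{RR}}]^2$. Under HWE controls and
gene dosage, $\bar p$ is the expected case allele frequency and $\delta$
reappears as HWD induced among the cases, giving the closed form
$p_i = ((1-\bar p)^2 + \delta,\; 2\bar p(1-\bar p) - 2\delta,\;
\bar p^2 + \delta)$ (`case_freqs_special()`).

For general `delta` and `gamma` there is no such shortcut. The package
builds the genotype-frequency map of the cases as a function of the allele
parameter: control frequencies reweighted by the genotype relative risks,
with RR expressed through `p` by inverting the mean formula,

$$g_i(p) = \frac{q_i\,\mathrm{GRR}_i(R(p))}{\sum_j q_j\,\mathrm{GRR}_j(R(p))},
  \qquad R(p) = \frac{p(1-q)}{q(1-p)},$$

and returns the second-order Taylor expectation
$p_i = g_i(\bar p) + \tfrac12 g_i''(\bar p)\,\delta$, renormalized to the
simplex. The construction was chosen because it is exact — not
approximate — in the gene-dosage/HWE case, where the `g_i` are quadratics in
`p` and the second-order expansion terminates; the test suite requires
agreement with the closed form at 1e-8 there. Admissibility
($\delta \le \bar p(1-\bar p)$, all frequencies in [0, 1]) is enforced as a
hard error: silent clamping would corrupt everything downstream.

### Numerical choice: the curvature term

$g_i''(\bar p)$ is computed by Richardson-extrapolated central finite
differences (steps `h` and `h/2`, `h = 1e-3`, shrunk near the interval
edges). A plain second difference at a much smaller step looks more
accurate but is not: the three-point stencil cancels to
$O(\varepsilon/h^2)$ roundoff, about 1e-4 of the curvature at `h = 1e-5`,
while the extrapolated pair at `h = 1e-3` has negligible truncation error
(exactly zero in the quadratic special case) and roundoff near 1e-9. The
unit tests cross-check the stencil against symbolic second derivatives
(`stats::deriv3`) on a grid of models.

## The optimal coefficient

With model-implied `p_i`, `q_i` and design-weighted pooled frequencies
$\bar n_i = (r p_i + s q_i)/n$, define the standardized contrasts
$d_i = (p_i - q_i)/\bar n_i$. The score vector proportional to
$(d_0, d_1, d_2)$ maximizes the expected trend statistic — the standard
optimal-scores result for chi-square trend statistics — and its affine
normalization to `(0, c, 1)` form is

$$c^{\mathrm{opt}} = \frac{d_1 - d_0}{d_2 - d_0}.$$

Two properties matter in practice. First, `c_opt` depends only on the
case:control ratio, not the absolute sample sizes. Second, it is computed
from a-priori parameters only, never estimated from the observed table —
re-using the data to pick `c` would invalidate the $\chi^2_1$ null. The API
keeps the observed table and the model as separate arguments to make this
hard to get wrong.

Because the closed form is a reconstruction, the package carries its own
correctness argument: `optimal_coefficient_numeric()` builds the expected
(real-valued) 2×3 table, scans `Z(c)` on a 1001-point grid over
`[-10, 11]` (generous bounds — heterogeneity pushes `c` modestly outside
[0, 1], and boundary hits raise a warning) and polishes with bounded
golden-section search. The acceptance suite requires
|closed − numeric| < 1e-4 across a 162-point model grid; mirror symmetry
(relabelling the alleles maps `c` to `1 − c`) is tested exactly.

## The summary test

When one parameter set is too much to commit to, `m` candidate coefficients
`c_j` with positive plausibility weights `w_j` combine into a single
statistic $W = \sum_j w_j Z(c_j)$. There is no multiplicity issue because
only `W` is referred to a null distribution.

Under the null each `Z(c_j)` is the square of a standardized score
statistic `U_j`, and `(U_1, ..., U_m)` is asymptotically multivariate
normal with a correlation matrix `R` computable from the pooled genotype
frequencies alone. Hence $W \sim \sum_k \lambda_k \chi^2_1$
asymptotically, with $\lambda_k$ the eigenvalues of
$D^{1/2} R D^{1/2}$, $D = \mathrm{diag}(w)$. Design choices here:

* **Observed pooled frequencies** `n_i/n` feed the null correlation — the
  null-consistent estimate, mirroring how the single-test variance uses the
  margins. (Model-implied pooled frequencies would make the null depend on
  the alternative.)
* Eigenvalues below 1e-12 are clipped to zero; duplicated coefficients
  produce rank deficiency by construction, not by accident. The trace
  identity $\sum_k \lambda_k = \sum_j w_j$ is asserted at 1e-8.
* With `m = 1` the machinery collapses to the single trend test exactly.

### Numerical choice: the mixture tail

$P(\sum_k \lambda_k \chi^2_1 > W)$ is computed by characteristic-function
inversion (Imhof-type): the integrand
$\sin\theta(u)/(u\,\rho(u))$ oscillates with asymptotic half-period
$\pi/(W/2)$ and decays only algebraically, which defeats generic adaptive
quadrature on $[0, \infty)$. The package integrates half-period by
half-period and accelerates the resulting alternating series by repeated
averaging (an Euler transform), reaching absolute accuracy around 1e-10 in
a few dozen terms; unit tests pin it against exact chi-square quantiles, an
independent smooth conditioning quadrature for two-component mixtures, and
large Monte-Carlo draws. If the sum fails to converge, a Satterthwaite
moment-matched scaled chi-square is substituted and the result is labelled
`satterthwaite` — never silently.

## Synthetic data and the power machinery

`sample_counts()` draws cases multinomially at the model-implied case
frequencies and controls at the control frequencies. This is the package's
primary generator and the regime the asymptotic theory targets; it is what
the power and size studies use.

`sample_counts_individual()` is a deliberate antagonist: each case gets a
personal relative risk from a lognormal (default; closed-form moment match
to mean RR and CV, `sdlog² = log(1+CV²)`) or gamma family, and a genotype
with probability proportional to `q_i · GRR_i(RR)`. It makes no Taylor
approximation. The two generators coincide distributionally at `CV = 0`
(tested by goodness of fit), and diverge at strong heterogeneity — at
`CV = 1` the lognormal's heavy tail saturates the AA case share below the
Taylor value — which is exactly what it is for: probing how much of the
optimal test's advantage survives when the working approximation is wrong.
The tests assert the shared qualitative mixture signature (case mass moves
toward the reference homozygote, the heterozygote drains) rather than
numeric agreement.

Neither generator emulates linkage disequilibrium with neighboring markers,
genotyping error, missing genotypes, covariates, or sampling designs other
than independent multinomial case and control draws. Passing simulation
tests therefore says nothing about those complications; they are outside
the model, not approximated by it.

`sample_size_ca()` returns the per-group size for the gene-dosage trend
test from the noncentrality form
$n = (z_{1-\alpha/2}\sigma_0 + z_{1-\beta}\sigma_1)^2 / e^2$ with `e` the
case-control difference in mean scores, $\sigma_0^2$ twice the pooled-score
variance and $\sigma_1^2$ the sum of the case and control score variances,
no continuity correction, rounded up. The formula is accepted on the
strength of simulation calibration, which is part of the acceptance suite:
at the returned `n` for a homogeneous RR = 1.5 alternative, empirical
Cochran-Armitage power over 10,000 replicates must land in [0.77, 0.83].
Had it failed, the continuity-corrected variant would have replaced it; it
did not.

`power_study()` takes a scenario tibble (one row per truth), computes each
"optimal" coefficient once per scenario from the assumed model — never per
replicate from data — and reports empirical power with binomial standard
errors. Scenarios run on independent seeded streams (`seed + row`), so
results are reproducible and independent of row order.

### Problem sizes

Monte-Carlo checks in the test and acceptance suites use 10,000 replicates
per scenario (binomial SE ≈ 0.004 at power 0.8, ≈ 0.002 at size 0.05) and
200,000 draws for the summary-test null comparisons; these sizes make the
envelope tests sharp at desk scale while keeping the full suite in minutes.
The type-I envelope used throughout is the 99% binomial band around the
nominal level.

## Degenerate inputs and edge policies

* Counts must be integers; proportions are rejected, not rescaled — the
  variance term assumes counts.
* A sample concentrated in one genotype has zero pooled score variance:
  hard error, for any `c`.
* In the 2-df Pearson comparator, a genotype absent from the whole sample
  contributes an empty observed and expected cell; the column is dropped
  and the degrees of freedom reduced, with an error only when fewer than
  two genotypes remain. (The alternative — erroring on any empty column —
  would refuse tables that the statistic handles perfectly well.)
* A null effect model (RR = 1, CV = 0) has a flat expected statistic; the
  numeric maximizer refuses it rather than returning an arbitrary grid
  point, and the sample-size calculator reports the size as unbounded.
* Frequency triples are renormalized to sum exactly to 1 after the Taylor
  step (drift is below 1e-10) and all simplex invariants are tested at
  1e-12.

## Known limitations

* The optimal coefficient is only optimal for the supplied model; a badly
  wrong a-priori model can cost power relative to Cochran-Armitage. The
  summary test is the built-in hedge.
* The asymptotic nulls (both $\chi^2_1$ and the eigenvalue mixture) are
  large-sample approximations; no exact or permutation versions are
  provided, and very sparse tables deserve skepticism.
* One biallelic marker at a time: no multi-allelic markers, covariate
  adjustment, stratified variants, or genome-wide multiplicity handling.
* Estimation of `(q, RR, CV_RR)` from external data is out of scope; the
  package consumes those parameters, it does not produce them.
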