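---
title: "Decreasingly informative priors for continuously monitored single-arm trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decreasingly informative priors for continuously monitored single-arm trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diptrial)
```

## The design problem

A single-arm phase II trial asks whether a new treatment clears an efficacy
bar well enough to justify a phase III study. With a likelihood
$f(y \mid \theta)$ and prior $\pi(\theta)$, the hypotheses are
$H_0: \theta \le \theta_0 + \delta_0$ versus
$H_1: \theta > \theta_0 + \delta_0$ (inequalities flipped when lower values
of $\theta$ mean benefit). Monitoring is *continuous*: after every enrolled
subject the posterior probability of benefit is computed and compared with
an upper boundary $p_s$ and a lower boundary $p_f$. The trial stops for
efficacy when the probability is $\ge p_s$, for futility when it is
$\le p_f$, and continues inside the open band, up to a planned maximum of
$N$ subjects. Both boundaries are inclusive, monitoring starts at the first
subject (there is no burn-in; restraining the earliest looks is precisely
the DIP's job), and a trial that exhausts $N$ inside the band is recorded
as inconclusive and counted as *not* rejecting $H_0$. That terminal
convention is a genuine design choice — no separate final-analysis rule is
defined — and it is recorded explicitly so a sensitivity analysis can flip
it.

Continuous Bayesian monitoring is attractive but fragile: with a flat or an
optimistic prior, a lucky first handful of subjects can push the posterior
probability over $p_s$ and stop the trial almost immediately, inflating the
type I error.

## The decreasingly informative prior

The DIP counters exactly that failure mode. It is a skeptical prior centred
at the null value whose *effective sample size* (ESS) is tied to the
unobserved sample size $N - n$: worth $N$ hypothetical null observations at
enrolment, none at completion. The total information in the posterior is
then roughly constant over the trial — what the likelihood gains, the prior
gives up — so early looks are restrained and the final analysis is driven
by data alone.

The conjugate constructions, with ESS conventions `a + b` (beta), the rate
(gamma in shape/rate form) and $s^2/\tau^2$ (normal with known sampling SD
$s$):

| Outcome | DIP prior | Posterior after $n$ subjects |
|---|---|---|
| Bernoulli($p$) | Beta$(1 + p_0(N-n),\; 1 + (1-p_0)(N-n))$ | Beta$(1 + p_0(N-n) + y,\; 1 + (1-p_0)(N-n) + n - y)$ |
| Poisson($\lambda$) | Gamma$(0.5 + \lambda_0(N-n),\; 0.001 + (N-n))$ | Gamma$(0.5 + \lambda_0(N-n) + y,\; 0.001 + N)$ |
| Normal($\mu$, $s^2$ known) | N$(\mu_0,\; s^2/(N-n))$ | N$\big(\tfrac{N-n}{N}\mu_0 + \tfrac{n}{N}\bar y,\; s^2/N\big)$ |

Three structural consequences are worth noting (each is a test in the
package): at $n = N$ every DIP posterior equals the corresponding
non-informative-prior posterior — Beta$(1+y, 1+N-y)$, Gamma$(0.5+y,
0.001+N)$, N$(\bar y, s^2/N)$; the ESS telescopes,
$\mathrm{ess}(n) + n = \mathrm{ess}(0)$ at every look; and the gamma
posterior rate ($0.001 + N$) and normal posterior variance ($s^2/N$) are
constant over the whole trial.

### Numerical and parameterisation choices

* **Beta centring.** Mode-centring and mean-centring both lead, after the
  adjustment that keeps the prior proper and exactly non-informative at
  $n = N$, to the same working form $a = 1 + p_0(N-n)$,
  $b = 1 + (1-p_0)(N-n)$. That form is the canonical DIP beta here. The
  strict mode-centred variant (pseudo-count $N-n-2$, floored at 0 to stay
  proper) is exposed as `centering = "mode"` / flavor `"dip_mode"` for
  comparison but is used nowhere in the benchmark replications, because the
  source of the published tables does not distinguish the two and the
  canonical form is the one whose printed posterior the tables quote.
* **Gamma parameterisation** is shape/rate, not shape/scale: only under the
  rate convention is the rate the ESS and Gamma(0.5, 0.001)
  near-non-informative.
* **Normal endpoint cases.** At $n = N$ the DIP prior variance
  $s^2/(N-n)$ is undefined; the posterior is computed directly from its
  closed form, which is well defined there (and at $n = 0$, where it
  returns mean $\mu_0$, variance $s^2/N$ — needed so monitoring code has a
  value before any data exist). `prior_params()` at $n = N$ returns the
  fully diffuse prior (infinite variance, ESS 0), keeping the telescoping
  identity exact.
* **Tails.** Posterior tail probabilities use `lower.tail` switching rather
  than `1 - CDF`, avoiding cancellation when the probability is near 1.
* **Two roles of $\delta_0$.** The testing margin (in
  `efficacy_probability()` and `trial_design()`) and the Thall–Simon prior
  centring offset ($\text{mean} = p_0 + \delta_0/2$) are independent
  inputs; the benchmark settings set the testing margin to 0.

## Operating characteristics

`estimate_oc()` replicates `simulate_trial()` `R` times (default 1000,
matching the usual simulation templates). Power is the rejection proportion
at $\theta_1$, type I error the same proportion at $\theta_1 = \theta_0$.
Each replicate runs on a deterministically derived seed
(`(seed * 1009 + replicate) mod (2^31 - 1)`), so results do not depend on
how replicates are batched.

For Bernoulli designs the stopping decision at look $n$ depends on the data
only through the success count $y$, so the full operating characteristics
can be computed *exactly* in $O(N^2)$ by propagating continuation
probability mass over the states $(n, y)$ (`exact_oc_bernoulli()`). The
exact recursion is validated against exhaustive enumeration of all $2^N$
outcome sequences for small $N$, and the Monte Carlo engine is validated
against the exact recursion (agreement within 3 Monte Carlo SEs). No such
recursion is provided for the Poisson family (the cumulative count is
unbounded) or the normal family (continuous statistic); those are
cross-checked by boundary tabulation (`boundary_table()`, discrete
families) and forced-stream scan oracles instead.

## Admissible-design search

`search_smallest_admissible()` scans $N \in \{10, \dots, 100\}$,
$p_s \in \{0.80, \dots, 0.99\}$, $p_f \in \{0.01, \dots, 0.10\}$ (ranges
inclusive; steps 1 and 0.01 — every published boundary value has two
decimals, so finer steps are unidentifiable from the reports) for the
smallest $N$ carrying an *admissible* design: power $\ge 0.80$ and type I
error $\le 0.05$. Estimates are compared with the thresholds as point
estimates. Ties at the minimal $N$ — the selection rule leaves this open —
are broken deterministically: highest power, then lowest type I error, then
highest $p_s$, then lowest $p_f$; the selection is therefore independent of
grid iteration order. When no point is admissible, one of two fallback
rules fires: lowest type I error among points reaching the power floor, or
(when the floor is unreachable) highest power with, among powers within one
Monte Carlo SE of the maximum, the lowest type I error.

Two backends are available: `"monte_carlo"` (any family; fresh per-point
substreams by default, since reusing one outcome stream across grid points
— the other mode a published search may have used — only changes which
near-tied point wins by noise) and `"exact_dp"` (Bernoulli only;
deterministic, so the admissible set is exact and minimality can be
verified by enumeration).

A consequence worth stating plainly: published minimal-$N$ tables produced
by a Monte Carlo search inherit *selection bias*. A marginal grid point is
selected precisely when its estimated power clears 0.80, so printed powers
at marginal designs overestimate the truth (for instance, the exact type I
error of the published Bernoulli DIP design $N = 22$, $p_f = 0.02$,
$p_s = 0.98$ is 0.0577, slightly above the nominal 0.05 it was selected
under; the exact-backend minimal admissible $N$ for that scenario is 24).
Fresh-seed replications of such rows are expected to undershoot by one to
two Monte Carlo SEs.

## What the simulator does and does not emulate

Outcomes are drawn i.i.d. from the stated parametric families at fixed
true parameters — the same stated world the published tables assume. Real
trials add drift over calendar time, heterogeneity across subjects,
delayed or missing outcomes between enrolment and assessment, and deviations
from the parametric form; none of these are modelled, so a green operating
characteristic here certifies the decision rule under the stated sampling
model, not robustness to those departures. Cohort (batched) monitoring and
two-arm randomised comparisons are likewise out of scope.

## Worked example

```{r example}
design <- trial_design(
  "bernoulli", theta0 = 0.1,
  prior = prior_spec("beta", "dip", null_center = 0.1, planned_N = 22),
  N = 22, p_s = 0.98, p_f = 0.02)

exact_oc_bernoulli(design, theta_true = 0.30)  # power, exactly
exact_oc_bernoulli(design, theta_true = 0.10)  # type I error, exactly
estimate_oc(design, theta_true = 0.30, R = 1000, seed = 1)

boundary_table(design)[4:8, ]
```

The boundary table shows the restraint in action: no success count can
trigger efficacy before the fourth subject, whereas under a flat Beta(1, 1)
prior a single first-subject success would already push the posterior
probability to 0.99.

## Known limitations

* The exact backend covers only the Bernoulli family; Poisson and normal
  searches are Monte Carlo and inherit MC noise at the admissibility
  boundary (an optional strict mode tightening thresholds by one SE is the
  natural extension and is deliberately not the default, to match the
  published practice of comparing point estimates).
* Single-parameter conjugate models only; no MCMC path for non-conjugate
  priors, and prior ESS is defined by the closed-form conjugate identities,
  not by general expected-local-information-ratio computation.
* The run-configuration format is JSON, not YAML (no YAML parser among the
  package's dependencies); the schema is flat and flag-overridable.
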