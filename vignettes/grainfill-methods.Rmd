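---
title: "Grain-filling kinetics with the Richards equation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grain-filling kinetics with the Richards equation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainfill)
library(dplyr)
```

## The growth model

Grain dry weight after anthesis is modelled by the Richards (generalised
logistic) equation

$$W(t) = A\,(1 + B e^{-Kt})^{-1/N},$$

with $t$ in days after panicle labeling, $W$ in mg per grain, final weight
$A > 0$, position constant $B > 0$, rate constant $K > 0$ (day$^{-1}$) and
shape parameter $N > 0$. The model assumes a single smooth sigmoid
accumulation per grain class: no transient stalls, no late re-mobilisation,
no double sigmoid. The shape parameter absorbs the asymmetry of the curve;
$N = 1$ recovers the logistic, $N \to 0$ approaches the Gompertz-like
extreme where the inflection sits very early relative to $A$.

The grain-filling rate is the exact time derivative,

$$\mathrm{GFR}(t) = \frac{AK}{N}\, u\,(1+u)^{-(N+1)/N},
  \qquad u = B e^{-Kt},$$

implemented in `filling_rate()`. From it the characteristics reported by
`filling_characteristics()` follow in closed form: the rate peak
$T_{max} = (\ln B - \ln N)/K$ at height
$\mathrm{GFR}_{max} = AK(1+N)^{-(N+1)/N}$ and weight
$W_{max} = A(N+1)^{-1/N}$, the average rate
$\mathrm{GFR}_{avg} = AK/(2(N+2))$, and the initial relative growth rate
$R_0 = K/N$. $\mathrm{GFR}_{avg}$ is used as printed in the agronomic
literature this package follows; we do not attach an averaging-interval
interpretation to it.

## Conventions the literature leaves open

Three quantities have no universally fixed definition; the package adopts
one convention each and exposes it.

**Active grain-filling duration (GFD).** Defined here as the time for the
fitted curve to reach a fraction $p$ of $A$, inverted in closed form by
`time_to_fraction()`; $p$ defaults to 0.99. Against self-consistent
published characteristic tables for high-latitude japonica cultivars this
convention agrees to 1–3%, which is within the rounding of two-decimal
parameter estimates. $p$ is configurable (`gfd_fraction`, constrained to
$(0.9, 0.9999)$) but the default is the package's fixed convention.

**Initial growth rate $R_0$.** Taken as $K/N$, the relative growth rate
$\dot W / W$ in the small-$W$ limit. This reproduces the published
initial-growth comparisons (e.g. 0.45 vs 0.40 for superior grains of the
same cultivar at two sites, which are $0.24/0.55$ vs $0.60/1.52$).

**Sub-phase boundaries $t_1, t_2$.** The start/middle/late decomposition
uses the inflection points of the *rate* curve, i.e. the zeros of
$d^3W/dt^3$ — the standard convention in growth analysis. In terms of $u$
they solve $u^2 - N(N+3)u + N^2 = 0$, so
$u_\pm = \tfrac{N}{2}[(N+3) \pm \sqrt{(N+1)(N+5)}]$ and
$t_i = (\ln B - \ln u_i)/K$. Because $u_+ u_- = N^2$, the boundaries are
symmetric about the peak: $t_1 + t_2 = 2T_{max}$. The middle-phase share
$\bigl(W(t_2)-W(t_1)\bigr)/A$ depends on $N$ only and evaluates to
$1/\sqrt3 \approx 0.577$ at $N=1$ and to $\approx 0.60$ for the small $N$
typical of superior grains — consistent with published reports that the
middle sub-phase contributes close to 60% of final grain weight. Published
per-year sub-phase percentages that sum to more than 100% (e.g. 38.17 +
60.05 + 28.91) evidently use heterogeneous denominators; the package
implements only the per-curve fractional definition, whose three parts plus
the weight already present at $t=0$ sum to exactly 1.

Some characteristic tables also list a column "D, days to the maximum
grain-filling rate" alongside $T_{max}$ without defining the distinction;
the package emits only its own defined quantities and treats such a column
as the filling-duration alias when mapping outputs onto that layout.

**Degenerate rate peaks.** Parameter sets with $B \le N$ place the analytic
rate peak at or before $t = 0$. These occur in real fits of slowly
saturating series (several published Qiqihar superior-grain rows have this
property, which is irreconcilable with the positive peak times printed
alongside them). `filling_characteristics()` flags such rows with
`pre_anthesis_maximum` and still reports every quantity rather than
failing: the flag, not an error, is the honest description of a fit whose
fastest growth precedes the observation window.

## Fitting

`fit_richards()` minimises the unweighted residual sum of squares of
weight — no weighting scheme is assumed for the measurement error — with
bounded Levenberg–Marquardt (`minpack.lm::nls.lm`), gradient/step
tolerances of $10^{-10}$ and at most $10^4$ function evaluations. Default
bounds are $A \in (0, 3\max W]$, $B \in (0, 10^4]$, $K \in (0, 5]$
day$^{-1}$, $N \in [0.01, 10]$: generous relative to any realistic grain
curve, tight enough to stop the optimiser wandering off the data's scale.

The deterministic start is `init_guess()`: $A_0 = 1.05 \max W$, $N_0 = 1$,
and $(B_0, K_0)$ from ordinary least squares of $\ln(A_0/W - 1)$ on $t$
over observations with $0 < W < A_0$, floored at $B_0 \ge 0.1$,
$K_0 \ge 0.01$. The linearisation is deliberately crude — inflating $A_0$
above the true asymptote biases the late points, so $B_0$ and $K_0$ can be
well off the truth — but it reliably lands in the correct basin: started
from it, noise-free series are recovered to $10^{-4}$ relative.

Because the Richards likelihood has a flat ridge trading $A$ against $N$
(and $B$ against $K$ near-degenerately when the curve saturates early),
the fit is multi-start: the deterministic start plus `multistart - 1`
log-normal perturbations of it (sd 0.3 on the log scale) from a seeded
stream. The lowest-SSE converged start wins; ties within $10^{-10}$
relative SSE are broken by smallest $N$, then smallest $B$, so results are
reproducible to the bit for a fixed seed. Solutions touching a bound are
flagged `boundary_hit`, converged starts disagreeing by more than 1% in
SSE `multistart_disagreement`; neither is rejected, mirroring how
near-degenerate fits are reported rather than censored in published
parameter tables.

$R^2$ is $1 - \mathrm{SSE}/\mathrm{SST}$ with centred SST, clipped to 0
only within $10^{-10}$ of numerical noise. Note that for near-plateau
series (the degenerate rows above) SST itself is mostly measurement noise,
so a modest $R^2$ there reflects the geometry of the series, not a fitting
failure; the residual SSE still sits at the noise level.

## Association analysis

`trait_correlations()` reports plain Pearson $r$ over pairwise-complete
rows with the two-sided $t$-based p-value on $n-2$ degrees of freedom;
`partial_correlation()` correlates OLS residuals after projection on the
controls plus intercept, with $n - 2 - k$ degrees of freedom. Choices:

* linear (Pearson) correlation is the primary tool, matching how
  filling-characteristic/trait relationships are reported in this
  literature; `quadratic_trend()` is provided for screening curvilinear
  relationships but fits no binomial GLM;
* no multiple-testing correction by default (matching common practice in
  the field's tables); `adjust = "BH"` is available;
* $\alpha$ defaults to 0.05 and the `significant` flag is exactly
  `p_value < alpha`;
* zero-variance pairs yield `r = NA` with no significance call;
  pairwise-complete deletion handles missing values.

With the $n = 32$ unit set of the default study design the critical $|r|$
at $\alpha = 0.05$ is about 0.35; with $n = 4$ cultivar means (as in
published region-year tables) it is about 0.95, which is why only
near-perfect correlations are starred there. The package computes over
whatever unit set the caller supplies.

## The synthetic-data generator

`default_scenario()` emulates the reference study design: 4 japonica
cultivars × 2 Heilongjiang sites × 2 years × 2 grain classes = 32 series,
with true parameters set to the published estimates in
`richards_reference_params()`, sampling at days 1, 5, 10, …, 45 after
labeling, and multiplicative Gaussian noise with relative sd 2%. The noise
level follows from the reported fit quality: uniformly $R^2 \ge 0.977$ on
10-point series implies residuals of a few percent of signal. Additive
noise and per-day replicates are supported; negative simulated weights
(possible under additive noise) are clipped to zero with a warning.

Environment covariates are per-(cultivar, site, year) grain-filling-stage
means (`site_environment()`): temperature, sunshine, radiation, humidity
and soil temperature. No daily weather is generated and no mechanistic
temperature-to-parameter response is modelled — the covariates are
constants available to the trait linkage.

Trait tables are generated by a linear linkage: each trait is an intercept
plus a small named linear combination of the unit's *true* characteristics
and environment covariates plus Gaussian noise, clipped to its valid range
(percentages to $[0,100]$, seed set to $[0,1.2]$). The default linkage is a
documented stand-in, not a biological claim: grain yield increases with $A$
and $\mathrm{GFR}_{avg}$, chalkiness increases as GFD shortens, amylose
tracks mean temperature, protein tracks humidity, 1000-grain weight tracks
$A$, seed set tracks the middle-phase share; milling percentages and
length–width ratio are intercept-only. Intercepts and coefficients were
chosen once, from the cross-correlation structure of the 32 true parameter
sets, so that site-level means land in realistic ranges for high-latitude
japonica (yield ≈ 9500–10800 kg ha$^{-1}$, amylose ≈ 14–22%) and every
nonzero link is detectable at $n = 32$.

What passing tests on this generator do **not** show about real data: the
generator has no replicate-plot structure (real studies average blocks of
labeled panicles), no within-panicle heterogeneity, no non-Gaussian or
day-dependent measurement error, no weather-driven parameter variation,
and its trait linkage is linear by construction — so recovery of the
injected signs validates the pipeline's plumbing and power at the study's
scale, not any agronomic hypothesis.

## Numerical notes

* For extreme parameters the weight curve saturates in double precision:
  $W$ underflows to 0 far before the rise and equals $A$ exactly far
  after. Properties like strict monotonicity therefore hold on the
  representable range (tests probe between the 0.1% and 99.9% quantile
  times of each curve).
* `time_to_fraction()` is the exact closed-form inverse; round-trips hold
  to $10^{-9}$ relative.
* The tie-break rule (smallest $N$, then $B$) resolves exact SSE ties on
  the $A$–$N$ ridge deterministically.
* All simulation and fitting randomness flows from explicit integer seeds
  through isolated RNG scopes; the trait stream is decoupled from the
  series stream (seed offset by one) so adding traits never perturbs the
  simulated weights.

## Problem sizes used by the test suite

The suite's stochastic harnesses use sizes chosen to make the checked
quantities stable at the asserted tolerances on a single CPU: 100-replicate
Monte-Carlo parameter recovery at 2% and 5% noise (median relative error of
$A$ within 2% and 5%, of $T_{max}$ within 5% and 10%), 100 random
parameter sets with $N \in [0.05, 5]$ for the analytic-vs-numeric oracle
equivalence at $10^{-6}$, 1000–2000 seeded null replicates for the
type-I-error check of the significance flag (rejection rate within
3–7% at $\alpha = 0.05$), and the full 32-series end-to-end closure at the
default noise level.

## Known limitations

* One growth law: no Gompertz/Weibull alternatives, no model selection,
  and no mechanistic temperature-driven rate models.
* Single-curve fits: replicate plots are pooled or pre-averaged
  (`average_replicates`), not modelled hierarchically; no mixed-effects
  pooling across cultivars.
* The inferential layer is deliberately minimal (Pearson/partial
  correlation at caller-defined unit sets); it inherits the usual caveats
  of small-$n$ correlation screens.
* For series observed only near the plateau the Richards parameters are
  weakly identified; the package reports the flags (`boundary_hit`,
  `pre_anthesis_maximum`, `multistart_disagreement`) and leaves judgement
  to the analyst.
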