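---
title: "Estimating comorbidity risk from a single cross-sectional survey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating comorbidity risk from a single cross-sectional survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbidrisk)
```

## The problem

Incidence of chronic disease — the probability that a person free of a
disease develops it within a year — is usually estimated from longitudinal
registries. For elderly populations such registries are scarce, while
cross-sectional prevalence surveys are abundant. `comorbidrisk` implements a
pipeline that extracts age- and sex-specific one-year onset probabilities,
*conditional on the person's current combination of other chronic diseases*,
from a single survey wave plus a life table, and summarizes how much each
combination of "basic" (already present) diseases raises the onset risk of a
"target" disease relative to full health.

The pipeline has four stages:

1. **Hypothetical cohort.** Each observed age group is back-cast to an
   anchor age (65) with survey-year mortality and rescaled, so the age axis
   of one survey can be read as the time axis of a single cohort.
2. **Network screening.** A disease co-occurrence network reduces the
   dimensionality: only diseases whose weighted degree lies above the mean
   enter the multistate analysis.
3. **Multistate transition model.** For every pair of screened diseases, a
   2×2 joint prevalence table per age is "inverted": survivors expected
   after mortality are compared with the next age's populations, and the
   differences are decomposed into onset flows. Pairwise rates are
   aggregated into conditional incidence for each of the `2^m` comorbidity
   states by a population-weighted average.
4. **Marginal risk.** For each target disease and state, the age-wise
   difference to the healthy-state incidence is summarized as a mean with a
   95% interval, ranked, chained into maximum-impact sequences, and scanned
   for mutually amplifying disease pairs.

## Hypothetical cohort

Let $p_i(t)$ be the surveyed number of survivors at age $i$ and $s_i(t)$
the survey-year death probability at age $i$. The cohort currently aged
$a$ had, at the anchor age,

$$\hat p_{65}^{(a)} = \frac{p_a(t)}{\prod_{j=0}^{a-66}\bigl(1-s_{65+j}(t)\bigr)},$$

and the scaling rate $w_a = p_{65}(t)/\hat p_{65}^{(a)}$ (with $w_{65}=1$)
aligns every age group to the anchor population. Scaling is applied to the
*state counts* (one count per joint disease combination per age and sex),
never by resampling individuals, so counts become real-valued and
within-age prevalence — joint as well as marginal — is untouched. Two exact
identities are enforced by tests: forward-projecting the ancestors with the
same life table reproduces the observed counts, and a stationary population
generated from the life table yields $w_a \equiv 1$.

The terminal open age band (105+) is treated as a single terminal age; no
back-cast reaches beyond it. An optional 3-point moving average over age
(`build_cohort(smooth = TRUE)`) is provided for noisy surveys but is off by
default: a smoother changes the estimand, and no canonical choice exists.

## Network screening

For one sex stratum, the weight of the edge between diseases $i$ and $j$
is the number of individuals carrying both; a node's weighted degree $x$
is the sum of its incident weights. Degrees are standardized as
$z = (x-\mu)/s$ where $s$ is the **population** (divisor-$n$) standard
deviation — recomputation of published degree tables confirms this
convention (the divisor-$(n-1)$ form does not reproduce the printed
values). Screening keeps diseases with $z>0$, i.e. degree strictly above
the mean; degrees are computed from raw survey counts, not scaled cohort
counts, because integer published degrees are only consistent with raw
co-occurrence counts. Ties at exactly the mean would be excluded; they do
not occur in practice.

## Multistate transition model

Assumptions, in the package's terms:

* **Absorption.** Chronic diseases are never left once entered.
* **Additive mortality.** An individual's annual death probability is the
  base rate $\alpha_{base}(s,t)$ plus the sum of the excess rates
  $\alpha_d$ of all their current diseases, capped at 1 (validated).
* **Period-cohort reading.** Consecutive ages of the hypothetical cohort
  are treated as consecutive years of one cohort.

For diseases $(i,j)$ the four cell populations
$pop_t(d_i,d_j)$ are reduced by mortality to survivors $surv_t$, and the
balance against $pop_{t+1}$ yields the flow system: with $a,b$ the onsets
of $i$ and $j$ out of $(0,0)$ and $c,d$ the comorbid onsets out of
$(1,0),(0,1)$,

$$a+b = surv_t(0,0)-pop_{t+1}(0,0),\quad
  a-c = pop_{t+1}(1,0)-surv_t(1,0),\quad
  b-d = pop_{t+1}(0,1)-surv_t(0,1).$$

### The closure

The system is under-determined by one degree of freedom: the healthy-cell
balance fixes only $a+b$. The package closes it by splitting $a:b$ in
proportion to the *marginal* onset counts of $i$ and $j$ — the collapsed
single-disease tables identify those uniquely. This closure uses only
quantities the data identify, reduces to the truth when either disease has
no onsets, and keeps the $(1,1)$-inflow identity $c+d =
pop_{t+1}(1,1)-surv_t(1,1)$ exact. It is an interpretation, not a
data-determined fact; it is exact whenever the two diseases' onset
patterns are exchangeable within the healthy cell, and the
parameter-recovery tests quantify its bias when they are not.

### Mortality resolution

The pair-cell survivor formula uses only $\alpha_{base}, \alpha_i,
\alpha_j$ — but a pair cell contains individuals who carry *other*
diseases, whose excess deaths the formula then misattributes to onsets.
Because the joint cohort over all screened diseases is always available
here, `build_surface()` defaults to `mortality = "state"`: survivors are
computed per full joint state (the additive assumption applied to each
individual's complete disease set) and then marginalized into pair cells.
This makes the estimator an exact inverse of the forward process; the
literal pair-cell form (`mortality = "pair"`) is retained for sensitivity
analysis, and on oracle data its error is of order
$\alpha_{\text{out-of-pair}} \times$ (out-of-pair prevalence share) — the
tests assert that bound rather than hiding it.

### Aggregation to m-dimensional states

The conditional incidence of target $k$ in state
$(d_1,\dots,d_m)$ ($d_k=0$) is the weighted average over partners $l \ne k$
of the pairwise rate of $k$ out of cell $(0,d_l)$, weighted by that cell's
population. With $m$ diseases this yields $2^{m-1}$ states per target and
$2^m$ states overall (128 for seven diseases, 64 for six). The weighted
average is a projection, not a full joint model: it reproduces any
pairwise-consistent truth exactly (verified on oracle cohorts) but cannot
express interactions invisible to all pairwise margins.

### Numerical policy

Negative solved flows — sampling noise, or genuinely non-monotone
prevalence such as the dip real surveys show in the late 90s — are clipped
to zero and counted; rates are clipped to $[0,1]$; flows out of an empty
source cell are flagged missing (`NA`), not zero, and flagged terms are
dropped from the Eq-style weighted average. Flag and clip counters surface
in the run report, so a silent degradation is impossible.

## Marginal risk

For target $k$ and state $d$, the difference series is
$\Delta_t = inc_t(d) - inc_t(\text{healthy})$ over the ages where both are
unflagged. The marginal risk is $\bar\Delta$; the default 95% interval is
the t-interval over age points, with a seeded nonparametric bootstrap over
ages as an alternative — the construction behind published comorbidity
tables is unstated, so both are provided and the choice is explicit in the
API. Lag-1 autocorrelation and the linear age trend of each series are
reported (`series_diagnostics()`) but never enforced: the mean is the
estimand regardless, and the diagnostics tell the analyst how honest the
"stationary sequence" reading is.

Maximum-impact chains default to **nested** construction (each step adds
the single disease that most raises the mean difference), matching the
additive column structure of published tables; **exhaustive** per-size
argmaxes are available, and the exhaustive chain dominates the nested one
by construction — a property the tests assert. Ties break by disease-list
order. Mutual-impact pairs are the pairs of diseases that are each other's
single-basic argmax.

## The synthetic generator and the oracle

The generator emulates the structure the estimator assumes — it does not
fit any real survey's margins:

* ~12,000 records, ages uniform on 65–105 with 105 an open band, 44.58%
  male;
* disease indicators from a pairwise log-linear (Ising) model per age:
  pairwise log-odds are the model parameters themselves, and main effects
  are calibrated by an exact fixed point on the enumerated state space so
  marginal prevalence follows `baseline + slope*(age-65)`; sampling is by
  per-subject Gibbs sweeps with a 50-sweep burn-in;
* default prevalence anchored at 0.8× the published overall proportion per
  disease with slope 0.01× per year — age-increasing, cross-sectionally
  near the published values; pairwise log-odds 0.4 among the seven
  high-degree diseases and 0.1 elsewhere, so the network stage has signal
  to find; Gompertz base mortality `0.015*exp(0.095*(age-65))` (about 1.5%
  at 65, ~50% near 102), excess mortality 1% per disease with larger
  values for cancer, stroke, dementia and the cardiovascular group.

What it deliberately does **not** reproduce: CLHLS's oversampling design
and nonuniform age pyramid, sex-specific prevalence, cohort effects,
reporting error, and any real-data association structure. Passing tests
therefore demonstrate correctness of the *machinery* under the model's own
assumptions, not the accuracy of any real-population estimate.

The **oracle simulator** is the generator's deterministic counterpart:
expected-count forward simulation over the full joint state space with
known per-state hazards, base and additive excess mortality, both deaths
and onsets drawn from start-of-interval populations. It conserves counts
to machine precision and records nothing the estimator sees —
`true_pairwise_rates()` recomputes the truth from the hazard function and
the state surface, an independent path from the estimator's
prevalence-inversion. Recovery tests use *exchangeable* scenarios
(identical superadditive count-dependent hazards, identical excess
mortality, permutation-symmetric initial populations): exchangeability is
precisely the condition under which the proportional closure is exact, so
the estimator must match truth to ~1e-15, and does. Non-exchangeable
bias and the pair-mortality bias are asserted against explicit bounds.

## Problem sizes and defaults used in the test-suite

Recovery and amplification fixtures use 3–4 diseases over ages 65–90 with
initial populations of 10,000 expected individuals; generator-based tests
use 1,000–50,000 records and 2–4 diseases; the end-to-end pipeline test
uses 4,000 records, four diseases, ages 65–85. These sizes make every
binomial tolerance in the tests meaningful while keeping the whole suite
around a quarter of a minute.

## Known limitations

* The closure and the pairwise aggregation are identification choices; on
  real data their bias is unquantifiable without longitudinal validation.
* Excess mortality inputs must be supplied; published analyses of this
  design typically do not print theirs, so real-data cell values are not
  reproducible and are not claimed.
* Counts are expected values; no uncertainty is propagated from the life
  table or the survey's sampling design into the incidence surface (the
  interval construction only reflects age-to-age variation).
* Remission, multi-wave linkage and higher-order (beyond pairwise) network
  structure are out of scope.
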