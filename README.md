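# comorbidrisk

Chronic-disease **incidence under comorbidity, from a single
cross-sectional survey**. For epidemiologists and health-systems modellers
who have one prevalence survey of an elderly population (one row per
respondent: age, sex, a 0/1 indicator per chronic disease) plus a life
table — but no longitudinal registry — and who want age- and sex-specific
one-year onset probabilities of each disease *conditional on which other
diseases are already present*, and the marginal risk each "basic" disease
combination adds over full health.

## The model

**Hypothetical cohort.** With survey-year death probabilities $s_i(t)$ and
observed survivors $p_i(t)$, each age group $a$ is back-cast to the anchor
age 65,

$$\hat p_{65}^{(a)} = p_a(t) \Big/ \prod_{j=0}^{a-66}\bigl(1 - s_{65+j}(t)\bigr),
\qquad w_a = p_{65}(t)/\hat p_{65}^{(a)},$$

and every joint disease-state count at age $a$ is multiplied by $w_a$, so
the survey's age axis becomes the time axis of one cohort.

**Network screening.** Disease pair weight = number of individuals with
both diseases; weighted degree $x$ = sum of incident weights;
$z = (x - \mu)/s$ with $s$ the population (divisor-$n$) standard deviation.
Diseases with $z > 0$ (degree above the mean) are analyzed; typical
surveys of Chinese elderly yield seven such diseases in men and six in
women, i.e. $2^7 = 128$ and $2^6 = 64$ comorbidity states.

**Multistate transitions.** Diseases are absorbing; an individual's annual
death probability is base mortality plus the sum of their diseases' excess
mortalities. For each disease pair, expected survivors
$surv_t(d_i, d_j)$ are compared with the next age's populations, and the
cell balances are solved for the onset flows; the under-determined split of
the healthy cell's outflow between the two diseases is closed in proportion
to the marginal single-disease onset counts. Conditional incidence of
target $k$ in state $(d_1,\dots,d_m)$, $d_k = 0$, is the pair-population
weighted average

$$\frac{\sum_{l \ne k} r_k^{(k,l)}(0, d_l)\, pop^{(k,l)}(0, d_l)}
       {\sum_{l \ne k} pop^{(k,l)}(0, d_l)}.$$

**Marginal risk.** Per target and state: mean over ages of
(state incidence − healthy incidence), with a 95% t-interval over age
points (seeded bootstrap optional), ranks per basic-disease count, nested
maximum-impact chains, and mutual-impact pairs.

A synthetic survey generator (pairwise log-linear indicator model with
exactly calibrated age-dependent marginals) and a deterministic
expected-count oracle simulator make every stage testable without any
restricted microdata; see the methods vignette
(`vignettes/comorbidity-risk-methods.Rmd`).

## Worked example

Screen diseases from a published weighted-degree table, then estimate and
summarize risk on a three-disease oracle cohort with superadditive
hazards:

```r
library(comorbidrisk)

deg <- read.csv(system.file("extdata", "clhls2018_weighted_degrees.csv",
                            package = "comorbidrisk"), check.names = FALSE)
zm <- network_zscores(setNames(deg$degree_male, deg$disease))
head(zm[order(-zm$z), ], 3)
#>   disease       degree     z
#> 1 hypertension    5532 2.72
#> 2 heart disease   3750 1.49
#> 3 arthritis       2576 0.675
screen_diseases(zm)
#> [1] "hypertension" "heart disease" "arthritis" "stroke" "diabetes"
#> [6] "chronic lung disease" "dyslipidemia"        # 7 diseases, 2^7 = 128 states

dis <- c("hypertension", "diabetes", "heart disease")
ex  <- setNames(rep(0.02, 3), dis)                 # 2% excess mortality each
p   <- synth_params(age_range = c(65, 90), disease_names = dis,
                    baseline_prevalence = rep(0.1, 3),
                    prevalence_age_slope = rep(0, 3),
                    pairwise_log_odds = matrix(0, 3, 3),
                    gompertz_a = 0.01, gompertz_b = 0.08,
                    excess_mortality = ex)
lt  <- generate_lifetable(p)
S    <- 10000 * 0.05^rowSums(comorbidrisk:::state_matrix(3)); S[1] <- 10000
scn <- oracle_scenario(dis, 65:90,
                       count_hazard(c(0.01, 0.03, 0.08), age_factor = 1.02),
                       S, lt, excess_mortality = ex)
coh  <- simulate_oracle_cohort(scn)
surf <- build_surface(coh, mortality_model(lt, ex), "male")
tab  <- marginal_risk_table(surf, "male")
max_impact_chain(tab, "heart disease")
#>   size state added        mean      lo      hi
#> 1    1 100   hypertension 0.00582 0.00449 0.00716
#> 2    2 110   diabetes     0.04014 0.03576 0.04452
mutual_impact_pairs(tab)
#>   disease_a disease_b
#> 1 diabetes  hypertension
```

Reading: with hypertension already present, one-year onset of heart
disease is on average 0.58 percentage points (95% CI 0.45–0.72) above the
healthy state; adding diabetes raises the margin to 4.01 points — the
amplification a superadditive hazard produces. In the `state` bitstrings,
bit positions follow the disease-list order (here
hypertension/diabetes/heart disease, so `110` = hypertension + diabetes).

The full pipeline (generation or CSV ingestion → cohort → screening →
incidence surface → risk tables → JSON report) runs from one config:

```r
run_pipeline(run_config("config.yaml"))
```

or from the shell via `inst/scripts/comorbidity_pipeline.R`.

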