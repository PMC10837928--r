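Package: comorbidrisk
Title: Comorbidity Risk of Chronic Diseases from Cross-Sectional Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates age- and sex-specific incidence of chronic diseases
    under every comorbidity state from a single cross-sectional survey of an
    elderly population. A hypothetical aging cohort is constructed by
    back-casting each age group to an anchor age with survey-year mortality
    and rescaling disease-state counts; a disease co-occurrence network with
    weighted-degree z-scores screens the significantly comorbid diseases; a
    discrete-time multistate transition model inverts consecutive joint
    prevalence tables (after removing base and disease-specific excess
    mortality) into one-year onset probabilities per comorbidity state; and
    marginal comorbidity risks compare each state's incidence with the
    healthy state, with nested maximum-impact chains and mutual-impact
    pairs. Includes a synthetic survey generator and a deterministic
    expected-count oracle simulator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
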