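Package: icpday
Title: First-Day Intracranial Pressure Trajectory Analysis for ICU Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for first-ICU-day intracranial pressure (ICP)
    monitoring data in subarachnoid hemorrhage cohorts. Converts irregular
    timestamped chart events into complete 24-point hourly series (nearest-hour
    rounding, duplicate averaging, gap-based exclusion, interpolation
    imputation), clusters normalized trajectories by K-medoids with
    Davies-Bouldin model selection, locates optimal survival cut-points for
    daily ICP mean and variance by minimum log-rank p-value scanning, estimates
    treatment effects of cut-point-defined ICP groups by stabilized inverse
    probability of treatment weighting with confounder screening, and produces
    FDR-controlled baseline comparison tables, multivariable logistic models
    and fluid-balance correlations. Includes a synthetic cohort generator with
    planted trajectory archetypes and ICP-driven mortality for end-to-end
    validation without access to protected ICU databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    cluster,
    survival,
    mgcv,
    nortest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
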