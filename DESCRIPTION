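Package: vretvol
Title: Within-Session Volatility Analysis and Adaptive Pacing for Virtual
    Exposure Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the moment-to-moment dynamics of
    physiological and behavioural signals recorded during virtual-reality
    exposure therapy (VRET) sessions. Fits AR(p) mean models with
    GARCH(1,1) conditional variance by Gaussian quasi-maximum likelihood
    and summarises volatility persistence, half-life and unconditional
    variance; provides the accompanying diagnostic battery (skewness,
    kurtosis, Jarque-Bera, Durbin-Watson, ARCH-LM, Ljung-Box on squared
    residuals, augmented Dickey-Fuller, information criteria) and
    forecast-accuracy scores (MAE, MAPE, RMSE, Theil's U). Includes a
    deterministic rule-based micro-relaxation controller (z-scored
    heart-rate and head-movement triggers, hold/step-up pacing, a hard
    heart-rate ceiling), cohort-level outcome statistics (paired t,
    Cohen's dz, fear-severity stratification, post-session questionnaire
    scoring), model-utility benchmarking (ARCH-LM gating, AR vs AR-GARCH
    fit gain, volatility proxies, incremental-validity tests), and a
    synthetic-cohort generator that emulates a 55-participant,
    seven-session study so the full pipeline runs without access to raw
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
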