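Package: dyadarousal
Title: Event-Locked Arousal and Vocalisation Analyses for Caregiver-Infant Dyads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analyses of how autonomic arousal co-fluctuates with vocalisation
    timing in caregiver-infant dyads recorded over day-long sessions at 1-min
    epoch resolution. Provides a synthetic dyad generator (bivariate AR(1)
    arousal with logistic, self-exciting vocal event links and duty-cycled
    audio sampling), composite-arousal preprocessing with autocorrelation
    removal, matched control "non-vocalisation" resampling, event-locked
    likelihood and arousal trajectories, arousal-peak contingency, ROC/AUC
    prediction of vocal events from arousal, partner-arousal quartile splits,
    moving-window arousal stability and coupling, and permutation-based
    temporal cluster inference with Mann-Whitney / Hodges-Lehmann statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
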