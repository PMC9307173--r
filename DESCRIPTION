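Package: oxsleep
Title: Rodent EEG/EMG Sleep Staging, Cataplexy Detection and Orexin
    Dose-Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for narcoleptic mouse sleep physiology:
    semi-Markov simulation of vigilance-state sequences with
    state-conditioned EEG/EMG signal synthesis, per-epoch spectral and
    EMG features, rule-based Wake/NREM/REM staging at 20-s and 4-s epoch
    lengths with a predominant-state rule, detection of cataplexy-like
    episodes by the three standard criteria (sustained atonia,
    theta-dominant EEG, preceding wakefulness), sleep-architecture and
    fragmentation metrics (state totals, episode durations, transition
    counts, hourly profiles, NREM delta power), conditioned-place-preference
    scoring, and four-parameter logistic fitting of intracellular calcium
    dose-response curves with EC50, fold-selectivity and potency ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
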