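Package: pinnacle
Title: Dual-System Decision-Bound Models of Category Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, fitting and trial-classification machinery for the
    PINNACLE dual-system model of visual category learning. Two competing
    decision-bound learners (a rule-based system with a vertical bound on
    stimulus frequency and an information-integration system with a slope-1
    diagonal bound) each maintain a boundary and a perceptual-shaping
    confidence parameter; a noisy odds comparison resolves which system
    drives the response, and configurable feedback-routing policies decide
    which systems learn on each trial. The package generates synthetic
    rule-based and information-integration category structures and trial
    sequences, runs single sessions and large simulated groups, fits group
    summaries by weighted least squares and individual trial tables by
    maximum likelihood (both via downhill simplex), compares the twelve
    feedback-routing policies, and classifies trials post hoc
    (high-competition versus non-competition trials, best-fit blocks,
    off-system correctness) for model-based event files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
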