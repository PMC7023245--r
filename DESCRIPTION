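Package: ddgsampler
Title: Holdout Random Sampling and Neural Network Regression of Protein
    Stability Changes
Version: 0.1.0
Authors@R:
    person("ddgsampler", "developers", email = "ddgsampler@example.org",
           role = c("aut", "cre"))
Description: Predicts the change in protein unfolding free energy (ddG,
    kcal/mol) caused by single and double amino-acid substitutions. A
    holdout random sampler learns position- and protein-independent
    empirical distributions of ddG per substitution type from bootstrap-style
    75/25 data bags, Monte-Carlo predicts a residual-corrected energy-change
    CDF per mutant, and a one-hidden-layer ReLU network trained with the
    Levenberg-Marquardt algorithm regresses observed ddG from the predicted
    CDF quantiles plus mutation and protein codes. Includes a synthetic
    ProTherm-like data generator with known ground truth, evaluation metrics
    (Pearson, RMSE, sign accuracy), and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
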