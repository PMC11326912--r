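Package: tachometric
Title: Tachometric and Neurometric Analysis of Urgent Antisaccade Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-resolved analysis of urgent antisaccade performance and of
    the prefrontal activity that accompanies it. Computes raw processing time
    (rPT) from reaction times under overlap/zero-gap/gap timing variants,
    classifies saccades against cue and target windows, estimates tachometric
    curves (proportion correct versus rPT) with binomial confidence intervals,
    fits them with a two-sigmoid model by mean-absolute-error minimization,
    and derives the rPT at criterion, the asymptotic accuracy, and the
    probability of exogenous capture, with trial-wise bootstrap confidence
    intervals. On the neural side it builds Gaussian-kernel spike density
    functions, selects visuomotor neurons by paired t-test criteria,
    computes pooled per-neuron-centered ROC neurometric curves (S_ROC) over
    rPT, and evaluates the superposition conflict model that predicts
    presaccadic spatial bias from cue-aligned and saccade-aligned response
    profiles. Includes seeded generators for synthetic trial tables and
    inhomogeneous-Poisson spike trains with the same statistical structure,
    so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
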