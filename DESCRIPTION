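Package: microstates
Title: EEG Microstate Segmentation and Information-Theoretic Sequence
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Segments multichannel resting-state EEG into microstate
    sequences using polarity-invariant (modified) K-means clustering of
    the topographies at global field power peaks, with competitive
    back-fitting by maximum squared spatial correlation. Provides an
    information-theoretic toolbox for the resulting symbolic sequences:
    Shannon entropy, transition matrices, likelihood-ratio (G) tests for
    zero-, first- and second-order Markovianity, geometric lifetime
    distributions, stationarity and symmetry of the transition matrix,
    first-order Markov surrogate synthesis, and the time-lagged mutual
    information (autoinformation) function with surrogate confidence
    bands. Includes a basic EDF reader/writer, a synthetic-EEG generator
    for validation, and a batch pipeline with a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
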