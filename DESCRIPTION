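Package: eegmontage
Title: Design of Symmetric Wearable EEG Electrode Montages for Passive
    Brain-Computer Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing application-specialized and general-purpose
    wearable EEG electrode montages. Extracts a nine-family feature battery
    (band power, interhemispheric asymmetries, Hjorth parameters, entropy
    and complexity measures, filter-bank common spatial patterns) from
    multichannel EEG, evaluates every hemispherically symmetric electrode
    subset for four-class emotion classification accuracy and for
    attention-estimation correlation strength against a behavioral
    concentration index, and selects montages by classification accuracy,
    correlation, or their sum (the generalized-configuration score).
    Includes a synthetic EEG generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    MASS,
    nortest,
    Rcpp,
    rpart,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
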