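Package: adlzero
Title: Zero-Shot Recognition of Daily Activities from Ambient Binary Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Recognizes previously unseen activities of daily living from
    smart-home binary-sensor event streams by bridging sensor space and
    language space. Annotated event logs (CASAS dialect) are segmented into
    labeled activity instances and summarized as per-sensor activation
    counts; a shallow network with SELU hidden layers maps count vectors
    into a word-embedding space through a frozen output layer whose columns
    are the seen classes' word vectors; unseen activities are recognized by
    nearest-prototype cosine matching against their own label embeddings.
    Includes a word2vec text-format reader, confusion-matrix and one-vs-rest
    metric tooling, seen/unseen correlation analysis, a distractor-vocabulary
    robustness experiment, and a synthetic event-stream generator so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
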