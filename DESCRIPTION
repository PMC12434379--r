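Package: wavescore
Title: Evaluation of Reconstructed Speech Waveforms for Speech Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Standardized evaluation of speech waveform reconstruction quality,
    aimed at invasive speech brain-computer interface (BCI) research. Provides
    the objective metrics used in that literature on a common MFCC substrate
    (Pearson correlation, a short-time segment correlation variant of STOI,
    mel cepstral distortion, and a normalized spectrogram-entropy complexity
    measure), mean-opinion-score (MOS) aggregation with Cronbach's alpha for
    rater panels, predictive MOS models (a published piecewise linear scorer
    gated on entropy, plus trainable support-vector and random-forest
    regressors on STOI and MCD), and grouped leave-one-dataset-out /
    leave-one-trial-out cross-validation scored on aggregated out-of-sample
    predictions. A synthetic benchmark generator produces paired audio with
    controlled degradations and simulated rater panels so the whole pipeline
    is testable without any external audio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    signal,
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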