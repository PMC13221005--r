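Package: ccindex
Title: Co-Contraction Indices for Agonist-Antagonist EMG Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calculators for six electromyography (EMG) co-contraction indices
    (simple ratio, Falconer-Winter, Thoroughman-Shadmehr, Unnithan-Frost,
    Rudolph, and a temporal overlap index) over rectified, amplitude-normalized
    EMG envelope pairs, together with Chatterjee's rank correlation coefficient,
    synthetic EMG generators (random sinusoid and polynomial families, and
    deterministic piecewise-linear scenario signals), and the simulation studies
    that characterize index behaviour: constant-signal surfaces and slices, a
    correlation-based index classification study, and amplitude-normalization,
    comparability and sensitivity scenario experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
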