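Package: somnohrv
Title: Autonomic Sleep Staging and Trial Statistics from Wearable R-R
    Intervals and Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open pipeline from raw wearable-sensor recordings of a night's
    sleep to group-level trial statistics. Takes millisecond R-R interval (RRI)
    series and 125 Hz 3-axis accelerometry; flags body-movement artifacts with a
    0.5 G dynamic-acceleration threshold; removes ectopic intervals; resamples
    the tachogram to a uniform grid; computes per-minute low-frequency
    (0.05-0.15 Hz) and high-frequency (0.15-0.40 Hz) spectral powers, their
    square-root-of-integral amplitudes and the LF/HF sympathovagal ratio;
    scores sleep/wake from activity counts with the Cole weighted-sum
    algorithm and estimates sleep onset and total sleep time; classifies each
    sleep minute into sympathetic-dominant (S) sleep and shallow/deep
    parasympathetic (PS) sleep from the autonomic balance; and compares groups
    and measurement days with two-tailed t tests, Pearson correlations,
    one-way ANOVA, Games-Howell post-hoc contrasts and uncapped Bonferroni
    correction. A fully seeded synthetic-data module generates overnight
    recordings and multi-night cohorts with known ground truth so every stage
    is testable without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
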