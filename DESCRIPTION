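Package: pigait
Title: Activity, Gait and Behavioural Scoring for Porcine Spinal Cord Injury Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Functional-evaluation pipeline for preclinical porcine spinal
    cord injury studies. Quantifies unsupervised physical activity from
    trunk-mounted inertial measurement units (Savitzky-Golay smoothed
    dorsal-plane angular acceleration binned into rest/low/high intensity
    levels), detects walking bouts by block-wise FFT of thoracic
    medio-lateral acceleration, extracts and time-normalizes hip
    electro-goniometer gait cycles (101-point curves, peak flexion and
    extension, range of motion, extrema timing), and aggregates
    multi-observer Porcine Thoracic Injury Behaviour Scale (PTIBS) scores
    into group summaries and baseline-relative changes. Includes a seeded
    synthetic-session generator with ground-truth manifests so the whole
    pipeline can be validated without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
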