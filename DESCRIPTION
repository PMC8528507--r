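Package: sicitrack
Title: Simulation and Test-Retest Reliability of Threshold-Tracking and
    Conventional SICI Protocols
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates paired-pulse transcranial magnetic stimulation (TMS)
    examinations of short-interval intracortical inhibition (SICI) on virtual
    subjects with log-linear motor-evoked-potential (MEP) recruitment curves,
    and analyses their test-retest reliability.  Implements proportional
    threshold tracking with weighted semi-logarithmic regression threshold
    estimation, the parallel threshold-tracking SICI protocol (T-SICI), the
    automated conventional amplitude protocol (A-SICI), prestimulus EMG
    gating, and a full multi-session, multi-observer study design.  The
    statistical battery covers within-subject standard deviation, the
    coefficient of repeatability with chi-square confidence intervals,
    ICC(2,1) with F-based confidence intervals and qualitative bands,
    repeated-measures ANOVA with Mauchly's sphericity test and
    Greenhouse-Geisser correction, Bland-Altman agreement (including
    back-transformed ratio limits on the log scale), one-sample and paired t
    tests, and inter-method regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
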