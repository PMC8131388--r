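Package: bradyfusion
Title: Early Bradycardia Detection in Preterm Infants by Detector Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Real-time detection of bradycardia events in preterm-infant
    RR-interval series. Implements three online beat-by-beat detectors (a
    fixed-threshold rule emulating NICU monitor alarms, a relative
    adaptive-threshold rule, and a Page-Hinkley abrupt-change detector)
    fused by majority vote, together with the event-annotation procedures
    used to score them: the standard bradycardia definitions (heart rate
    below 100 bpm for at least 5 s, below 80 bpm for at least 10 s, and a
    clinical-significance rule), merging of multiphasic events, and
    sigmoid-based onset/offset adjustment. Includes a seeded synthetic
    cohort generator with ground-truth annotations and the full evaluation
    protocol (TP/FP/FN matching, sensitivity, false alarm rate, detection
    delay with acquisition-latency compensation, paired Wilcoxon
    comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
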