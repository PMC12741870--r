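Package: oartex
Title: Extraction, Analytics and Cohort Sharing for Online Adaptive Radiotherapy Plan-Check Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Toolkit for mining online adaptive radiotherapy (oART) plan-check
    records from a Mobius-style secondary dose-verification JSON API. Parses the
    Ethos plan naming grammar to resolve plan lineage (scheduled versus adaptive
    plans, structure-set revisions, delivered plans via linked delivery log-file
    checks), rebuilds continuous cumulative dose-volume histograms from truncated
    point lists and evaluates arbitrary V(D)/D(V) objectives, tracks organ-at-risk
    volume and centroid changes against the reference structure set, stores
    everything in a de-identified, mergeable long-format cohort store, and renders
    longitudinal visualizations (volume trends, DVH percentile-band spread plots,
    dosimetric-objective distributions). A bundled synthetic fixture service
    emulates the clinical data source so the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
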