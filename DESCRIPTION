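Package: cohortflow
Title: Cohort Trajectory Mining and Sankey Visualization for Longitudinal EMR Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploratory analysis of longitudinal claims and
    electronic medical record (EMR) data around an index diagnosis.
    Diagnosis and procedure codes are mapped to a configurable factor
    vocabulary (a chronic kidney disease map with ICD-9-CM and Taiwan NHI
    procedure codes is shipped as the default), patient event trajectories
    are aligned on the first index-factor occurrence and partitioned into
    half-open time windows, patients are grouped into cohorts by
    frequency-based merging or agglomerative clustering under the Ochiai
    set-similarity coefficient, and the resulting cohort-trajectory network
    is filtered by outcome entropy, laid out with a barycenter/simulated
    annealing heuristic, and exported as a renderer-agnostic Sankey
    document (JSON) plus a self-contained static HTML view. A seeded
    synthetic-cohort generator and a cached end-to-end pipeline runner are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
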