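Package: semirigid
Title: Semi-Rigid Domain Decomposition of Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies semi-rigid domains in molecular dynamics trajectories
    by an unsupervised three-step spatio-temporal consensus procedure: crisp
    combinatorial clustering of distance-variability (STDDV) matrices within
    short trajectory segments, time-wise consensus over segments, and
    agglomerative grouping of the consensus dissimilarity, followed by
    Hungarian-algorithm matching of groups across replicate trajectories and
    extraction of stable kernels. Includes readers and writers for multi-model
    PDB and multi-frame GRO trajectories, rigid-body least-squares trajectory
    fitting, a synthetic planted-domain trajectory generator for validation,
    recovery scoring via the adjusted Rand index, VMD Tcl export, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
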