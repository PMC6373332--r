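Package: catimprove
Title: Model-Guided Correction of Coronary Artery Tree Extractions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic detection and correction of incorrect extractions in
    coronary artery centerline trees from coronary CT angiography. Guided by an
    anatomical statistical model of the AHA segment topology, the package applies
    a coarse improvement (orphan removal, length pruning, bifurcation-angle
    filtering) followed by label-driven deletion and extension operations that
    bridge gaps in a binary vesselness volume, orchestrated by a decision tree
    and monitored by a quality score with explicit stopping and revert criteria.
    A phantom generator produces ground-truth labeled trees, rasterized binary
    skeleton volumes, and realistically degraded initial extractions so the full
    pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
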