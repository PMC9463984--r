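Package: vsdbn
Title: Two-Stage Volumetric Sparse Deep Belief Networks for Naturalistic fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Decomposes multi-subject volumetric fMRI into hierarchical
    functional brain networks with a two-stage volumetric sparse deep belief
    network (vsDBN). Stage one trains a group model on time-concatenated,
    transposed volume data; stage two fine-tunes per-subject models
    initialized from the group weights so individual networks stay in
    register with the group networks. The network architecture (number of
    hidden layers and nodes) is selected by a particle-swarm neural
    architecture search with aging-evolution mutation. Includes a synthetic
    naturalistic-fMRI generator with known ground truth, and an evaluation
    suite: inter-subject correlation of temporal features, spatial
    correlation and overlap between group and individual maps, tapered
    sliding-window dynamic functional connectivity with k-means states, and
    a state-similarity index between group and individual dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    clue,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
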