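Package: egmatch
Title: Equivariant Graph Matching Networks Pre-Trained on Molecular
    Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Self-supervised pre-training of an E(3)-equivariant graph
    matching encoder on molecular-dynamics trajectories of protein-ligand
    complexes. Builds atom-level ligand and pocket graphs from 3D
    coordinates with distance-cutoff edge rules, encodes them with a
    layered equivariant message-passing network featuring cross-graph
    attention, and pre-trains it with two objectives: prompt-based
    denoising prediction of a future conformation, and snapshot ordering
    decoded by topological sort. Downstream heads predict binding
    affinity (pK regression) and ligand efficacy (binary classification)
    under linear-probing or fine-tuning protocols, and a per-complex
    motion statistic links predicted atomic displacement to binding
    strength. A bundled overdamped-Langevin simulator generates toy
    ligand-pocket trajectories with a tunable binding-strength parameter
    for end-to-end experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
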