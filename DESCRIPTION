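Package: aquabridge
Title: Detection and Ensemble Statistics of Protein-Water Bridges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects hydrogen-bonded water bridges between protein residues
    in single structures, multi-model ensembles, and molecular dynamics
    trajectories. Provides configurable geometric hydrogen-bond criteria
    (donor-acceptor distance and donor-H-acceptor angle ranges, with an
    angle-free mode for hydrogen-less structures), a Chain method that
    reports residue pairs linked through chains of up to maxDepth water
    molecules, a Cluster method that reports connected water/residue
    clusters, per-pair ensemble statistics (bridge frequency, interaction
    duration, endpoint distance moments, water counts), density-based
    clustering of water oxygen positions into hydration sites, readers and
    writers for PDB, mmCIF (atom_site) and binary DCD trajectories, and a
    synthetic fixture generator with planted, exactly known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
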