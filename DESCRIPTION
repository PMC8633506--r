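Package: latentmd
Title: Latent-Space Exploration of Molecular Dynamics Trajectories with
    Variational Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns low-dimensional latent representations of protein
    molecular dynamics (MD) trajectory coordinates with autoencoders and
    variational autoencoders (VAEs).  Provides trajectory input/output
    (multi-model PDB and flat coordinate matrices), Kabsch superposition
    and alignment to a reference frame, per-coordinate MinMax featurization
    with exact inversion, a dense hourglass AE/VAE trained by
    backpropagation with Adam, encoder/decoder fidelity benchmarks
    (Spearman and Pearson distance preservation, superposition RMSD,
    maximum mean discrepancy, earth mover's distance), latent-space seed
    generation for adaptive sampling (interpolated latent points decoded
    to PDB restart structures, domain-angle collective variables), and
    Markov state model implied-timescale analysis of discretized
    collective-variable trajectories.  A synthetic two-metastable-state
    trajectory generator makes the whole pipeline runnable and testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
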