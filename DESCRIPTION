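Package: filacomp
Title: Two-Resolution Brownian Dynamics of Actin Filament Compression and
    Shape-Space Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates compression of single actin filaments with overdamped
    Brownian dynamics at two resolutions: a chiral monomer-scale bead chain
    (harmonic bonds and angles plus cosine dihedrals, so the helical lattice
    couples bend to twist) and an achiral fiber-scale segment chain (a
    discrete worm-like chain). Both are driven by the same translate/relax
    anchored-end compression protocol. Provides simulator-independent shape
    metrics for any filament point chain (compression ratio, peak asymmetry,
    non-coplanarity, signed supertwist angle, worm-like-chain persistence
    length), alignment and principal-component shape-space analysis with
    latent walks, a parametric shape generator with analytic ground truth,
    and a reproducible simulate/measure/pca pipeline with plain-text
    trajectory and metric formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
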