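Package: specdenoise
Title: Intensity-Based Denoising and Molecular-Network Diagnostics for
    Tandem Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Noise management for MS/MS fragmentation spectra and tools to
    evaluate its effect on spectral similarity and molecular networks. Implements
    an intensity-only tailored noise filter based on a robust linear model fitted
    to intensity-ordered ions, base-peak percentage cutoffs, and consensus-spectrum
    creation; GNPS-style modified-cosine similarity with neutral-loss matching;
    molecular-network construction with minimum-spanning-tree diagnostics of
    network structure; and a data-dependent workflow that balances the retention
    of structurally explained fragment ions against network collapse to locate an
    optimal noise cutoff. Includes a synthetic spectrum generator emulating
    uniform-intensity background ions under higher-intensity true fragments, plus
    MGF reading/writing and spectral-entropy-based library curation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    graphics,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
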