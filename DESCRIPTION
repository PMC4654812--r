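Package: sproutcpm
Title: Cellular Potts Models of Angiogenic Sprouting and Tip-Cell Overtaking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates angiogenic sprouting from endothelial spheroids with a
    two-dimensional Cellular Potts model in two variants (contact-inhibited
    chemotaxis and cell elongation), coupled to a secreted chemoattractant
    reaction-diffusion field and an optional per-cell VEGF-Dll4-Notch
    signaling network with cis-inhibition and contact-surface-weighted
    trans-signaling. Includes the full analysis pipeline: skeleton-graph
    sprout detection, geometric leader-cell identification, tip-cell-overtake
    counting with a persistence rule, cell-kinetics statistics (coordination,
    directional motility, biased-random-walk MSD fits), and mosaic wild-type
    versus Vegfr2 heterozygous tip-occupancy experiments with binomial tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    tiff,
    pracma,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
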