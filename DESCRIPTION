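Package: flysin
Title: Dyadic Social Interaction Analysis and Interaction Networks for Flies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying pairwise social behavior of fruit flies
    held in bisected circular arenas: distance-to-barrier geometry, the dyad
    interactivity index (Pearson correlation of the two flies' barrier
    distances), coincidental-approach counting, shuffled-pair permutation
    nulls, bootstrap standard errors, day-to-day persistence statistics
    (Fisher z), and thresholded social interaction networks. Includes
    locomotor control metrics (activity fraction, Y-maze turning bias,
    kernel density estimates with bootstrap bands), a seeded synthetic
    generator of coupled random-walk trajectories with sensory-channel
    gating, and an end-to-end pipeline over CSV artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
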