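Package: tideweb
Title: Linear Inverse Food-Web Models and Ecological Network Analysis for
    Tidal Flats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds seasonal linear inverse models (LIM) of intertidal
    benthic food webs, samples the under-determined flow polytope with a
    mirror-reflection Markov chain Monte Carlo walk, computes ecological
    network analysis indices (total system throughput, average mutual
    information, ascendency and its overhead partition, Finn and
    comprehensive cycling indices, average path length, simple-cycle
    counts) on the sampled flow networks, aggregates networks into a
    Lindeman trophic spine with per-level transfer efficiencies, and
    compares seasonal index distributions with rank-sum tests.  Ships a
    declarative plain-text model format together with winter and summer
    models of the Brouage mudflat (Marennes-Oleron Bay) benthic food web.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
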