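Package: turingtda
Title: Topological Classification of Turing Patterns in Reaction-Diffusion Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the chlorite-iodide-malonic acid (CIMA) and Schnakenberg
    reaction-diffusion systems on rectangular domains with Neumann boundaries,
    summarises the stable patterns by the persistent homology of normalised
    lower- and upper-star filtrations, and clusters points of the Turing space
    under composite Wasserstein metrics between persistence diagrams. Includes
    the supporting linear (dispersion relation, unstable Neumann modes) and
    weakly nonlinear (stripe/spot selection) analyses, seeded synthetic pattern
    generators with known topological content, and an end-to-end sweep pipeline
    with CSV/JSON interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
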