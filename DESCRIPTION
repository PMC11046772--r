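Package: bisdl
Title: A Description Language and Nets-Within-Nets Simulator for
    Multicellular Synthetic Biology
Version: 0.1.0
Authors@R:
    person("BiSDL", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Parse textual descriptions of multicellular synthetic
    biological designs written in a compact domain-specific language
    (modules, spatial scopes, gene-circuit processes, paracrine and
    juxtacrine signals), compile them into hierarchical nets-within-nets
    Petri-net models over two-dimensional spatial grids, and run
    discrete-time stochastic simulations with external stimulus
    schedules.  Ships programmatic generators for a worked
    water-formation example and three multicellular case studies
    (a LacI-controlled bacterial consortium, an RGB synthetic morphogen
    pattern, and conjugative plasmid transfer), plus DOT, CSV and JSON
    exports for model inspection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
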