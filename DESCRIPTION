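Package: leknet
Title: Conditional Genetic Covariance Networks for Lek-Breeding Species
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds range-wide genetic networks from multilocus microsatellite
    genotypes sampled at lek locations. Leks are clustered into nodes by
    geographic distance, a conditional genetic covariance network (population
    graph) is estimated by Gaussian graphical model edge pruning, network
    structure is classified against Erdos-Renyi null ensembles, and nodes are
    ranked by six centrality indices to prioritize hub, spoke, and keystone
    populations for conservation. Includes a stepping-stone Wright-Fisher
    genotype simulator so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
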