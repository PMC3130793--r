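Package: metabef
Title: Biodiversity-Ecosystem Function Analysis for Algal Metacommunity
    Microcosms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing biodiversity-ecosystem function
    experiments with freshwater microalgae in dispersal-connected
    metacommunities. Enumerates and validates the factorial design
    (phosphorus supply crossed with nitrogen-to-phosphorus ratio and
    species composition), converts microscope counts and cell geometry
    into biovolume, computes Pielou evenness and phosphorus use
    efficiency at local and metacommunity scales, partitions net
    diversity effects into complementarity and selection components
    (sensu Loreau and Hector), and runs balanced factorial ANOVA with a
    conservative degrees-of-freedom adjustment for the non-independence
    of patches within metacommunities. Includes a Monod-Liebig
    multi-resource competition simulator that emulates the experiment,
    with Poisson counting noise and tunable interaction effects for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
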