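Package: nestkin
Title: Colony Kinship, Mating System and Nest Density of Bumble Bees from
    Microsatellite Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the molecular spatial ecology of social bees. From
    multilocus microsatellite genotypes of field-sampled workers and
    dissected queens, the package performs locus quality control
    (Hardy-Weinberg exact tests, null-allele estimation, linkage
    permutation tests), estimates queen mating frequency from spermathecal
    sperm profiles with a contamination screen and a miscount calibration,
    reconstructs worker sibship groups under haplodiploidy, estimates nest
    locations and colony-specific worker foraging distances, derives nest
    density via the abundance-based coverage estimator (ACE) with a
    foraging-distance buffer, and tests between-year lineage survival and
    isolation by distance. A spatially explicit synthetic-population
    generator with known colony structure supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust
Config/testthat/edition: 3
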