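Package: c4leak
Title: Bundle-Sheath CO2 Leak Modelling and Mutant Mapping for C4 Leaves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward biochemical modelling of C4 photosynthesis (enzyme- and
    light-limited net assimilation, bundle-sheath CO2 and leak flux) together
    with the inverse analyses used to characterise leaky bundle-sheath mutants:
    bundle-sheath conductance from PEPC-inhibited CO2-response initial slopes,
    leakiness from 13C photosynthetic discrimination, bundle-sheath CO2 partial
    pressure from flux balance, and quantum yield from light-response slopes.
    Also provides a mapping-by-sequencing candidate filter for three-pool
    (wildtype, azygous, mutant) bulked-segregant sequencing, allele-frequency
    landscapes, coding-effect classification, and synthetic-data generators
    (model-driven gas exchange, isotope observations, and a BC1F2 cross with
    pooled binomial read sampling) so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    vcfR,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
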