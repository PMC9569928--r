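Package: mitomod
Title: Nuclear Modifier Gene Discovery for Incompletely Penetrant
    Mitochondrial Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exome-based screening pipeline for nuclear genes that modify
    the penetrance of a pathogenic mitochondrial DNA mutation, as in
    multi-family studies of Leber's hereditary optic neuropathy. Provides
    variant qualification against a mitochondria-related nuclear gene
    universe (consequence, ClinVar, CADD/REVEL cascade), per-gene affected
    sample rates contrasting probands with unaffected carrier controls,
    intra-family genotype-contrast filtering with cross-family concurrence
    counts, genotype and site quality control feeding a Cochran-Armitage
    trend test (with an exact Hardy-Weinberg equilibrium test), and
    hypergeometric pathway over-representation with Benjamini-Hochberg
    adjustment. Includes a seed-deterministic multi-family cohort
    simulator so every stage can be exercised without access to protected
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
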