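Package: mitonuc
Title: Mitonuclear Coevolution Analyses on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for testing mitonuclear coevolution and the nuclear
    compensation hypothesis across a phylogeny. Implements
    background-normalized evolutionary rate covariation (ERC) between
    mitochondrial and nuclear gene sets with bootstrap BCa difference
    tests, branch-length estimation on a fixed topology under a Poisson
    amino-acid model with root-to-tip rate extraction, Nei-Gojobori
    (NG86) dN/dS estimation with ANOVA group comparisons, mitonuclear
    residue contact-pair detection from protein complex structures,
    ancestral-state substitution mapping with mt-first versus
    nuclear-first ordering statistics, counting-based site selection
    tests, and a seeded synthetic-data generator with known ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape (>= 5.3),
    bio3d,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    boot,
    phangorn,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
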