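Package: barcodelim
Title: Character-Based DNA Barcoding, Monophyly Testing and Calibrated
    Divergence Dating for Sibling Species
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Species delimitation toolkit for closely related sibling
    species, built around the Drosophila lini clade (D. lini, D. ohnishii,
    D. ogumai). Implements the character-based DNA-barcoding method (pure
    simple diagnostic nucleotides fixed in one species and absent from the
    others, including coded indel characters), Kimura 2-parameter distances
    with pairwise deletion, deterministic Neighbor-Joining with nonparametric
    bootstrap support, outgroup rooting and species-monophyly testing,
    multilocus concatenation into a supermatrix, and calibration-point
    divergence dating by mean-path-length ultrametricization. A seeded
    multilocus sequence generator produces alignments with within-species
    polymorphism, incomplete lineage sorting between recently split species,
    and polymorphic indels, together with truth records for every downstream
    check.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
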