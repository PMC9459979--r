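Package: stype
Title: S-Haplotype Typing and Self-Incompatibility Analysis for Radish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale identification of S haplotypes at the radish
    (Raphanus sativus) S locus from SRK kinase-domain sequences. Provides a
    unified S-haplotype nomenclature built by transitive unification of
    team-specific allele names, virtual PCR with IUPAC degenerate primers to
    classify genotypes into Class I / Class II self-incompatibility groups,
    in-silico HinfI PCR-RFLP digestion with gel band-pattern simulation and
    profile matching, global-alignment identity-based haplotype assignment
    with novel-allele detection, sporophytic self-incompatibility cross
    prediction under Class I over Class II dominance, compatibility-index
    classification of pollination outcomes, a synthetic sequence-panel
    generator for validation, and an end-to-end typing workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
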