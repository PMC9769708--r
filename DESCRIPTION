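Package: cressevolve
Title: Clustering, Domain Classification, and Codon Usage Evolution of
    CRESS-DNA Virus Rep and Cap Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the genetic diversity of circular
    Rep-encoding single-stranded (CRESS) DNA viruses. Implements all-vs-all
    pairwise similarity network clustering of Rep and Cap proteins with a
    force-directed layout (CLANS-style), motif-based detection of the HUH
    endonuclease (Viral_Rep) and Walker A/B (P-loop NTPase) signatures with
    a domain-organization classifier mapped onto the CRESSV/pCRESS/
    Smacoviridae group scheme, neighbor-joining concordance checks and
    Rep-Cap cluster cross-tabulation as recombination evidence, and a codon
    usage bias suite (base composition, RSCU, effective number of codons,
    ENc-GC3s expected curve, neutrality regression, parity-rule-2 bias).
    Seeded synthetic-data generators emulate protein families, planted
    motifs and a tunable mutation-selection mixture so every stage is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
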