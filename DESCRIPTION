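Package: resisig
Title: Clinically Relevant Drug-Resistance Gene Signatures from
    Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for extracting clinically relevant drug-resistance
    genes from drug-induced resistant cancer cell-line experiments and
    responder/non-responder clinical cohorts. Implements fold-change and
    average-difference gene ranking for small-replicate designs, the
    basally-deregulated (BD), inducible-in-parental (IP) and
    inducible-difference (ID) gene classes, directional consistency
    scoring between gene lists with an exact cumulative-binomial null,
    rank-product differential expression with permutation significance,
    direction-consistent intersection of clinical DEG lists across
    chemotherapy regimens sharing drugs, hypergeometric pathway
    enrichment, and a synthetic-data generator with planted signal for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    limma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
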