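Package: cyclominer
Title: Mining Cyclic-Peptide Precursor Genes from Transcriptome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for screening ribosomally synthesized cyclic-peptide
    (orbitide/Caryophyllaceae-type) precursor genes in transcriptome
    assemblies. Enumerates all linear ring-openings of a head-to-tail cyclic
    peptide, searches them as exact matches in six-frame translations of
    assembled transcripts, extends hits to open reading frames, annotates
    precursor architecture (leader, core, recognition sequence) and mRNA
    features (UTRs, AATAAAA polyadenylation signal, poly(A) tail), predicts
    the consequences of coding indels on the precursor and its cyclic
    product, computes peptide masses and charge states, and builds
    neighbor-joining trees of precursor peptides with bootstrap support.
    Ships a seeded synthetic-transcriptome generator with planted precursor
    genes and a machine-readable truth set for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
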