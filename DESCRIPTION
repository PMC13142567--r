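Package: gromr
Title: Streaming Sparse Imputation of Genetically Regulated Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Individual-level imputation of genetically regulated gene
    expression (GReX) as the sparse linear score Y = G x B: prediction
    weights from tab-delimited tables or PrediXcan-style SQLite models are
    harmonized to chromosome-split PLINK2-style genotype filesets by
    chromosome-position-reference-alternate matching with complementary
    alleles, genotype dosages are streamed in SNP chunks, and predictions
    are accumulated per gene-model column with an allocate-on-first-touch /
    flush-on-completion lifecycle into a preallocated column-major binary
    dataset (.grom with .gid/.sid manifests) supporting selective reads.
    Includes a dense reference implementation used as a correctness oracle,
    per-column Pearson/RMSE concordance evaluation, and a seeded synthetic
    cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
SystemRequirements: python3 (standard library sqlite3) on PATH, used only
    for importing and generating PrediXcan-style SQLite .db weight models
Config/testthat/edition: 3
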