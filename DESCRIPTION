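Package: xrefdb
Title: Build and Query a Cross-Reference Database of Bioinformatics Identifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns heterogeneous bioinformatics dataset files (TSV, CSV, JSON,
    XML, GFF3, optionally gzip-compressed) into a uniform ordered key-value
    database of identifiers, special keywords (gene symbols, species names),
    attributes and cross-references. Datasets are ingested as streams with
    bounded memory, spilled as sorted chunk files, merged MapReduce-style with
    a k-way patience merge, and batch-inserted in key order. The resulting
    store is queried with a chain mapping language
    (map(dataset).filter(expression)) that hops the cross-reference graph
    dataset to dataset, with boolean, comparison, substring and genomic-range
    filter predicates, attribute selection and paging. Includes a deterministic
    synthetic-universe generator with a ground-truth graph and a brute-force
    query oracle, a command-line interface and a minimal web-service layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    yaml,
    utils,
    stats,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
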