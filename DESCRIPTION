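Package: rxncurate
Title: Generic Reaction Template Extraction and Reaction Dataset Curation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts generic (radius-0) retrosynthetic reaction templates
    from atom-mapped reaction SMILES, canonicalizes them by graph
    isomorphism under the principle of minimum chemical distance, removes
    rare templates, and applies the resulting template library back to
    each reaction's products to validate records, restore missing
    reactants, and correct atom-to-atom mapping errors.  Includes a
    condensed-graph-of-reaction (CGR) representation for detecting
    mapping changes, an optional by-product balancing step, and a
    synthetic noise-injection benchmark (missing reactants, structural
    edits, atom-map swaps) for end-to-end evaluation of the curation
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    tools,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
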