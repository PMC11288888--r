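Package: metacoloc
Title: Spatial Colocalization of Metabolite Images and Metaproteomic Enzymes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates mass spectrometry imaging (MSI) metabolite data with
    microscale metaproteomics to map substrate-enzyme-product relationships
    across tissue microhabitats. Reads and writes imzML, extracts ion images,
    annotates peaks by molecular formula and negative-mode adduct with a
    decoy-adduct false discovery rate, applies target-decoy PSM filtering with
    threshold optimization, derives consensus taxonomic and functional (KEGG
    Orthology) assignments from homology hit tables, links detected enzymes to
    reactions and compounds through a local reaction graph, and scores spatial
    colocalization of each enzyme's peptides with its substrate and product
    ion images via pairwise region-of-interest log2 fold-change profiles,
    G-test directional flags, scaled Pearson correlation and
    Benjamini-Hochberg adjustment. A synthetic-data module generates all
    pipeline inputs with planted ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    xml2,
    Biostrings
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
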