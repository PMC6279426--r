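Package: speclib
Title: Error-Controlled Assembly of Peptide Spectral Libraries
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds reference spectral libraries from peptide-spectrum
    matches and peak lists with library-level false discovery rate control.
    Implements database p-value scoring with dynamic search-space
    adjustment, synthetic-pool empirical FDR filtering, length-binned
    sliding-window local precursor FDR, picked protein FDR, representative
    spectrum selection by average cosine similarity, ambiguity filtering,
    and order-invariant incremental library updates. Downstream tools cover
    proteotypic precursor selection by greedy set cover, co-observation
    interaction detectability, novel-protein calling with single amino acid
    variant exclusion, and SILAC light/heavy gold-standard library
    construction. Includes a deterministic synthetic-data generator so the
    full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
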