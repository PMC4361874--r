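Package: caconserve
Title: Intramolecular C-Alpha Distance Conservation in Heptahelical Transmembrane Bundles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the conservation of intramolecular C-alpha/C-alpha distances across
    ensembles of G protein-coupled receptor seven-transmembrane (7TM) bundles indexed by
    Ballesteros-Weinstein positions. Every residue-pair distance is scored by the inverse
    coefficient of variation (mean distance divided by its standard deviation) over the
    ensemble, ranked, and the top-ranked population is decomposed into helix-pair and
    helix-section-pair bins with normalisation by the possible-pair totals. Includes a
    companion backbone phi/psi circular-deviation analysis over the 35 helix sections,
    readers for PDB/mmCIF structures with alignment tables, and a deterministic synthetic
    7TM-ensemble generator with controllable per-helix conservation for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
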