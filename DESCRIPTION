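Package: chemkit
Title: Dependency-Light Cheminformatics: SMILES Graphs, Aromaticity,
    2D Depiction, Fingerprints and Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained cheminformatics kit for parsing SMILES into
    chemically validated molecular graphs with explicit electron and valence
    bookkeeping, perceiving rings and aromaticity (smallest set of smallest
    rings, recursive Hueckel evaluation), kekulising aromatic systems by
    maximum matching, computing 2D structure diagrams with stereo wedges and
    clash resolution, writing SVG/PNG images and MDL MOL V2000 files,
    stereo-aware substructure matching with highlighting, extended
    connectivity fingerprints with Tanimoto similarity, and chemically
    validated graph-edit reactions (hydrolysis, condensation, ketoreduction).
    Includes a seeded generator of valid test molecules and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    igraph,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2,
    jsonlite
Config/testthat/edition: 3
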