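Package: fgfr2dyn
Title: Structural Dynamics of the FGFR2 Tyrosine Kinase Domain from
    Crystallographic Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterizes the conformational dynamics of the FGFR2
    tyrosine kinase domain (and, generically, of any protein chain family)
    from an ensemble of experimentally resolved structures. Parses PDB
    coordinate files into C-alpha traces, curates chains against required
    functional regions, superposes traces onto a reference by the Kabsch
    algorithm, and fits an essential-dynamics principal component model
    with projection, reconstruction, per-residue displacement profiles and
    out-of-sample placement of modeled variant structures. A geodesic
    (Isomap) embedding complements the linear model, and bundled
    annotation tables map functional regions, activation states, disease
    classes and pathogenicity calls onto the embeddings. A synthetic
    conformational-ensemble generator with known motion modes supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
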