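Package: growlite
Title: Shape-Guided Fragment Growing in Protein Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Structure-based fragment growing: a bound core ligand is extended
    with library fragments by casting a spherical ray-length shape descriptor
    from the growth vector, enumerating attachment torsions, and ranking poses
    by filled volume, close contacts and clash. Optional pharmacophore search
    points (donor, acceptor, hydrophobic, each with a tolerance radius)
    constrain poses; replaced crystallographic waters can seed such points.
    Poses may be refined by a restrained gradient optimization that keeps core
    atoms within a 0.5 Angstrom flat-bottom well, and fragment libraries can
    be screened against aligned binding-site ensembles keeping each fragment's
    best-scoring member. Includes the evaluation machinery for such workflows:
    cross-growing test-case construction by single-cut common-substructure
    matching, symmetry-corrected fragment RMSD, binomial success statistics,
    interaction-maintenance rates, and ROC/AUC enrichment with stratified
    bootstrap confidence intervals, plus a deterministic synthetic fixture
    generator (cavities, planted growing cases, labelled libraries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineR,
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
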