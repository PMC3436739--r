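Package: coevotopo
Title: Quaternary Topology of Protein Complexes from Evolutionary Rate
    Correlations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the three-dimensional arrangement of subunit centers
    ("quaternary topology") of a multi-subunit protein complex from
    correlations in the evolutionary rates of its subunits.  Per-family
    phylogenetic trees are reduced to patristic distance vectors over
    species pairs; the shared species-phylogeny signal is removed by
    orthogonal projection on an averaged reference vector; the corrected
    vectors are correlated by Spearman rank correlation (mirror-tree
    method); the resulting co-evolutionary dissimilarities are embedded in
    three dimensions by classical multidimensional scaling with a P_k
    goodness-of-fit and a permutation null for embeddability; and the
    inferred configuration is validated against a reference crystal
    structure by similarity Procrustes superposition (rmsd, per-axis
    correlations, distance-versus-distance regressions).  Includes a
    synthetic benchmark generator producing ground-truth configurations,
    noisy dissimilarities, and species trees with distance-correlated
    branch-rate multipliers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
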