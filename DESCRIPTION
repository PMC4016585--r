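Package: modulyzer
Title: Statistically Supported Module Detection in Protein Structural
    Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies sub-domain modules - groups of residues whose
    centroid coordinates co-vary - in ensembles of protein structures,
    either homologous crystal structures mapped through a multiple
    alignment or snapshots from a molecular dynamics trajectory.  Builds
    a weighted graph from per-dimension Pearson correlations between
    residue landmarks (Fisher-z significance filtering, correlation
    vector magnitude as edge weight, optional contact masking), detects
    communities by fast-greedy weighted modularity maximization, and
    supports each cluster with a permutation t-test of intra- versus
    inter-correlations under Benjamini-Hochberg false discovery rate
    control, an iterative bidirectional-merge refinement, a Fisher-z
    power summary (minimum resolvable correlation and proportion of
    variables with enough power), and bipartition bootstrap support.
    Includes a multivariate-normal block-correlation simulator for
    validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
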