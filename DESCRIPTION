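Package: mrptree
Title: Matrix Representation with Parsimony Supertree Construction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building species-level supertrees from collections of
    published phylogenies ("source trees") with partially overlapping leaf
    sets. Implements a complete, repeatable construction protocol: source-tree
    curation (synonym standardisation, higher-taxon substitution, weighting
    and removal of non-independent trees, taxonomic-overlap checks), Baum-Ragan
    matrix representation with parsimony (MRP) encoding with a hypothetical
    all-zero outgroup, weighted Fitch parsimony scoring with heuristic
    (random-addition plus SPR/TBR branch swapping) and exact branch-and-bound
    searches, strict consensus and maximum agreement subtree (MAST)
    summarisation, per-node V and V+ support indices with novel-clade
    detection, and a synthetic source-tree generator with known truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    igraph,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    phangorn,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
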