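Package: ontorules
Title: Rare Generalized Association Rules Between Biomedical Ontologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mines pairwise generalized association rules between (or within)
    category hierarchies such as the Gene Ontology, with an emphasis on rare
    rules. Provides loaders for OBO and edge-table hierarchies and for
    GAF-like annotation tables, ancestor-closure expansion of annotations,
    sparse pair-support counting at a minimum support of one occurrence, a
    registry of null-invariant and classical interestingness measures
    (support, confidence, cosine, all-confidence, Kulczynski, lift, Bayes
    factor, centered confidence, the phi coefficient and Jaccard), and the
    hierarchy-aware "interestingness by difference" measures JacDif and
    CosDif, which score a rule by how far its measure value departs from the
    value expected under proportional distribution from its parent rules.
    Comparator pruning schemes (expected-value pruning of generalized rules
    and agreement/structure-based filtering), ranked-list evaluation against
    a ground-truth mapping, and a synthetic benchmark generator with planted
    cross-ontology links are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
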