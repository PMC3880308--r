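# ontorules

Rare generalized association-rule mining between biomedical ontologies.

## The problem

Objects such as proteins are annotated with categories from one or more
rooted hierarchies (the Gene Ontology branches, receptor family trees,
encyclopedia taxonomies). Treating each object as a transaction whose items
are its (ancestor-closed) categories, pairwise association rules `a → b`
between categories of two hierarchies reveal cross-ontology links —
existing knowledge, new biology, or annotation inconsistencies. Two things
make this hard:

1. **The interesting rules are rare.** Specific categories are infrequent,
   so support/confidence thresholds discard exactly the rules worth
   finding. Null-invariant measures (Jaccard, cosine, all-confidence,
   Kulczynski) — unchanged by transactions containing neither item — are
   the right tools for rare rules.
2. **The hierarchy itself creates redundancy.** A rule at one level
   subsumes its specializations; after ancestor closure, child→parent
   rules hold with confidence 1 trivially.

`ontorules` addresses both with the **interestingness-by-difference**
measure class. For a rule `a → b` with counts `n_ab`, `n_a`, `n_b`, the
expected support under proportional distribution from a parent `pa` of `a`
is

```
SupExp(a → b) = n(pa, b) · n_a / n_pa
```

taking the minimum over all parents (both sides, in the default mode) when
the hierarchy is a DAG, and the independence product `n_a·n_b/N` when both
items are roots. A base measure `M` (Jaccard or cosine) is re-evaluated at
the expected count to give `E`, and the rule is scored

```
Dif = M · (M − E)
```

Rules *unexpected from the hierarchy* get positive scores even when rare;
rules explained by a parent (or outperformed by a sibling) score near zero
or negative. The package also implements the two comparator pruning
frameworks it is benchmarked against — expected-value pruning of
generalized rules (root rules always kept, interest factor `R`) and
agreement/structure-based filtering (minimum support/confidence/agreement
plus specific-structure pruning) — and a ranked-list evaluation harness
(F-1 at k, best-possible F-1 over prefixes, median absolute support,
top-n intersections).

## Worked example

A clothing hierarchy (Clothes > Outerwear > {Jackets, Travel Pants}) and a
footwear hierarchy (Footwear > Hiking Boots) over 1000 transactions:

```r
library(ontorules)
fx <- toy_clothing_fixture()
ranked <- mine_rules(fx$store, fx$ontologies, c("apparel", "footwear"),
                     measures = c("Jac", "JacDif"), rank_by = "JacDif",
                     expectation_mode = "antecedent_only",
                     select_direction = FALSE)
ranked[ranked$consequent == "Hiking Boots"]
```

```
    antecedent   consequent n_ab n_a n_b expectation   Jac JacDif
1 Travel Pants Hiking Boots   10  15  30         3.0 0.286  0.061
2      Clothes Hiking Boots   30 150  30         4.5 0.200  0.035
3    Outerwear Hiking Boots   20 100  30        20.0 0.182  0.000
4      Jackets Hiking Boots   15  90  30        18.0 0.143 -0.005
```

Jackets → Hiking Boots has a *higher* raw support (15) and Jaccard than
Travel Pants → Hiking Boots (10), but its parent rule Outerwear → Hiking
Boots predicts 20·90/100 = 18 co-occurrences — more than observed — so its
difference score is negative (−0.005). Travel Pants is expected to yield
only 20·15/100 = 3 and delivers 10, so it is ranked on top (0.061) despite
being the rarer rule.

## Command line

```sh
exec/ontorules synth --out-dir fixtures --seed 42
exec/ontorules mine --ontology fixtures/ontology1.tsv=O1 \
    --ontology fixtures/ontology2.tsv=O2 \
    --annotations fixtures/annotations.tsv \
    --measures Jac,JacDif --rank-by JacDif \
    --expectation-mode antecedent_only --ancestor-removal --out rules.tsv
exec/ontorules eval --rules rules.tsv --truth fixtures/truth.tsv
```

OBO 1.2 files (`is_a` edges; `part_of` opt-in), child–parent edge tables,
plain TSV annotations and a minimal GAF 2.x subset (with evidence-code
exclusion, e.g. IEA) are supported.

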