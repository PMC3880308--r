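---
title: "Hierarchy-aware mining of rare association rules between ontologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchy-aware mining of rare association rules between ontologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontorules)
```

## The model

Objects (proteins, database entries, documents) are classified into the
categories of one or more rooted hierarchies. Membership is upward-closed:
an object annotated with a category belongs to all of that category's
ancestors, which `ancestor_closure()` makes explicit. Each object is one
transaction; the transaction total `N` is the number of objects, including
objects carrying no annotation in the mined ontologies (relative supports
divide by the full corpus; pass a restricted `objects` vector to
`annotation_store()` to change this).

Mining is deliberately *pairwise*: all directed rules `a → b` between
categories of two ontologies (or within one) with at least one
co-occurrence. No itemset lattice is built — the hypothesis space is
category pairs, and a minimum support of one keeps the rare pairs that are
the point of the exercise. Both directions of a pair are scored; after
ranking, `direction_select()` keeps the better-ranked one.

## Interestingness measures

`compute_measure()` implements ten classical measures (see
`?measure_ids`). Five of them — Jaccard, cosine, all-confidence,
Kulczynski and confidence — are null-invariant: appending transactions
containing neither item leaves them unchanged, which matters because in
large corpora almost all transactions are null transactions for any
specific pair. Support, lift, Bayes factor, centered confidence and the φ
coefficient are not; φ does, however, converge to cosine as `N` grows with
the counts fixed, which the test suite checks numerically.

Two conventions are worth stating. The Bayes factor is implemented as the
confidence ratio `(n_ab/n_a) / ((n_b − n_ab)/(N − n_a))`, the standard
reading consistent with a `[0, ∞)` range, with `+Inf` returned when the
consequent never occurs without the antecedent (an infinitely strong
association, ranked above all finite values). φ is computed signed; a
`phi_clamp` option truncates negatives to zero for strict `[0, 1]` range
conformance, since negative dependence is not of interest in this task.

## Expected support and the difference measures

The hierarchy-aware score contrasts a rule with what its parent rules
predict. Under proportional distribution, a parent rule `pa(a) → b` with
support `n(pa, b)` predicts `n(pa, b) · n_a / n_pa` co-occurrences for the
child rule. `support_expectation()` collects one candidate per parent of
the antecedent and (in the default `both_sides_min` mode) per parent of
the consequent, and keeps the **minimum** — in a DAG the most conservative
parent explains the rule best. Root–root rules have no parent rule;
expectation falls back to the independence product `n_a·n_b/N`, so root
rules are *not* automatically interesting (in contrast to the
expected-value pruning comparator below). The `antecedent_only` mode
restricts candidates to the antecedent side — the simpler variant used in
the worked example — and treats a root antecedent with the independence
fallback.

The difference score re-evaluates the base measure (Jaccard or cosine) at
the expected count, giving `E`, and combines it with the actual value `M`
as `Dif = M·(M − E)`. The product form both rewards deviation from the
expectation and weights it by the rule's own strength, keeping noise pairs
with tiny `M` from drifting up the ranking; the plain difference `M − E`
is available via `dif_form = "plain"`. `Dif` is negative exactly when the
rule underperforms its hierarchy-based expectation — for example when a
sibling of the antecedent carries most of the parent's association — and
never exceeds `M`. A child whose transactions are distributed exactly
proportionally to its parent scores 0.

## Comparator pruning methods

Two established frameworks are implemented for comparison.

**Expected-value pruning** (`grp_prune()`) keeps a rule when its actual
support or confidence exceeds `R` times the value expected from a parent
rule (interest factor default `R = 1.1`, the canonical choice in the
literature; configurable). Root–root rules are always kept, by the
method's definition. The same expectation machinery serves both this
method and the difference measures; the expected confidence is the
expected support divided by `n_a`, which makes the two tests coincide —
kept deliberately, as it follows from defining the confidence expectation
through the support expectation.

**Agreement/structure filtering** (`grl_filter()`) keeps rules with
absolute support ≥ 10, confidence ≥ 0.8 and agreement ≥ 0.8 (all
configurable). Agreement (`agreement()`) is confidence over *unique label
combinations*: each distinct closed annotation profile counts once, so
many identically-annotated objects cannot inflate a rule.
Specific-structure pruning (`ssp_filter()`) then removes rules whose items
are ≤ 4 undirected edges apart, rules with an item having > 10
descendants, and ancestor rules. Between two disjoint ontologies no edge
path exists, so only the descendant limit applies there, with ancestor
rules removable separately by `ancestor_rule_removal()`. Descendants are
counted in the annotated sub-ontology when a support table is supplied
(categories never annotated are invisible to the analysis), otherwise in
the full graph. Ancestor-rule removal processes rules from most specific
to most general (largest combined ancestor count first), which resolves
the order dependence of the clause deterministically: a chain of
generalizations keeps only its most specific member.

The minimum-support threshold of 10 makes this framework structurally
unable to retain any rule with fewer than 10 co-occurrences — the rare
rules the difference measures are designed to find. The acceptance checks
reproduce this contrast on the synthetic benchmark.

## Structural machinery and numerical choices

* Hierarchies are `igraph` DAGs of `is_a` edges; acyclicity is verified at
  load time and a cycle is a hard error naming a member. OBO
  `relationship` types such as `part_of` are ignored unless opted in
  (`relations=`), the minimal safe reading for ancestor expansion.
  Obsolete terms are loaded but carry no edges.
* `dag_to_tree()` converts a DAG to a tree by copying each multi-parent
  node once per parent, duplicating its subtree; copies are named
  `"<id>@<tree-parent>"` (deterministic and collision-free under nesting)
  and carry provenance back to the original id. Annotation closure maps an
  annotation of a duplicated original onto every copy.
* `edge_distance()` is undirected (the structure-pruning clause does not
  orient its paths) and returns `Inf` for disconnected pairs.
* Ranking is a deterministic total order: measure value descending, then
  absolute support descending, then lexicographic antecedent/consequent.
  On a full tie of all keys the lexicographically smaller direction
  survives direction selection.
* Degenerate inputs: φ with a marginal probability of 0 or 1 returns 0
  with a warning; an expected measure value above 1 indicates inconsistent
  counts and is an error; an empty store yields an empty support table
  with `N = 0`, and measures needing `N` refuse to run on it.

## The synthetic benchmark

`synth_config()` / `generate_ontology()` / `generate_annotations()` build
a fully controlled two-ontology corpus: two complete trees (default depth
4, branching 3/3/3/4 → 108 leaves, matching the scale of a mid-sized
ontology branch), optional extra parents (`dag_fraction`) to exercise the
DAG machinery, and 2000 objects annotated at the leaves — mirroring real
usage, where annotation effort concentrates on specific categories and
interior nodes gain support only through closure. Twenty one-to-one leaf
links are planted; a source-leaf carrier also receives the linked target
leaf with probability 0.9. Thirty percent of the links are *rare*: their
source leaf is capped at 3–9 carrier objects (drawn uniformly, below the
comparator's support threshold by construction) and excluded from random
draws so the cap is exact. A 5% noise rate adds one extra random leaf per
hierarchy. All draws come from one seeded stream, so a configuration
reproduces byte-identical fixtures.

What this emulates — and what it does not: real annotation corpora have
heavily skewed category frequencies, correlated (not one-to-one) links,
multi-label objects far beyond one leaf per hierarchy, and evolving
ontology structure. A passing recovery test therefore shows the method
separates planted signal from uniform noise under leaf-biased annotation
and closure; it does not certify performance on real GO-scale data.

The recovery check ranks cross-ontology rules by `JacDif`
(antecedent-only expectations), selects directions, removes ancestor
rules — the protocol used for cross-ontology comparison, where
generalization-level relatives of every true leaf pair would otherwise
crowd the top of the list — and asks how many planted pairs appear in the
top 40, how many of the rare ones, and how many rare links survive the
threshold-based comparator at its defaults (none can, by construction).

## Problem sizes and scope

The test suite runs entirely on generated data: the 1000-transaction
worked example, random stores of up to 500 transactions checked against a
naive double-loop counting oracle, 100-case property sweeps for the
evaluation statistics, and one 2000-object benchmark run — sizes chosen so
the full suite completes in well under a minute while still exercising
every code path at meaningful scale. Known limitations: itemsets larger
than pairs are out of scope; the expectation generalizes on one side at a
time (a simultaneous two-sided generalization term is not implemented);
and qualifier handling (NOT annotations), taxon filtering and full OBO
semantics (typedefs, cross-products) are not supported.
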