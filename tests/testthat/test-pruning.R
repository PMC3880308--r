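toy_rules <- function() {
  fx <- toy_clothing_fixture()
  sup <- count_pair_supports(fx$store, c("apparel", "footwear"))
  list(fx = fx, sup = sup, rules = generate_rules(sup, fx$ontologies))
}

test_that("expected-value pruning keeps root rules and under-expectation rules only", {
  tr <- toy_rules()
  kept <- grp_prune(tr$rules, tr$sup, tr$fx$ontologies,
                    interest_factor = 1.1, expectation_mode = "antecedent_only")
  key <- paste(kept$antecedent, kept$consequent, sep = "->")
  # root-root rule survives regardless of its measure values
  expect_true("Clothes->Footwear" %in% key)
  # actual 15 below 1.1 * expected 18 on both tests: pruned
  expect_false("Jackets->Hiking Boots" %in% key)
  # actual 10 well above 1.1 * expected 3: kept
  expect_true("Travel Pants->Hiking Boots" %in% key)
  # with R = 1 every rule meeting its expectation survives
  kept1 <- grp_prune(tr$rules, tr$sup, tr$fx$ontologies, interest_factor = 1,
                     expectation_mode = "antecedent_only")
  expect_gte(nrow(kept1), nrow(kept))
  expect_error(grp_prune(tr$rules, tr$sup, tr$fx$ontologies, interest_factor = 0.5))
})

test_that("agreement counts each unique label combination once", {
  o <- flat_ontology("F", c("a", "b"))
  st <- annotation_store(
    data.frame(object_id = rep(c("p1", "p2", "p3"), times = c(2L, 2L, 1L)),
               ontology_id = "F",
               category_id = c("a", "b", "a", "b", "a")),
    list(o))
  st <- ancestor_closure(st, list(o))
  combos <- unique_combinations(st, "F")
  r <- rule_stub("a", "b", ant_ontology = "F", cons_ontology = "F")
  expect_equal(agreement(r, combos), 0.5)           # combos {a,b}, {a}
  sup <- count_pair_supports(st, "F")
  expect_equal(compute_measure("Cnf", 2, 3, 2), 2 / 3)  # object-level confidence
  expect_equal(agreement(rule_stub("b", "a"), combos), 1)  # all b-combos have a
  expect_error(agreement(rule_stub("zz", "a"), combos), "no unique combination")
})

test_that("agreement equals confidence when every object's label set is unique", {
  set.seed(21)
  fx <- random_flat_store(25)
  combos <- unique_combinations(fx$store, c("F1", "F2"))
  # this seed yields pairwise-distinct label sets, so combos == objects
  expect_equal(nrow(combos), length(unique(fx$store$labels$object_id)))
  sup <- count_pair_supports(fx$store, c("F1", "F2"))
  rules <- generate_rules(sup, fx$ontologies)
  rules$Cnf <- compute_measure("Cnf", rules$n_ab, rules$n_a, rules$n_b)
  agr <- agreement(rules, combos)
  expect_equal(agr, rules$Cnf, tolerance = 1e-12)
})

test_that("structure pruning applies the distance, descendant and ancestor clauses", {
  ch <- chain_ontology(5)
  rules <- rule_stub(c("r", "r"), c("c4", "c5"), n_ab = 2L,
                     ant_ontology = "chain", cons_ontology = "chain")
  rules$cross_ontology <- FALSE
  out <- ssp_filter(rules, list(ch), cross_ontology = FALSE)
  key <- paste(out$antecedent, out$consequent)
  expect_false("r c4" %in% key)  # 4 edges apart: pruned
  expect_true("r c5" %in% key)   # 5 edges apart: kept

  long <- chain_ontology(12)     # root has 12 > 10 descendants
  r2 <- rule_stub("r", "c12", ant_ontology = "chain", cons_ontology = "chain")
  r2$cross_ontology <- FALSE
  expect_equal(nrow(ssp_filter(r2, list(long), cross_ontology = FALSE)), 0L)
  # restricted to an annotated sub-ontology with few categories, r survives
  # the descendant limit (and r--c12 are 12 > 4 edges apart)
  sup <- list(item_counts = stats::setNames(rep(1L, 2), c("r", "c12")))
  class(sup) <- "support_table"
  expect_equal(nrow(ssp_filter(r2, list(long), cross_ontology = FALSE,
                               supports = sup)), 1L)

  # cross-ontology mode applies only the descendant limit (no distances
  # exist between disjoint graphs)
  o1 <- chain_ontology(12, id = "L"); o2 <- flat_ontology("R", "z")
  rx <- rule_stub(c("r", "c12"), c("z", "z"),
                  ant_ontology = "L", cons_ontology = "R")
  outx <- ssp_filter(rx, list(o1, o2), cross_ontology = TRUE)
  expect_equal(outx$antecedent, "c12")  # r pruned on descendants only
})

test_that("ancestor rules are removed in favor of their most specific specialization", {
  ch <- chain_ontology(3)
  oz <- flat_ontology("Z", "z")
  rules <- rule_stub(c("c3", "c2", "c1"), c("z", "z", "z"),
                     ant_ontology = "chain", cons_ontology = "Z")
  out <- ancestor_rule_removal(rules, list(ch, oz))
  expect_equal(out$antecedent, "c3")  # chain of generalizations: deepest kept

  pair <- rule_stub(c("c3", "c2"), c("z", "z"),
                    ant_ontology = "chain", cons_ontology = "Z")
  expect_equal(ancestor_rule_removal(pair, list(ch, oz))$antecedent, "c3")

  unrelated <- rule_stub(c("c3", "r"), c("z", "y"),
                         ant_ontology = "chain", cons_ontology = "Z")
  oz2 <- flat_ontology("Z", c("z", "y"))
  expect_equal(nrow(ancestor_rule_removal(unrelated, list(ch, oz2))), 2L)
})

test_that("threshold filtering is monotone and rejects at its boundaries", {
  tr <- toy_rules()
  combos <- unique_combinations(tr$fx$store, c("apparel", "footwear"))
  base <- grl_filter(tr$rules, tr$sup, combos, tr$fx$ontologies,
                     min_abs_support = 1, min_cnf = 0.1, min_agr = 0.1,
                     ssp = FALSE)
  key <- function(r) paste(r$antecedent, r$consequent)
  for (args in list(list(min_abs_support = 11), list(min_cnf = 0.5),
                    list(min_agr = 0.5))) {
    tighter <- do.call(grl_filter,
                       c(list(tr$rules, tr$sup, combos, tr$fx$ontologies,
                              ssp = FALSE),
                         utils::modifyList(list(min_abs_support = 1,
                                                min_cnf = 0.1, min_agr = 0.1),
                                           args)))
    expect_true(all(key(tighter) %in% key(base)))
  }
  # absolute support 9 fails a minimum of 10
  r9 <- rule_stub("a", "b", n_ab = 9L)
  r9$n_a <- 9L; r9$n_b <- 9L
  o <- flat_ontology("L", "a"); o2 <- flat_ontology("R", "b")
  cmb <- structure(data.table::data.table(labels = list(c("a", "b")),
                                          n_objects = 1L),
                   class = c("combo_table", "data.table", "data.frame"))
  expect_equal(nrow(grl_filter(r9, NULL, cmb, list(o, o2),
                               min_abs_support = 10, ssp = FALSE)), 0L)
  # confidence passes but agreement fails
  r <- rule_stub("a", "b", n_ab = 10L)
  r$n_a <- 10L; r$n_b <- 12L
  cmb2 <- structure(data.table::data.table(labels = list(c("a", "b"), "a"),
                                           n_objects = c(1L, 1L)),
                    class = c("combo_table", "data.table", "data.frame"))
  expect_equal(nrow(grl_filter(r, NULL, cmb2, list(o, o2),
                               min_abs_support = 10, min_cnf = 0.8,
                               min_agr = 0.8, ssp = FALSE)), 0L)
})
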