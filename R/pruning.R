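#' Expected-value pruning of generalized rules
#'
#' The classical pruning scheme for generalized association rules: a
#' specialized rule deeper in the hierarchy is kept only if its actual
#' support or confidence exceeds the value expected from its parent rule by
#' at least the interest factor `R`. Rules between two root categories have
#' no parent rule and are always considered interesting by this scheme
#' (one of its acknowledged weaknesses for ontology data, where root-level
#' rules are the least informative ones). Survivors are ranked by
#' confidence.
#'
#' @param rules a `rule_table`.
#' @param supports the matching [count_pair_supports()] table.
#' @param ontologies list of [ontology()] objects.
#' @param interest_factor multiplicative threshold `R >= 1` (default 1.1).
#' @param tests which of the support and confidence tests to apply; a rule
#'   survives if it passes any applied test.
#' @param expectation_mode passed to [support_expectation()].
#' @return the surviving `rule_table`, ranked by `Cnf`.
#' @export
grp_prune <- function(rules, supports, ontologies, interest_factor = 1.1,
                      tests = c("support", "confidence"),
                      expectation_mode = "both_sides_min") {
  stopifnot(interest_factor >= 1)
  tests <- match.arg(tests, several.ok = TRUE)
  if (!nrow(rules)) return(rules)
  names(ontologies) <- vapply(ontologies, `[[`, "", "ontology_id")
  root_of <- function(ont, id) id %in% ontologies[[ont]]$roots
  a_root <- mapply(root_of, rules$ant_ontology, rules$antecedent)
  b_root <- mapply(root_of, rules$cons_ontology, rules$consequent)

  expected <- support_expectation(rules, ontologies, supports,
                                  mode = expectation_mode)
  keep <- a_root & b_root
  if ("support" %in% tests)
    keep <- keep | rules$n_ab >= interest_factor * expected
  if ("confidence" %in% tests)
    keep <- keep | rules$n_ab / rules$n_a >= interest_factor * expected / rules$n_a
  out <- rules[keep]
  if (!"Cnf" %in% names(out))
    out$Cnf <- compute_measure("Cnf", out$n_ab, out$n_a, out$n_b)
  rank_rules(out, "Cnf")
}

#' Agreement: confidence over unique label combinations
#'
#' Confidence recomputed with every distinct (closed) annotation profile
#' counted once, however many objects share it: the number of unique
#' combinations containing both items divided by the number containing the
#' antecedent. Repeatedly co-annotated but identical objects therefore do
#' not inflate the score.
#'
#' @param rules a `rule_table`.
#' @param combos a [unique_combinations()] table over the rules' ontology
#'   scope.
#' @return numeric vector of agreement values in `[0, 1]`.
#' @export
agreement <- function(rules, combos) {
  stopifnot(inherits(combos, "combo_table"))
  items <- unique(c(rules$antecedent, rules$consequent))
  # membership matrix: combos x items
  memb <- vapply(items, function(it)
    vapply(combos$labels, function(l) it %in% l, TRUE),
    logical(nrow(combos)))
  if (nrow(combos) == 1L) memb <- matrix(memb, nrow = 1L, dimnames = list(NULL, items))
  n_a <- colSums(memb)[rules$antecedent]
  if (any(n_a == 0))
    stop("agreement undefined: no unique combination contains antecedent '",
         rules$antecedent[which(n_a == 0)[1L]], "'")
  n_ab <- vapply(seq_len(nrow(rules)), function(i)
    sum(memb[, rules$antecedent[i]] & memb[, rules$consequent[i]]), 0)
  unname(n_ab / n_a)
}

#' Structure-based rule pruning
#'
#' Removes, within one ontology, rules whose items are structurally too
#' close or too general to be informative: items connected by
#' `max_edge_distance` or fewer undirected edges, items with more than
#' `max_descendants` descendants, and ancestor rules (a rule both of whose
#' items are ancestors-or-equal of another retained rule's items, with at
#' least one strict). Between two different ontologies the edge-distance
#' clause is meaningless and the ancestor clause is handled separately by
#' [ancestor_rule_removal()], so only the descendant limit applies.
#' Descendants are counted within the annotated sub-ontology when
#' `supports` is given (only categories that actually occur), otherwise in
#' the full ontology.
#'
#' @param rules a `rule_table`.
#' @param ontologies list of [ontology()] objects.
#' @param cross_ontology logical: is the scope a pair of ontologies?
#' @param max_edge_distance rules at this undirected distance or less are
#'   pruned (intra-ontology only; default 4).
#' @param max_descendants items with more than this many descendants are
#'   pruned (default 10).
#' @param supports optional [count_pair_supports()] table restricting
#'   descendant counting to annotated categories.
#' @return the surviving `rule_table`.
#' @export
ssp_filter <- function(rules, ontologies, cross_ontology = FALSE,
                       max_edge_distance = 4, max_descendants = 10,
                       supports = NULL) {
  if (!nrow(rules)) return(rules)
  names(ontologies) <- vapply(ontologies, `[[`, "", "ontology_id")
  within <- NULL
  if (!is.null(supports))
    within <- names(supports$item_counts)[supports$item_counts > 0]

  items <- unique(data.frame(
    id = c(rules$antecedent, rules$consequent),
    ont = c(rules$ant_ontology, rules$cons_ontology)))
  ndesc <- mapply(function(id, ont)
    descendant_count(ontologies[[ont]], id, within = within),
    items$id, items$ont)
  names(ndesc) <- items$id
  keep <- ndesc[rules$antecedent] <= max_descendants &
          ndesc[rules$consequent] <= max_descendants

  if (!cross_ontology) {
    same <- rules$ant_ontology == rules$cons_ontology
    dist_ok <- rep(TRUE, nrow(rules))
    idx <- which(same & keep)
    for (i in idx) {
      d <- edge_distance(ontologies[[rules$ant_ontology[i]]],
                         rules$antecedent[i], rules$consequent[i])
      dist_ok[i] <- d > max_edge_distance
    }
    keep <- keep & dist_ok
    out <- rules[keep]
    return(ancestor_rule_removal(out, ontologies))
  }
  rules[keep]
}

#' Remove ancestor rules from a rule set
#'
#' A rule is removed when a retained rule exists whose antecedent and
#' consequent are descendants-or-equal of this rule's antecedent and
#' consequent respectively (and the rules differ): the more general rule
#' carries no information beyond its specialization. Rules are processed
#' from most specific (largest combined ancestor count) to most general,
#' so a chain of generalizations keeps only its most specific member.
#'
#' @param rules a `rule_table`.
#' @param ontologies list of [ontology()] objects.
#' @return the `rule_table` without ancestor rules, input order preserved.
#' @export
ancestor_rule_removal <- function(rules, ontologies) {
  if (!nrow(rules)) return(rules)
  names(ontologies) <- vapply(ontologies, `[[`, "", "ontology_id")

  items <- unique(data.frame(
    id = c(rules$antecedent, rules$consequent),
    ont = c(rules$ant_ontology, rules$cons_ontology)))
  amap <- list()
  for (ont in unique(items$ont))
    amap <- c(amap, ancestors_map(ontologies[[ont]], items$id[items$ont == ont]))
  depth <- lengths(amap)

  spec <- depth[rules$antecedent] + depth[rules$consequent]
  ord <- order(-spec)
  dominated <- new.env(hash = TRUE, parent = emptyenv())
  keep <- logical(nrow(rules))
  for (i in ord) {
    a <- rules$antecedent[i]; b <- rules$consequent[i]
    self_key <- paste(a, b, sep = "\r")
    if (!is.null(dominated[[self_key]])) next
    keep[i] <- TRUE
    # mark every generalization (ancestor-or-self on both sides) as dominated
    for (ga in c(a, amap[[a]]))
      for (gb in c(b, amap[[b]])) {
        k <- paste(ga, gb, sep = "\r")
        if (k != self_key) dominated[[k]] <- TRUE
      }
  }
  rules[keep]
}

#' Agreement-and-structure rule filtering
#'
#' The comparator filtering pipeline built around confidence: keep rules
#' with absolute support, confidence and agreement above their thresholds,
#' then apply structure-based pruning ([ssp_filter()]; between two
#' ontologies additionally [ancestor_rule_removal()]), and rank the
#' survivors by confidence. The default minimum absolute support of 10
#' co-occurrences makes this scheme blind to rare rules by construction.
#'
#' @param rules a `rule_table`.
#' @param supports the matching [count_pair_supports()] table.
#' @param combos a [unique_combinations()] table for the agreement test.
#' @param ontologies list of [ontology()] objects.
#' @param min_abs_support minimum co-occurrence count (default 10).
#' @param min_cnf minimum confidence (default 0.8).
#' @param min_agr minimum agreement (default 0.8).
#' @param ssp apply structure-based pruning (default TRUE).
#' @param cross_ontology passed to [ssp_filter()]; when TRUE, ancestor
#'   rules are removed after the descendant limit.
#' @return the surviving `rule_table`, ranked by `Cnf`.
#' @export
grl_filter <- function(rules, supports, combos, ontologies,
                       min_abs_support = 10, min_cnf = 0.8, min_agr = 0.8,
                       ssp = TRUE, cross_ontology = FALSE) {
  stopifnot(min_cnf >= 0, min_cnf <= 1, min_agr >= 0, min_agr <= 1)
  if (!nrow(rules)) return(rules)
  if (!"Cnf" %in% names(rules))
    rules$Cnf <- compute_measure("Cnf", rules$n_ab, rules$n_a, rules$n_b)
  keep <- rules$n_ab >= min_abs_support & rules$Cnf >= min_cnf
  out <- rules[keep]
  if (nrow(out)) {
    out$Agr <- agreement(out, combos)
    out <- out[out$Agr >= min_agr]
  }
  if (ssp && nrow(out)) {
    out <- ssp_filter(out, ontologies, cross_ontology = cross_ontology,
                      supports = supports)
    if (cross_ontology && nrow(out))
      out <- ancestor_rule_removal(out, ontologies)
  }
  if (!nrow(out)) return(out)
  rank_rules(out, "Cnf")
}
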