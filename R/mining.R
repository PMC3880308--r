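#' Count item and pair supports over a transaction database
#'
#' Computes absolute supports: `n(a)` for every category with at least one
#' annotated object, and `n(a, b)` for every category pair in scope that
#' co-occurs in at least `min_abs_support` transactions. The default
#' minimum of one occurrence deliberately keeps rare pairs: associations
#' between specific, infrequent categories are the ones of interest here.
#' Scope is either a pair of distinct ontology ids (cross-ontology pairs)
#' or a single id (pairs within one ontology). Category ids must not
#' collide between the two ontologies of a cross scope.
#'
#' @param store a closed [annotation_store()].
#' @param scope character vector of one (intra-ontology) or two
#'   (cross-ontology) ontology ids.
#' @param min_abs_support minimum absolute co-occurrence count (default 1).
#' @return An object of class `support_table`: list with `N`, `item_counts`
#'   (named integer), `pair_counts` (data.table `item_a`, `item_b`,
#'   `n_ab`), `scope` and `ontology_of` (named character mapping category
#'   to ontology id).
#' @export
count_pair_supports <- function(store, scope, min_abs_support = 1L) {
  stopifnot(inherits(store, "annotation_store"),
            is.character(scope), length(scope) %in% 1:2,
            min_abs_support >= 1L)
  if (!store$closed) stop("store must be ancestor-closed before counting")
  cross <- length(scope) == 2L
  if (cross && scope[1L] == scope[2L]) { scope <- scope[1L]; cross <- FALSE }

  lab <- store$labels[store$labels$ontology_id %in% scope]
  item_dt <- lab[, list(n = .N), by = c("ontology_id", "category_id")]
  if (cross && anyDuplicated(item_dt$category_id))
    stop("category ids collide between the two ontologies in scope")
  item_counts <- stats::setNames(as.integer(item_dt$n), item_dt$category_id)
  ontology_of <- stats::setNames(item_dt$ontology_id, item_dt$category_id)

  if (!nrow(lab)) {
    pairs <- data.table::data.table(item_a = character(), item_b = character(),
                                    n_ab = integer())
  } else if (cross) {
    d1 <- lab[lab$ontology_id == scope[1L], c("object_id", "category_id"), with = FALSE]
    d2 <- lab[lab$ontology_id == scope[2L], c("object_id", "category_id"), with = FALSE]
    data.table::setnames(d1, "category_id", "item_a")
    data.table::setnames(d2, "category_id", "item_b")
    j <- merge(d1, d2, by = "object_id", allow.cartesian = TRUE)
    pairs <- j[, list(n_ab = .N), by = c("item_a", "item_b")]
  } else {
    d <- lab[, c("object_id", "category_id"), with = FALSE]
    d2 <- data.table::copy(d)
    data.table::setnames(d, "category_id", "item_a")
    data.table::setnames(d2, "category_id", "item_b")
    j <- merge(d, d2, by = "object_id", allow.cartesian = TRUE)
    j <- j[j$item_a < j$item_b]
    pairs <- j[, list(n_ab = .N), by = c("item_a", "item_b")]
  }
  pairs <- pairs[pairs$n_ab >= min_abs_support]
  data.table::setkeyv(pairs, c("item_a", "item_b"))

  structure(
    list(N = store$N, item_counts = item_counts, pair_counts = pairs,
         scope = scope, ontology_of = ontology_of,
         min_abs_support = as.integer(min_abs_support)),
    class = "support_table")
}

#' @export
print.support_table <- function(x, ...) {
  cat(sprintf("<support_table>: N=%d, %d items, %d pairs (min abs support %d)\n",
              x$N, length(x$item_counts), nrow(x$pair_counts), x$min_abs_support))
  invisible(x)
}

# co-occurrence count of an (x, y) pair; 0 when the pair was not retained.
# Vectorized over x/y; orientation-insensitive.
pair_count <- function(supports, x, y) {
  pc <- supports$pair_counts
  a <- pmin(x, y); b <- pmax(x, y)
  # cross-ontology tables key pairs as (scope[1] item, scope[2] item)
  if (length(supports$scope) == 2L) {
    o1 <- supports$ontology_of[x] == supports$scope[1L]
    a <- ifelse(o1, x, y); b <- ifelse(o1, y, x)
  }
  idx <- pc[data.table::data.table(item_a = a, item_b = b), on = c("item_a", "item_b"),
            which = TRUE]
  n <- pc$n_ab[idx]
  n[is.na(n)] <- 0L
  as.integer(n)
}

#' Generate directed candidate rules from a support table
#'
#' Each retained unordered pair yields both directed rules `a -> b` and
#' `b -> a`. Rules inside one ontology whose consequent is an ancestor of
#' the antecedent are flagged `hierarchical`: after ancestor closure these
#' child-to-parent rules hold with confidence 1 by construction and are
#' trivially true, so downstream filters may wish to drop them.
#'
#' @param supports a [count_pair_supports()] result.
#' @param ontologies list of [ontology()] objects (needed for the
#'   `hierarchical` flag; may be omitted for cross-ontology scopes).
#' @return a `rule_table`: data.table with columns `antecedent`,
#'   `consequent`, `ant_ontology`, `cons_ontology`, `n_ab`, `n_a`, `n_b`,
#'   `N`, `cross_ontology`, `hierarchical`.
#' @export
generate_rules <- function(supports, ontologies = NULL) {
  stopifnot(inherits(supports, "support_table"))
  pc <- supports$pair_counts
  rules <- data.table::data.table(
    antecedent = c(pc$item_a, pc$item_b),
    consequent = c(pc$item_b, pc$item_a),
    n_ab = rep(pc$n_ab, 2L))
  rules$ant_ontology <- unname(supports$ontology_of[rules$antecedent])
  rules$cons_ontology <- unname(supports$ontology_of[rules$consequent])
  rules$n_a <- unname(supports$item_counts[rules$antecedent])
  rules$n_b <- unname(supports$item_counts[rules$consequent])
  rules$N <- supports$N
  rules$cross_ontology <- rules$ant_ontology != rules$cons_ontology
  rules$hierarchical <- FALSE
  if (any(!rules$cross_ontology) && !is.null(ontologies)) {
    names(ontologies) <- vapply(ontologies, `[[`, "", "ontology_id")
    for (oid in unique(rules$ant_ontology[!rules$cross_ontology])) {
      sel <- which(!rules$cross_ontology & rules$ant_ontology == oid)
      amap <- ancestors_map(ontologies[[oid]], unique(rules$antecedent[sel]))
      rules$hierarchical[sel] <- mapply(
        function(a, b) b %in% amap[[a]],
        rules$antecedent[sel], rules$consequent[sel])
    }
  }
  data.table::setcolorder(rules, c("antecedent", "consequent", "ant_ontology",
                                   "cons_ontology", "n_ab", "n_a", "n_b", "N",
                                   "cross_ontology", "hierarchical"))
  class(rules) <- c("rule_table", class(rules))
  rules[]
}

#' Rank rules by a measure value
#'
#' Sorts descending by the measure column, breaking ties by absolute
#' support `n_ab` (descending) and then lexicographically by antecedent and
#' consequent, giving a deterministic total order across runs.
#'
#' @param rules a `rule_table` carrying the measure column (see
#'   [annotate_measures()]).
#' @param measure measure id naming a column of `rules`.
#' @param descending sort direction for the measure value.
#' @return the reordered `rule_table`.
#' @export
rank_rules <- function(rules, measure, descending = TRUE) {
  if (!measure %in% names(rules))
    stop("rules carry no '", measure, "' column; run annotate_measures() first")
  v <- rules[[measure]]
  if (anyNA(v)) stop("missing '", measure, "' values; cannot rank")
  ord <- order(if (descending) -xtfrm(v) else xtfrm(v),
               -rules$n_ab, rules$antecedent, rules$consequent)
  rules[ord]
}

#' Keep only the better-ranked direction of each rule pair
#'
#' A pair `{a, b}` appears as both `a -> b` and `b -> a`; only the
#' direction ranked earlier is kept. On an exact tie of all ranking keys
#' the lexicographically smaller direction comes first in
#' [rank_rules()] order and therefore survives.
#'
#' @param ranked a ranked `rule_table` (output of [rank_rules()]).
#' @return the `rule_table` restricted to one direction per pair, order
#'   preserved.
#' @export
direction_select <- function(ranked) {
  key <- paste(pmin(ranked$antecedent, ranked$consequent),
               pmax(ranked$antecedent, ranked$consequent), sep = "\r")
  ranked[!duplicated(key)]
}

# unordered pair key, used for truth matching and intersections
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
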