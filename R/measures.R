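#' Interestingness measure registry
#'
#' Twelve measures are available under their conventional abbreviations.
#' With absolute counts `n_ab` (co-occurrences of antecedent a and
#' consequent b), `n_a`, `n_b` and the transaction total `N`:
#'
#' * `Sup`  = n_ab / N
#' * `Cnf`  = n_ab / n_a
#' * `Cos`  = n_ab / sqrt(n_a * n_b)
#' * `ACnf` = n_ab / max(n_a, n_b)  (all-confidence)
#' * `Kulc` = (n_ab/n_a + n_ab/n_b) / 2  (Kulczynski)
#' * `Lift` = N * n_ab / (n_a * n_b)
#' * `BF`   = (n_ab/n_a) / ((n_b - n_ab)/(N - n_a))  (Bayes factor,
#'   confidence against b in the absence of a; `+Inf` when n_ab = n_b)
#' * `CCnf` = n_ab/n_a - n_b/N  (centered confidence)
#' * `Phi`  = (P_ab - P_a P_b) / sqrt(P_a P_b (1-P_a)(1-P_b)), P_x = n_x/N
#' * `Jac`  = n_ab / (n_a + n_b - n_ab)  (Jaccard)
#' * `JacDif`, `CosDif` — hierarchy-aware differences, see [dif_measure()]
#'
#' `Jac`, `Cos`, `ACnf`, `Kulc` and `Cnf` are null-invariant: adding
#' transactions that contain neither a nor b leaves them unchanged, which
#' makes them suitable for rare rules. `Sup`, `Lift`, `BF`, `CCnf` and
#' `Phi` depend on `N`.
#'
#' @return `measure_ids()` returns the character vector of measure ids;
#'   `measure_needs_N(id)` says whether a measure depends on the
#'   transaction total.
#' @export
measure_ids <- function() {
  c("Sup", "Cnf", "Cos", "ACnf", "Kulc", "Lift", "BF", "CCnf", "Phi",
    "Jac", "JacDif", "CosDif")
}

#' @rdname measure_ids
#' @param measure_id one of `measure_ids()`.
#' @export
measure_needs_N <- function(measure_id) {
  measure_id %in% c("Sup", "Lift", "BF", "CCnf", "Phi")
}

#' Evaluate an interestingness measure on absolute counts
#'
#' Vectorized over the count arguments. `n_ab` may be fractional: the
#' difference measures re-evaluate a base measure at the (real-valued)
#' expected support count.
#'
#' @param measure_id one of the non-difference ids of [measure_ids()].
#' @param n_ab co-occurrence count of the pair (may be fractional when
#'   evaluating at an expectation).
#' @param n_a,n_b item counts (must be >= 1).
#' @param N transaction total; required for `Sup`, `Lift`, `BF`, `CCnf`,
#'   `Phi`.
#' @param phi_clamp clamp negative phi values to 0 (so the value range is
#'   `[0, 1]`); default keeps the signed coefficient.
#' @return numeric vector of measure values.
#' @export
compute_measure <- function(measure_id, n_ab, n_a, n_b, N = NULL,
                            phi_clamp = FALSE) {
  measure_id <- match.arg(measure_id, setdiff(measure_ids(), c("JacDif", "CosDif")))
  if (any(n_a < 1) || any(n_b < 1)) stop("item counts must be >= 1")
  if (any(n_ab < 0) || any(n_ab > pmin(n_a, n_b) + 1e-9))
    stop("n_ab must lie in [0, min(n_a, n_b)]")
  if (measure_needs_N(measure_id)) {
    if (is.null(N)) stop("measure '", measure_id, "' needs the transaction total N")
    if (any(N < pmax(n_a, n_b))) stop("N must be >= max(n_a, n_b)")
  }
  switch(measure_id,
    Sup  = n_ab / N,
    Cnf  = n_ab / n_a,
    Cos  = n_ab / sqrt(n_a * n_b),
    ACnf = n_ab / pmax(n_a, n_b),
    Kulc = 0.5 * (n_ab / n_a + n_ab / n_b),
    Lift = N * n_ab / (n_a * n_b),
    BF   = {
      out <- (n_ab / n_a) / ((n_b - n_ab) / (N - n_a))
      out[n_ab == n_b] <- Inf  # no b without a: rank above all finite values
      out
    },
    CCnf = n_ab / n_a - n_b / N,
    Phi  = {
      p_ab <- n_ab / N; p_a <- n_a / N; p_b <- n_b / N
      den <- sqrt(p_a * p_b * (1 - p_a) * (1 - p_b))
      out <- (p_ab - p_a * p_b) / den
      degenerate <- p_a %in% c(0, 1) | p_b %in% c(0, 1)
      if (any(degenerate)) {
        warning("phi undefined for marginal probability 0 or 1; returning 0")
        out[degenerate] <- 0
      }
      if (phi_clamp) out <- pmax(out, 0)
      out
    },
    Jac  = n_ab / (n_a + n_b - n_ab))
}

#' Expected support count of a rule from its parent rules
#'
#' Under the proportional-distribution assumption, a child rule
#' `a -> b` is expected to inherit the parent rule's support scaled by the
#' child-to-parent item-support ratio: for a parent `pa` of `a`, the
#' candidate expectation is `n(pa, b) * n_a / n_pa`, and symmetrically
#' `n(a, pb) * n_b / n_pb` for a parent `pb` of `b`. When a category has
#' multiple parents (a DAG), the smallest candidate over all parents is
#' kept. When both items are roots no parent rule exists and the
#' independence expectation `n_a * n_b / N` is used instead (root rules are
#' exactly the ones a hierarchy cannot explain).
#'
#' Mode `"antecedent_only"` generalizes only on the antecedent side: the
#' candidates are restricted to parents of `a`, and a root antecedent falls
#' back to the independence expectation.
#'
#' @param rules a `rule_table` (see [generate_rules()]).
#' @param ontologies list of [ontology()] objects covering the rule items.
#' @param supports the [count_pair_supports()] table the rules came from.
#' @param mode `"both_sides_min"` (default) or `"antecedent_only"`.
#' @return numeric vector of expected support counts, one per rule.
#' @export
support_expectation <- function(rules, ontologies, supports,
                                mode = c("both_sides_min", "antecedent_only")) {
  mode <- match.arg(mode)
  names(ontologies) <- vapply(ontologies, `[[`, "", "ontology_id")
  n <- nrow(rules)
  out <- numeric(n)
  items <- unique(c(rules$antecedent, rules$consequent))
  ont_of <- c(stats::setNames(rules$ant_ontology, rules$antecedent),
              stats::setNames(rules$cons_ontology, rules$consequent))[items]
  par_of <- lapply(seq_along(items), function(i) {
    o <- ontologies[[ont_of[[i]]]]
    if (is.null(o)) stop("no ontology loaded for id '", ont_of[[i]], "'")
    o$parents[[items[[i]]]]
  })
  names(par_of) <- items
  ic <- supports$item_counts

  for (i in seq_len(n)) {
    a <- rules$antecedent[i]; b <- rules$consequent[i]
    pa <- par_of[[a]]; pb <- par_of[[b]]
    a_root <- is.null(pa) || length(pa) == 0L
    b_root <- is.null(pb) || length(pb) == 0L
    independent <- a_root && (mode == "antecedent_only" || b_root)
    if (independent) {
      out[i] <- rules$n_a[i] * rules$n_b[i] / rules$N[i]
      next
    }
    cand <- numeric()
    if (!a_root) {
      n_pa <- ic[pa]
      if (anyNA(n_pa) || any(n_pa == 0))
        stop("inconsistent hierarchy: parent of '", a, "' has no support count")
      cand <- c(cand, pair_count(supports, pa, rep(b, length(pa))) *
                        rules$n_a[i] / n_pa)
    }
    if (mode == "both_sides_min" && !b_root) {
      n_pb <- ic[pb]
      if (anyNA(n_pb) || any(n_pb == 0))
        stop("inconsistent hierarchy: parent of '", b, "' has no support count")
      cand <- c(cand, pair_count(supports, rep(a, length(pb)), pb) *
                        rules$n_b[i] / n_pb)
    }
    if (!length(cand)) stop("no expectation candidate for rule ", a, " -> ", b)
    out[i] <- min(cand)
  }
  out
}

#' Interestingness by difference
#'
#' Scores a rule by contrasting its actual measure value `M` with the value
#' `E` expected from its parent rule: the base measure is re-evaluated with
#' the co-occurrence count replaced by the expected support count of
#' [support_expectation()]. The default functional form is the product
#' `Dif = M * (M - E)`, which weights the deviation from expectation by the
#' strength of the rule itself; the plain difference `M - E` is available
#' via `form = "plain"`. The score is negative exactly when the rule is
#' weaker than its hierarchy leads one to expect — for instance when a
#' sibling of the antecedent carries most of the parent's association — and
#' it never exceeds `M`.
#'
#' @param base_measure `"Jac"` or `"Cos"`.
#' @param n_ab,n_a,n_b absolute counts of the rule.
#' @param expected_count expected support count (from
#'   [support_expectation()]).
#' @param form `"product"` (default) or `"plain"`.
#' @return numeric vector of difference scores.
#' @export
dif_measure <- function(base_measure = c("Jac", "Cos"), n_ab, n_a, n_b,
                        expected_count, form = c("product", "plain")) {
  base_measure <- match.arg(base_measure)
  form <- match.arg(form)
  m <- compute_measure(base_measure, n_ab, n_a, n_b)
  e <- switch(base_measure,
              Jac = expected_count / (n_a + n_b - expected_count),
              Cos = expected_count / sqrt(n_a * n_b))
  if (any(e > 1 + 1e-9))
    stop("expected measure value exceeds 1: inconsistent counts")
  if (form == "product") m * (m - e) else m - e
}

#' Attach measure values (and expectations) to a rule table
#'
#' Adds one column per requested measure. Requesting `JacDif` or `CosDif`
#' triggers the expectation computation, whose expected support counts are
#' stored in an `expectation` column.
#'
#' @param rules a `rule_table`.
#' @param measures character vector of measure ids (see [measure_ids()]).
#' @param supports the [count_pair_supports()] table.
#' @param ontologies list of [ontology()] objects; required for the
#'   difference measures.
#' @param expectation_mode passed to [support_expectation()].
#' @param dif_form passed to [dif_measure()].
#' @param phi_clamp passed to [compute_measure()].
#' @return the `rule_table` with measure columns added.
#' @export
annotate_measures <- function(rules, measures, supports, ontologies = NULL,
                              expectation_mode = c("both_sides_min", "antecedent_only"),
                              dif_form = c("product", "plain"),
                              phi_clamp = FALSE) {
  expectation_mode <- match.arg(expectation_mode)
  dif_form <- match.arg(dif_form)
  bad <- setdiff(measures, measure_ids())
  if (length(bad)) stop("unknown measure id: ", paste(bad, collapse = ", "))
  if (!nrow(rules) || !length(measures)) return(rules)
  if (any(measure_needs_N(measures)) && supports$N == 0L)
    stop("measures requiring N cannot be computed on an empty transaction set")

  needs_exp <- any(measures %in% c("JacDif", "CosDif"))
  if (needs_exp) {
    if (is.null(ontologies))
      stop("difference measures need the ontologies to find parent rules")
    rules$expectation <- support_expectation(rules, ontologies, supports,
                                             mode = expectation_mode)
  }
  for (m in measures) {
    rules[[m]] <-
      if (m %in% c("JacDif", "CosDif"))
        dif_measure(sub("Dif$", "", m), rules$n_ab, rules$n_a, rules$n_b,
                    rules$expectation, form = dif_form)
      else
        compute_measure(m, rules$n_ab, rules$n_a, rules$n_b, N = rules$N,
                        phi_clamp = phi_clamp)
  }
  rules[]
}
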