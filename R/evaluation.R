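#' Ground-truth pair set
#'
#' A ground truth is a set of unordered category pairs known to be truly
#' linked (for instance a manually curated mapping between two
#' ontologies). Matching is direction-insensitive: a directed rule matches
#' a truth pair if its unordered item pair does.
#'
#' @param item_a,item_b character vectors of linked category ids.
#' @return an object of class `ground_truth` (a data.frame with a
#'   normalized unordered `key`).
#' @export
ground_truth <- function(item_a, item_b) {
  stopifnot(length(item_a) == length(item_b))
  df <- data.frame(item_a = as.character(item_a),
                   item_b = as.character(item_b),
                   stringsAsFactors = FALSE)
  df$key <- pair_key(df$item_a, df$item_b)
  df <- df[!duplicated(df$key), ]
  class(df) <- c("ground_truth", class(df))
  df
}

#' Read a ground-truth file (two tab-separated columns, one pair per line)
#' @param path file path.
#' @return a [ground_truth()].
#' @export
load_ground_truth <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (ncol(dt) < 2L) stop("ground-truth file needs two columns")
  ground_truth(dt[[1L]], dt[[2L]])
}

#' F-1 of the top k rules against a ground truth
#'
#' Precision is the fraction of the first `k` rules matching a truth pair,
#' recall the fraction of truth pairs found among them, and F-1 their
#' harmonic mean (0 when both are 0), reported as a percentage. By default
#' `k` equals the number of truth pairs, so precision and recall coincide.
#'
#' @param ranked a ranked `rule_table`.
#' @param truth a [ground_truth()].
#' @param k prefix size (default `nrow(truth)`).
#' @return list with `true_found`, `precision`, `recall` and `f1` (percent).
#' @export
f1_at_k <- function(ranked, truth, k = nrow(truth)) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!nrow(truth)) stop("empty ground truth")
  if (k > nrow(ranked)) stop("k exceeds the number of ranked rules")
  head_keys <- pair_key(ranked$antecedent, ranked$consequent)[seq_len(k)]
  tp <- sum(unique(head_keys) %in% truth$key)
  p <- tp / k
  r <- tp / nrow(truth)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(true_found = tp, precision = p, recall = r, f1 = 100 * f1)
}

#' Best-possible F-1 over all prefixes of a ranking
#'
#' Equivalent to iteratively removing the lowest-ranked rule and
#' re-scoring: evaluates F-1 on every prefix of the ranking and returns the
#' prefix that maximizes it (ties resolved toward the smaller prefix).
#'
#' @inheritParams f1_at_k
#' @return list with `size`, `true_found` and `f1` (percent).
#' @export
best_possible_f1 <- function(ranked, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!nrow(truth)) stop("empty ground truth")
  if (!nrow(ranked)) return(list(size = 0L, true_found = 0L, f1 = 0))
  keys <- pair_key(ranked$antecedent, ranked$consequent)
  is_true <- keys %in% truth$key & !duplicated(keys)
  tp <- cumsum(is_true)
  k <- seq_along(tp)
  p <- tp / k
  r <- tp / nrow(truth)
  f1 <- ifelse(p + r == 0, 0, 2 * p * r / (p + r))
  best <- which.max(f1)  # first maximum: smallest prefix on ties
  list(size = best, true_found = tp[best], f1 = 100 * f1[best])
}

#' Median absolute support of a rule set
#'
#' The median co-occurrence count; preferred over the mean because single
#' very frequent rules would dominate it. Even-sized sets use the midpoint
#' of the two central values.
#'
#' @param rules a nonempty `rule_table`.
#' @return numeric scalar.
#' @export
median_abs_support <- function(rules) {
  if (!nrow(rules)) stop("empty rule set")
  stats::median(rules$n_ab)
}

#' Number of common rules among the top n of two rankings
#'
#' Counts unordered category pairs shared by the first `top_n` rules of
#' each ranking (after direction selection a ranking holds one direction
#' per pair); a ranking shorter than `top_n` contributes its full length.
#'
#' @param ranked_a,ranked_b ranked `rule_table`s over the same mining
#'   universe.
#' @param top_n prefix size (default 500).
#' @return integer count of shared pairs.
#' @export
rule_set_intersection <- function(ranked_a, ranked_b, top_n = 500L) {
  ka <- unique(utils::head(pair_key(ranked_a$antecedent, ranked_a$consequent), top_n))
  kb <- unique(utils::head(pair_key(ranked_b$antecedent, ranked_b$consequent), top_n))
  length(intersect(ka, kb))
}

#' Evaluation report for a ranked rule list
#'
#' Bundles the standard comparison statistics: F-1 at `k = |truth|`, the
#' best-possible F-1 over prefixes, and median absolute supports of the
#' found-true, not-found-true and all-found subgroups at `k`.
#'
#' @inheritParams f1_at_k
#' @return list of class `eval_report`.
#' @export
eval_report <- function(ranked, truth, k = nrow(truth)) {
  at_k <- f1_at_k(ranked, truth, k)
  best <- best_possible_f1(ranked, truth)
  keys <- pair_key(ranked$antecedent, ranked$consequent)
  headed <- ranked[seq_len(min(k, nrow(ranked)))]
  hk <- keys[seq_len(min(k, nrow(ranked)))]
  med <- list(
    all_found = if (nrow(headed)) stats::median(headed$n_ab) else NA_real_,
    found_true = if (any(hk %in% truth$key))
      stats::median(headed$n_ab[hk %in% truth$key]) else NA_real_,
    not_found_true = if (any(!hk %in% truth$key))
      stats::median(headed$n_ab[!hk %in% truth$key]) else NA_real_)
  structure(list(k = k, f1_at_k = at_k, best_possible = best,
                 median_abs_support = med),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("F-1@%d: %.1f%% (%d true found)\n",
              x$k, x$f1_at_k$f1, x$f1_at_k$true_found))
  cat(sprintf("best possible: %.1f%% at set size %d (%d true found)\n",
              x$best_possible$f1, x$best_possible$size, x$best_possible$true_found))
  cat(sprintf("median absolute support (all found @k): %s\n",
              format(x$median_abs_support$all_found)))
  invisible(x)
}
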