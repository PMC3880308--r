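#' Mine, score and rank rules in one call
#'
#' End-to-end convenience wrapper: ancestor-closes the store if necessary,
#' counts pair supports in the given scope, generates directed candidate
#' rules, attaches the requested measures, optionally applies a pruning
#' method, ranks by `rank_by`, keeps the better direction of each pair and
#' optionally removes ancestor rules. Stage counts are logged via
#' `message()`.
#'
#' @param store an [annotation_store()] (closed or not).
#' @param ontologies list of [ontology()] objects.
#' @param scope one or two ontology ids (see [count_pair_supports()]).
#' @param measures measure ids to attach (see [measure_ids()]).
#' @param rank_by measure id used for the final ranking.
#' @param min_abs_support minimum co-occurrence count (default 1).
#' @param prune `"none"`, `"grp"` or `"grl"`.
#' @param expectation_mode,dif_form passed to [annotate_measures()].
#' @param select_direction keep only the better-ranked direction of each
#'   pair (default TRUE).
#' @param remove_ancestor_rules apply [ancestor_rule_removal()] to the
#'   ranked list (default FALSE).
#' @param prune_args list of extra arguments for [grp_prune()] /
#'   [grl_filter()].
#' @return a ranked `rule_table`.
#' @export
mine_rules <- function(store, ontologies, scope,
                       measures = c("Jac", "JacDif"), rank_by = measures[[1L]],
                       min_abs_support = 1L,
                       prune = c("none", "grp", "grl"),
                       expectation_mode = "both_sides_min",
                       dif_form = "product",
                       select_direction = TRUE,
                       remove_ancestor_rules = FALSE,
                       prune_args = list()) {
  prune <- match.arg(prune)
  if (!store$closed) store <- ancestor_closure(store, ontologies)
  if (store$N == 0L) stop("no transactions in the annotation store")
  supports <- count_pair_supports(store, scope, min_abs_support)
  message("counted ", nrow(supports$pair_counts), " co-occurring pairs over N=",
          supports$N, " transactions")
  rules <- generate_rules(supports, ontologies)
  rules <- annotate_measures(rules, unique(c(measures, rank_by)), supports,
                             ontologies, expectation_mode = expectation_mode,
                             dif_form = dif_form)
  message(nrow(rules), " candidate rules before pruning")
  if (prune == "grp") {
    rules <- do.call(grp_prune,
                     c(list(rules, supports, ontologies,
                            expectation_mode = expectation_mode), prune_args))
  } else if (prune == "grl") {
    combos <- unique_combinations(store, scope)
    rules <- do.call(grl_filter,
                     c(list(rules, supports, combos, ontologies,
                            cross_ontology = length(scope) == 2L), prune_args))
  }
  if (prune != "none") message(nrow(rules), " rules after ", prune, " pruning")
  if (!nrow(rules)) return(rules)
  rules <- rank_rules(rules, rank_by)
  if (select_direction) rules <- direction_select(rules)
  if (remove_ancestor_rules) rules <- ancestor_rule_removal(rules, ontologies)
  message(nrow(rules), " rules in the final ranking")
  rules
}

#' Write a rule table to tab-separated text
#'
#' One rule per row with a stable column order; measure values are rounded
#' to `digits` decimals unless `digits = NA` (full precision). The output
#' is diff-friendly and round-trips through [read_rules()].
#'
#' @param rules a `rule_table`.
#' @param path output file path.
#' @param digits decimal places for measure columns (default 3; `NA` keeps
#'   full precision).
#' @return the path, invisibly.
#' @export
write_rules <- function(rules, path, digits = 3L) {
  out <- data.table::as.data.table(rules)
  if (!is.na(digits)) {
    num <- names(out)[vapply(out, is.double, TRUE)]
    for (col in num) out[[col]] <- round(out[[col]], digits)
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a rule table written by [write_rules()]
#' @param path file path.
#' @return a `rule_table`.
#' @export
read_rules <- function(path) {
  rules <- data.table::fread(path, sep = "\t",
                             colClasses = list(character = c("antecedent", "consequent")))
  class(rules) <- c("rule_table", class(rules))
  rules[]
}

#' Write an ontology as a child-parent edge table
#' @param o an [ontology()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_ontology_edges <- function(o, path) {
  el <- edge_list(o$parents)
  data.table::fwrite(data.table::data.table(child = el$from, parent = el$to),
                     path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write annotations in the package's TSV format
#' @param store an [annotation_store()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_annotations <- function(store, path) {
  data.table::fwrite(store$labels[, c("object_id", "ontology_id", "category_id"),
                                  with = FALSE],
                     path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a ground truth as a two-column pair table
#' @param truth a [ground_truth()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  data.table::fwrite(data.table::data.table(item_a = truth$item_a,
                                            item_b = truth$item_b),
                     path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Generate and write a complete synthetic fixture
#'
#' Writes the two ontology edge tables, the (un-closed) annotation TSV and
#' the ground-truth pair list into `dir`; every file round-trips through
#' the package loaders.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if missing).
#' @return named character vector of the four file paths, invisibly.
#' @export
run_synth <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  o1 <- generate_ontology(cfg, 1L)
  o2 <- generate_ontology(cfg, 2L)
  ann <- generate_annotations(cfg, o1, o2)
  paths <- c(ontology1 = file.path(dir, "ontology1.tsv"),
             ontology2 = file.path(dir, "ontology2.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_ontology_edges(o1, paths[["ontology1"]])
  write_ontology_edges(o2, paths[["ontology2"]])
  write_annotations(ann$store, paths[["annotations"]])
  write_ground_truth(ann$truth, paths[["truth"]])
  invisible(paths)
}

#' Evaluate a ranked rule file against a ground-truth file
#'
#' Truth pairs referencing categories absent from the ranked list's mining
#' universe are kept (they count toward recall); pairs whose two columns
#' are identical are dropped with a warning.
#'
#' @param rules_path path to a rule table written by [write_rules()].
#' @param truth_path path to a two-column ground-truth file.
#' @param k prefix size; defaults to the number of truth pairs.
#' @return an [eval_report()].
#' @export
run_eval <- function(rules_path, truth_path, k = NULL) {
  ranked <- read_rules(rules_path)
  truth <- load_ground_truth(truth_path)
  if (is.null(k)) k <- nrow(truth)
  eval_report(ranked, truth, k)
}
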