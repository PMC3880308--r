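#' Build an annotation store from a table of object-category assignments
#'
#' The annotation store is the transaction database: each object (protein,
#' Wikipedia entry, ...) is one transaction whose items are the ontology
#' categories annotated to it. `N`, the total transaction count used by the
#' frequency-based measures, is the number of objects in the store; objects
#' known to the corpus but carrying no annotation can be included through
#' `objects` so that relative supports divide by the full corpus size.
#'
#' @param labels data.frame with columns `object_id`, `ontology_id`,
#'   `category_id` and optionally `evidence`.
#' @param ontologies list of [ontology()] objects covering the
#'   `ontology_id`s used; records referencing unknown ontologies or unknown
#'   categories are dropped (with a count kept in `n_dropped_unknown`).
#' @param objects optional character vector of all object ids in the corpus;
#'   defaults to the annotated objects.
#' @return An object of class `annotation_store` with fields `labels`
#'   (unique rows), `objects`, `N` and `closed`.
#' @seealso [load_annotations()], [ancestor_closure()]
#' @export
annotation_store <- function(labels, ontologies, objects = NULL) {
  stopifnot(is.list(ontologies), all(vapply(ontologies, inherits, TRUE, "ontology")))
  labels <- data.table::as.data.table(labels)
  need <- c("object_id", "ontology_id", "category_id")
  if (!all(need %in% names(labels)))
    stop("labels must have columns ", paste(need, collapse = ", "))
  names(ontologies) <- vapply(ontologies, `[[`, "", "ontology_id")

  known <- rep(FALSE, nrow(labels))
  for (oid in names(ontologies)) {
    sel <- labels$ontology_id == oid
    known[sel] <- labels$category_id[sel] %in% category_ids(ontologies[[oid]])
  }
  n_dropped <- sum(!known)
  if (n_dropped > 0L)
    message("dropped ", n_dropped, " annotation(s) referencing unknown categories")
  labels <- unique(labels[known, need, with = FALSE])

  if (is.null(objects)) objects <- unique(labels$object_id)
  objects <- unique(as.character(objects))
  if (!all(labels$object_id %in% objects))
    stop("labels reference objects missing from 'objects'")

  structure(
    list(labels = labels, objects = objects, N = length(objects),
         closed = FALSE, n_dropped_unknown = n_dropped,
         n_dropped_evidence = 0L),
    class = "annotation_store")
}

#' @export
print.annotation_store <- function(x, ...) {
  cat(sprintf("<annotation_store>: %d objects (N), %d annotation rows%s\n",
              x$N, nrow(x$labels),
              if (x$closed) ", ancestor-closed" else ""))
  invisible(x)
}

#' Load annotations from a TSV or GAF-like file
#'
#' The TSV format has columns `object_id`, `ontology_id`, `category_id` and
#' optionally `evidence` (tab-separated, no header). The GAF-like format is
#' the minimal subset of GAF 2.x used here: comment lines start with `!`,
#' the object id is column 2, the category id column 5 and the evidence
#' code column 7; the ontology of each record is inferred from which loaded
#' ontology contains the category. Records whose evidence code is listed in
#' `exclude_evidence` (typically `"IEA"`, electronically inferred
#' annotations) are dropped, as are records referencing unknown categories;
#' both drop counts are retained on the store. Malformed lines are skipped
#' with a message; if every line is malformed the call fails.
#'
#' @param path path to the annotation file.
#' @param format `"tsv"` or `"gaf"`.
#' @param ontologies list of [ontology()] objects.
#' @param exclude_evidence character vector of evidence codes to drop.
#' @param objects optional full object universe (see [annotation_store()]).
#' @return an un-closed [annotation_store()].
#' @export
load_annotations <- function(path, format = c("tsv", "gaf"), ontologies,
                             exclude_evidence = character(), objects = NULL) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "gaf") lines <- lines[!startsWith(lines, "!")]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no transactions: annotation file is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)

  if (format == "tsv") {
    ok <- nf >= 3L
    if (!any(ok)) stop("all annotation lines are malformed")
    if (any(!ok)) message("skipped ", sum(!ok), " malformed annotation line(s)")
    fields <- fields[ok]
    labels <- data.table::data.table(
      object_id = vapply(fields, `[`, "", 1L),
      ontology_id = vapply(fields, `[`, "", 2L),
      category_id = vapply(fields, `[`, "", 3L),
      evidence = vapply(fields, function(f) if (length(f) >= 4L) f[4L] else NA_character_, ""))
  } else {
    ok <- nf >= 7L
    if (!any(ok)) stop("all annotation lines are malformed")
    if (any(!ok)) message("skipped ", sum(!ok), " malformed annotation line(s)")
    fields <- fields[ok]
    cat_id <- vapply(fields, `[`, "", 5L)
    # infer the ontology of each category id
    ont_of <- rep(NA_character_, length(cat_id))
    for (o in ontologies)
      ont_of[cat_id %in% category_ids(o)] <- o$ontology_id
    labels <- data.table::data.table(
      object_id = vapply(fields, `[`, "", 2L),
      ontology_id = ont_of,
      category_id = cat_id,
      evidence = vapply(fields, `[`, "", 7L))
    labels$ontology_id[is.na(labels$ontology_id)] <- "?"
  }

  drop_ev <- labels$evidence %in% exclude_evidence
  labels <- labels[!drop_ev]
  store <- annotation_store(labels, ontologies, objects = objects)
  store$n_dropped_evidence <- sum(drop_ev)
  store
}

#' Expand every annotation by the ancestors of its category
#'
#' If an object is annotated with a category it implicitly belongs to all
#' of that category's ancestors; closure makes this explicit by adding one
#' label per ancestor. The operation is idempotent and never removes
#' labels. When an ontology was produced by [dag_to_tree()], annotations
#' that reference an original (pre-duplication) category id are first
#' remapped to every copy of that category, since each copy is the original
#' observed through one parent path.
#'
#' @param store an [annotation_store()].
#' @param ontologies list of [ontology()] objects.
#' @return a closed [annotation_store()].
#' @export
ancestor_closure <- function(store, ontologies) {
  stopifnot(inherits(store, "annotation_store"))
  if (store$closed) return(store)
  if (!nrow(store$labels)) {
    store$closed <- TRUE
    return(store)
  }
  names(ontologies) <- vapply(ontologies, `[[`, "", "ontology_id")
  pieces <- list()
  for (oid in unique(store$labels$ontology_id)) {
    o <- ontologies[[oid]]
    if (is.null(o)) stop("no ontology loaded for id '", oid, "'")
    lab <- store$labels[store$labels$ontology_id == oid]
    # remap pre-duplication ids to all their tree copies
    if (!is.null(o$provenance)) {
      missing <- setdiff(unique(lab$category_id), category_ids(o))
      if (length(missing)) {
        copies <- split(names(o$provenance), unname(o$provenance))
        bad <- setdiff(missing, names(copies))
        if (length(bad))
          stop("unknown category id in ontology '", oid, "': ", bad[[1L]])
        sel <- lab$category_id %in% missing
        reps <- copies[lab$category_id[sel]]
        expanded <- data.table::data.table(
          object_id = rep(lab$object_id[sel], lengths(reps)),
          ontology_id = oid,
          category_id = unlist(reps, use.names = FALSE))
        lab <- rbind(lab[!sel], expanded)
      }
    }
    amap <- ancestors_map(o, unique(lab$category_id))
    n_anc <- lengths(amap)[lab$category_id]
    anc <- data.table::data.table(
      object_id = rep(lab$object_id, n_anc),
      ontology_id = oid,
      category_id = unlist(amap[lab$category_id], use.names = FALSE))
    pieces[[oid]] <- unique(rbind(lab, anc))
  }
  store$labels <- data.table::rbindlist(pieces)
  data.table::setkeyv(store$labels, c("object_id", "ontology_id", "category_id"))
  store$closed <- TRUE
  store
}

#' Unique label-set combinations of a store
#'
#' Collapses objects that carry identical (closed) label sets, restricted
#' to the given ontologies, into one combination each, recording how many
#' objects share it. These distinct combinations are the "classes" over
#' which the agreement variant of confidence is computed: each distinct
#' annotation profile counts once, however many objects exhibit it.
#'
#' @param store a closed [annotation_store()].
#' @param ontology_ids character vector of ontology ids to restrict to.
#' @return an object of class `combo_table`: a data.table with a list
#'   column `labels` (sorted category ids) and a count `n_objects`.
#' @export
unique_combinations <- function(store, ontology_ids) {
  stopifnot(inherits(store, "annotation_store"))
  if (!store$closed) stop("store must be ancestor-closed first")
  lab <- store$labels[store$labels$ontology_id %in% ontology_ids]
  if (!nrow(lab)) {
    out <- data.table::data.table(labels = list(), n_objects = integer())
    class(out) <- c("combo_table", class(out))
    return(out)
  }
  per_obj <- lab[, list(key = paste(sort(category_id), collapse = "\r")),
                 by = "object_id"]
  combos <- per_obj[, list(n_objects = .N), by = "key"]
  out <- data.table::data.table(
    labels = strsplit(combos$key, "\r", fixed = TRUE),
    n_objects = combos$n_objects)
  class(out) <- c("combo_table", class(out))
  out
}
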