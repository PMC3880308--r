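#' Construct an ontology from categories and parent edges
#'
#' An ontology is a rooted directed acyclic graph (DAG) of categories linked
#' by `is_a`-style child-to-parent edges. Roots are the categories without
#' parents; every category must reach a root, and the edge graph must be
#' acyclic. Obsolete categories are kept in the category table but carry no
#' edges and take no part in structural queries.
#'
#' @param ontology_id character scalar naming the hierarchy (e.g. `"GO-MF"`).
#' @param categories data.frame with columns `id`, `name` and optionally
#'   `obsolete` (logical, default `FALSE`).
#' @param parents named list mapping a category id to the character vector of
#'   its parent ids. Categories without an entry (or with an empty vector)
#'   are roots.
#' @param provenance optional named character vector mapping a category id to
#'   the id of the category it was copied from (used by [dag_to_tree()]).
#' @return An object of class `ontology`.
#' @seealso [load_hierarchy()], [ancestors()], [dag_to_tree()]
#' @export
ontology <- function(ontology_id, categories, parents = list(), provenance = NULL) {
  stopifnot(is.character(ontology_id), length(ontology_id) == 1L)
  categories <- as.data.frame(categories, stringsAsFactors = FALSE)
  if (!all(c("id", "name") %in% names(categories)))
    stop("categories must have 'id' and 'name' columns")
  if (is.null(categories$obsolete)) categories$obsolete <- FALSE
  if (anyDuplicated(categories$id))
    stop("duplicate category ids: ",
         paste(unique(categories$id[duplicated(categories$id)]), collapse = ", "))

  active <- categories$id[!categories$obsolete]
  parents <- parents[names(parents) %in% active]
  parents <- lapply(parents, function(p) unique(p))
  bad_child <- setdiff(names(parents), categories$id)
  if (length(bad_child))
    stop("parent edges reference unknown child id: ", bad_child[[1L]])
  all_parents <- unique(unlist(parents, use.names = FALSE))
  bad <- setdiff(all_parents, active)
  if (length(bad))
    stop("unknown or obsolete parent id: ", bad[[1L]])

  el <- edge_list(parents)
  g <- igraph::graph_from_data_frame(el, directed = TRUE,
                                     vertices = data.frame(name = active))
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    member <- igraph::ends(g, cyc[1L])[1L]
    stop("cycle detected in hierarchy (involves category '", member, "')")
  }
  has_parent <- vapply(parents, length, 1L) > 0L
  roots <- setdiff(active, names(parents)[has_parent])
  if (length(roots) == 0L && length(active) > 0L)
    stop("hierarchy has no root")

  structure(
    list(ontology_id = ontology_id,
         categories = categories,
         parents = parents[has_parent],
         roots = roots,
         provenance = provenance,
         graph = g),
    class = "ontology")
}

# child -> parent edge data.frame from a parents list
edge_list <- function(parents) {
  if (length(parents) == 0L)
    return(data.frame(from = character(), to = character()))
  n <- vapply(parents, length, 1L)
  data.frame(from = rep(names(parents), n),
             to = unlist(parents, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology '%s'>: %d categories (%d obsolete), %d roots, %d edges\n",
              x$ontology_id, nrow(x$categories), sum(x$categories$obsolete),
              length(x$roots), igraph::ecount(x$graph)))
  invisible(x)
}

#' Active (non-obsolete) category ids of an ontology
#' @param o an [ontology()].
#' @return character vector of category ids.
#' @export
category_ids <- function(o) {
  stopifnot(inherits(o, "ontology"))
  o$categories$id[!o$categories$obsolete]
}

#' Load a hierarchy from an OBO file or a child-parent edge table
#'
#' Two plain-text formats are supported: a subset of OBO 1.2 (`[Term]`
#' stanzas with `id`, `name`, `is_a`, `relationship` and `is_obsolete` tags)
#' and a two-column delimited table `child<TAB>parent` (a header line is
#' detected and skipped when its first field is `child`). Only `is_a` edges
#' are used by default; additional OBO relationship types (such as
#' `part_of`) can be opted in via `relations`. Obsolete terms are loaded but
#' excluded from the graph.
#'
#' @param path path to the hierarchy file.
#' @param format `"auto"` (by extension), `"obo"` or `"edge_table"`.
#' @param ontology_id identifier for the loaded hierarchy; defaults to the
#'   file name without extension.
#' @param relations OBO relationship types to honor in addition to `is_a`
#'   (e.g. `c("is_a", "part_of")`). Ignored for edge tables.
#' @return An [ontology()].
#' @export
load_hierarchy <- function(path, format = c("auto", "obo", "edge_table"),
                           ontology_id = NULL, relations = "is_a") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.obo$", path, ignore.case = TRUE)) "obo" else "edge_table"
  if (is.null(ontology_id))
    ontology_id <- sub("\\.[^.]*$", "", basename(path))
  switch(format,
         obo = parse_obo(readLines(path, warn = FALSE), ontology_id, relations),
         edge_table = parse_edge_table(path, ontology_id))
}

# Minimal OBO 1.2 reader: [Term] stanzas; tags id, name, is_a,
# relationship, is_obsolete. Trailing "! comment" text is stripped.
parse_obo <- function(lines, ontology_id, relations = "is_a") {
  lines <- sub("\\s*!.*$", "", trimws(lines))
  starts <- grep("^\\[", lines)
  if (!length(starts)) stop("no stanzas found in OBO input")
  ends <- c(starts[-1L] - 1L, length(lines))
  ids <- character(); nms <- character(); obs <- logical()
  parents <- list()
  for (k in seq_along(starts)) {
    if (lines[starts[k]] != "[Term]") next
    block <- lines[seq(starts[k] + 1L, ends[k])]
    tagval <- function(tag) {
      v <- block[startsWith(block, paste0(tag, ":"))]
      trimws(sub(paste0("^", tag, ":"), "", v))
    }
    id <- tagval("id")
    if (length(id) != 1L) stop("OBO [Term] stanza without a single id")
    nm <- tagval("name")
    pa <- tagval("is_a")
    if (length(setdiff(relations, "is_a"))) {
      rel <- tagval("relationship")
      if (length(rel)) {
        parts <- strsplit(rel, "\\s+")
        keep <- vapply(parts, function(p) p[1L] %in% relations, TRUE)
        pa <- c(pa, vapply(parts[keep], `[`, "", 2L))
      }
    }
    ids <- c(ids, id)
    nms <- c(nms, if (length(nm)) nm[1L] else id)
    obs <- c(obs, identical(tagval("is_obsolete"), "true"))
    if (length(pa) && !obs[length(obs)]) parents[[id]] <- pa
  }
  ontology(ontology_id,
           data.frame(id = ids, name = nms, obsolete = obs,
                      stringsAsFactors = FALSE),
           parents)
}

parse_edge_table <- function(path, ontology_id) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("child", "parent")[1:2],
                          colClasses = "character")
  if (nrow(dt) && tolower(dt$child[1L]) == "child") dt <- dt[-1L]
  if (!nrow(dt)) stop("empty edge table: ", path)
  ids <- unique(c(dt$child, dt$parent))
  parents <- split(dt$parent, dt$child)
  ontology(ontology_id,
           data.frame(id = ids, name = ids, stringsAsFactors = FALSE),
           parents)
}

check_category <- function(o, id) {
  stopifnot(inherits(o, "ontology"))
  if (!all(id %in% category_ids(o)))
    stop("unknown category id in ontology '", o$ontology_id, "': ",
         paste(setdiff(id, category_ids(o)), collapse = ", "))
}

#' Ancestors of a category
#'
#' Transitive closure over child-to-parent edges, excluding the category
#' itself. Roots have no ancestors.
#'
#' @param o an [ontology()].
#' @param id a category id.
#' @return character vector of ancestor category ids (possibly empty).
#' @export
ancestors <- function(o, id) {
  check_category(o, id)
  stopifnot(length(id) == 1L)
  anc <- igraph::subcomponent(o$graph, id, mode = "out")
  setdiff(names(anc), id)
}

# ancestors for many categories at once: named list id -> character vector
ancestors_map <- function(o, ids) {
  ids <- unique(ids)
  check_category(o, ids)
  out <- lapply(ids, function(i)
    setdiff(names(igraph::subcomponent(o$graph, i, mode = "out")), i))
  names(out) <- ids
  out
}

#' Number of descendants of a category
#'
#' Counts the distinct categories strictly below `id`. When `within` is
#' given, only descendants belonging to that set are counted — used to
#' restrict structure-based pruning to the annotated sub-ontology.
#'
#' @inheritParams ancestors
#' @param within optional character vector restricting which descendants
#'   count.
#' @return a non-negative integer.
#' @export
descendant_count <- function(o, id, within = NULL) {
  check_category(o, id)
  stopifnot(length(id) == 1L)
  desc <- setdiff(names(igraph::subcomponent(o$graph, id, mode = "in")), id)
  if (!is.null(within)) desc <- intersect(desc, within)
  length(desc)
}

#' Undirected edge distance between two categories
#'
#' Length of the shortest path between `a` and `b` treating `is_a` edges as
#' undirected; `0` when `a == b`, `Inf` when the categories lie in different
#' connected components.
#'
#' @inheritParams ancestors
#' @param a,b category ids in `o`.
#' @return a non-negative number (`Inf` if disconnected).
#' @export
edge_distance <- function(o, a, b) {
  check_category(o, c(a, b))
  as.numeric(igraph::distances(o$graph, v = a, to = b, mode = "all"))[1L]
}

#' Convert a DAG hierarchy into a tree by node duplication
#'
#' Every category with multiple parents is replaced by one copy per parent,
#' and its descendant subtree is duplicated under each copy, so that every
#' node of the result has exactly one parent. A category that ends up with a
#' single copy keeps its id; duplicated copies are named
#' `"<original>@<tree-parent-id>"`, which is deterministic and collision
#' free even when duplication nests. The mapping from copies back to
#' original ids is recorded in the result's `provenance` field.
#'
#' @param o an acyclic [ontology()].
#' @return an [ontology()] in which every non-root category has exactly one
#'   parent.
#' @export
dag_to_tree <- function(o) {
  stopifnot(inherits(o, "ontology"))
  ids <- category_ids(o)
  topo <- rev(names(igraph::topo_sort(o$graph, mode = "out")))  # parents first
  children <- split(edge_list(o$parents)$from, edge_list(o$parents)$to)

  # copies(v) = sum over parents of copies(parent); roots have one copy
  ncopies <- stats::setNames(integer(length(ids)), ids)
  for (v in topo) {
    pv <- o$parents[[v]]
    ncopies[[v]] <- if (is.null(pv)) 1L else sum(ncopies[pv])
  }

  tree_ids <- character(); tree_parent <- character(); origin <- character()
  # queue of (tree_id, original_id); children expanded breadth first
  queue_tid <- o$roots
  queue_orig <- o$roots
  tree_ids <- o$roots
  tree_parent <- rep(NA_character_, length(o$roots))
  origin <- o$roots
  i <- 1L
  while (i <= length(queue_tid)) {
    tid <- queue_tid[[i]]; orig <- queue_orig[[i]]
    for (ch in sort(children[[orig]])) {
      ctid <- if (ncopies[[ch]] == 1L) ch else paste0(ch, "@", tid)
      tree_ids <- c(tree_ids, ctid)
      tree_parent <- c(tree_parent, tid)
      origin <- c(origin, ch)
      queue_tid <- c(queue_tid, ctid)
      queue_orig <- c(queue_orig, ch)
    }
    i <- i + 1L
  }

  name_of <- stats::setNames(o$categories$name, o$categories$id)
  parents <- as.list(tree_parent[!is.na(tree_parent)])
  names(parents) <- tree_ids[!is.na(tree_parent)]
  ontology(o$ontology_id,
           data.frame(id = tree_ids, name = unname(name_of[origin]),
                      stringsAsFactors = FALSE),
           parents,
           provenance = stats::setNames(origin, tree_ids))
}
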