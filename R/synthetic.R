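#' Configuration for the synthetic benchmark generator
#'
#' The generator emulates the structure the mining method assumes: two
#' rooted hierarchies, leaf-biased annotation (real annotation effort
#' concentrates on the most specific categories, which are individually
#' infrequent), ancestor closure, a set of planted one-to-one
#' cross-hierarchy links of varying strength — including rare links whose
#' absolute support is forced below 10 — and annotation noise.
#'
#' @param seed integer seed; the whole fixture is a deterministic function
#'   of the configuration.
#' @param depth tree depth of each hierarchy (length-2 integer).
#' @param branching children per internal node; a scalar, or a list of two
#'   per-level vectors (one per hierarchy).
#' @param dag_fraction share of non-root categories given a second parent
#'   from the previous level (0 = trees).
#' @param n_objects number of objects (transactions).
#' @param n_planted_links number of planted one-to-one leaf links between
#'   the hierarchies.
#' @param p_link probability that an object annotated with a planted source
#'   leaf also receives the linked target leaf.
#' @param rare_fraction share of planted links forced to be rare (absolute
#'   support below 10).
#' @param rare_support_range integer range the capped support of each rare
#'   source leaf is drawn from (must stay below 10).
#' @param noise_rate probability that an object receives one extra random
#'   leaf in each hierarchy.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(seed = 42L, depth = c(4L, 4L),
                         branching = list(c(3L, 3L, 3L, 4L), c(3L, 3L, 3L, 4L)),
                         dag_fraction = 0, n_objects = 2000L,
                         n_planted_links = 20L, p_link = 0.9,
                         rare_fraction = 0.3, rare_support_range = c(3L, 9L),
                         noise_rate = 0.05) {
  if (!is.list(branching)) branching <- list(branching, branching)
  branching <- lapply(seq_len(2L), function(i) {
    b <- branching[[i]]
    if (length(b) == 1L) b <- rep(b, depth[i])
    if (length(b) != depth[i]) stop("branching length must match depth")
    as.integer(b)
  })
  stopifnot(dag_fraction >= 0, dag_fraction <= 1,
            p_link >= 0, p_link <= 1,
            rare_fraction >= 0, rare_fraction <= 1,
            noise_rate >= 0, noise_rate <= 1,
            rare_support_range[2L] < 10L, rare_support_range[1L] >= 1L,
            n_objects >= 1L, all(depth >= 1L))
  structure(list(seed = as.integer(seed), depth = as.integer(depth),
                 branching = branching, dag_fraction = dag_fraction,
                 n_objects = as.integer(n_objects),
                 n_planted_links = as.integer(n_planted_links),
                 p_link = p_link, rare_fraction = rare_fraction,
                 rare_support_range = as.integer(rare_support_range),
                 noise_rate = noise_rate),
            class = "synth_config")
}

#' Generate one synthetic rooted hierarchy
#'
#' Builds a complete tree of the configured depth and branching, then (for
#' `dag_fraction > 0`) gives a random share of the non-root categories one
#' extra parent drawn from the level above their own, which keeps the graph
#' acyclic by construction.
#'
#' @param cfg a [synth_config()].
#' @param which which of the two configured hierarchies to build (1 or 2).
#' @param ontology_id identifier of the generated ontology.
#' @return an [ontology()].
#' @export
generate_ontology <- function(cfg, which = 1L, ontology_id = paste0("O", which)) {
  stopifnot(inherits(cfg, "synth_config"), which %in% 1:2)
  set.seed(cfg$seed + which)
  depth <- cfg$depth[which]
  branching <- cfg$branching[[which]]

  fmt <- function(k) sprintf("%s:%04d", ontology_id, k)
  counter <- 1L
  levels <- list(fmt(1L))  # root
  counter <- 2L
  parents <- list()
  for (d in seq_len(depth)) {
    prev <- levels[[d]]
    ids <- fmt(seq.int(counter, counter + length(prev) * branching[d] - 1L))
    counter <- counter + length(ids)
    pa <- rep(prev, each = branching[d])
    for (i in seq_along(ids)) parents[[ids[i]]] <- pa[i]
    # extra parents: a share of this level gets a second parent one level up
    if (cfg$dag_fraction > 0 && length(prev) > 1L) {
      n_extra <- round(cfg$dag_fraction * length(ids))
      extra <- sample(ids, n_extra)
      for (id in extra) {
        cand <- setdiff(prev, parents[[id]])
        parents[[id]] <- c(parents[[id]], sample(cand, 1L))
      }
    }
    levels[[d + 1L]] <- ids
  }
  all_ids <- unlist(levels, use.names = FALSE)
  ontology(ontology_id,
           data.frame(id = all_ids, name = all_ids, stringsAsFactors = FALSE),
           parents)
}

# leaves = categories without children
ontology_leaves <- function(o) {
  with_children <- unique(unlist(o$parents, use.names = FALSE))
  setdiff(category_ids(o), with_children)
}

#' Generate annotations with planted cross-hierarchy links
#'
#' Each object draws one leaf of the first hierarchy uniformly; objects
#' whose leaf is the source of a planted link receive the linked leaf of
#' the second hierarchy with probability `p_link` and a random leaf
#' otherwise; all other objects draw a random second-hierarchy leaf. A
#' `rare_fraction` share of the planted links is made rare: their source
#' leaf is assigned to a capped number of objects (drawn from
#' `rare_support_range`, below 10) and excluded from all random draws, so
#' the link's absolute support stays below 10 after closure. Noise adds one
#' extra random leaf per hierarchy to a `noise_rate` share of objects.
#'
#' @param cfg a [synth_config()].
#' @param o1,o2 the two hierarchies (see [generate_ontology()]).
#' @return list with `store` (an un-closed [annotation_store()]), `truth`
#'   (a [ground_truth()] of the planted leaf pairs) and `rare_links`
#'   (logical vector marking the rare planted links).
#' @export
generate_annotations <- function(cfg, o1, o2) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  leaves1 <- sort(ontology_leaves(o1))
  leaves2 <- sort(ontology_leaves(o2))
  L <- cfg$n_planted_links
  if (L > length(leaves1) || L > length(leaves2))
    stop("more planted links than leaves available")

  src <- sample(leaves1, L)
  tgt <- sample(leaves2, L)
  n_rare <- round(cfg$rare_fraction * L)
  rare <- seq_len(L) <= n_rare  # first n_rare links are the rare ones
  n <- cfg$n_objects
  obj <- sprintf("obj%05d", seq_len(n))

  # base draw: uniform over leaves that are not rare sources
  pool1 <- setdiff(leaves1, src[rare])
  lab1 <- sample(pool1, n, replace = TRUE)
  # rare sources: capped number of carrier objects, support < 10 guaranteed
  if (n_rare > 0L) {
    caps <- sample(seq(cfg$rare_support_range[1L], cfg$rare_support_range[2L]),
                   n_rare, replace = TRUE)
    free <- sample(n)  # disjoint carrier sets
    taken <- 0L
    for (i in seq_len(n_rare)) {
      carriers <- free[seq.int(taken + 1L, taken + caps[i])]
      lab1[carriers] <- src[rare][i]
      taken <- taken + caps[i]
    }
  }

  # second hierarchy: planted target with probability p_link for source
  # carriers, random leaf otherwise
  tgt_of <- stats::setNames(tgt, src)
  lab2 <- sample(leaves2, n, replace = TRUE)
  is_src <- lab1 %in% src
  linked <- is_src & stats::runif(n) < cfg$p_link
  lab2[linked] <- unname(tgt_of[lab1[linked]])

  labels <- data.table::data.table(
    object_id = c(obj, obj),
    ontology_id = c(rep(o1$ontology_id, n), rep(o2$ontology_id, n)),
    category_id = c(lab1, lab2))

  # noise: extra random leaves (never a rare source, to keep the cap exact)
  noisy1 <- stats::runif(n) < cfg$noise_rate
  noisy2 <- stats::runif(n) < cfg$noise_rate
  if (any(noisy1))
    labels <- rbind(labels, data.table::data.table(
      object_id = obj[noisy1], ontology_id = o1$ontology_id,
      category_id = sample(pool1, sum(noisy1), replace = TRUE)))
  if (any(noisy2))
    labels <- rbind(labels, data.table::data.table(
      object_id = obj[noisy2], ontology_id = o2$ontology_id,
      category_id = sample(leaves2, sum(noisy2), replace = TRUE)))

  store <- annotation_store(labels, list(o1, o2), objects = obj)
  list(store = store,
       truth = ground_truth(src, tgt),
       rare_links = rare)
}
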