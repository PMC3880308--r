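# shared fixtures and independent oracles, built in code

# diamond: A <- B, A <- C, B <- D, C <- D
diamond_ontology <- function(id = "dia") {
  ontology(id,
           data.frame(id = c("A", "B", "C", "D"), name = c("A", "B", "C", "D")),
           list(B = "A", C = "A", D = c("B", "C")))
}

# chain r <- c1 <- c2 <- ... <- cn
chain_ontology <- function(n, id = "chain") {
  ids <- c("r", paste0("c", seq_len(n)))
  parents <- as.list(ids[-length(ids)])
  names(parents) <- ids[-1L]
  ontology(id, data.frame(id = ids, name = ids), parents)
}

# flat ontology: every category is a root
flat_ontology <- function(id, cats) {
  ontology(id, data.frame(id = cats, name = cats), list())
}

# independent counting oracle: naive double loop over transactions
naive_pair_counts <- function(store, scope) {
  cross <- length(scope) == 2L
  objs <- store$objects
  counts <- list()
  for (obj in objs) {
    lab <- store$labels[store$labels$object_id == obj]
    if (cross) {
      s1 <- sort(lab$category_id[lab$ontology_id == scope[1L]])
      s2 <- sort(lab$category_id[lab$ontology_id == scope[2L]])
      for (x in s1) for (y in s2) {
        k <- paste(x, y, sep = "|")
        counts[[k]] <- (counts[[k]] %||% 0L) + 1L
      }
    } else {
      s <- sort(lab$category_id[lab$ontology_id == scope[1L]])
      if (length(s) >= 2L)
        for (i in seq_len(length(s) - 1L)) for (j in seq.int(i + 1L, length(s)))
          counts[[paste(s[i], s[j], sep = "|")]] <-
            (counts[[paste(s[i], s[j], sep = "|")]] %||% 0L) + 1L
    }
  }
  unlist(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random closed store over two flat ontologies (closure is a no-op on flat
# hierarchies, so counting is exercised without structural effects)
random_flat_store <- function(n_obj, cats1 = paste0("x", 1:12),
                              cats2 = paste0("y", 1:9)) {
  o1 <- flat_ontology("F1", cats1)
  o2 <- flat_ontology("F2", cats2)
  rows <- list()
  for (i in seq_len(n_obj)) {
    k1 <- sample(0:3, 1L); k2 <- sample(0:3, 1L)
    if (k1 > 0L) rows[[length(rows) + 1L]] <- data.frame(
      object_id = sprintf("o%04d", i), ontology_id = "F1",
      category_id = sample(cats1, k1))
    if (k2 > 0L) rows[[length(rows) + 1L]] <- data.frame(
      object_id = sprintf("o%04d", i), ontology_id = "F2",
      category_id = sample(cats2, k2))
  }
  labels <- do.call(rbind, rows)
  store <- annotation_store(labels, list(o1, o2),
                            objects = sprintf("o%04d", seq_len(n_obj)))
  store <- ancestor_closure(store, list(o1, o2))
  list(store = store, ontologies = list(o1, o2))
}

# rule_table stub from explicit columns, for evaluation tests
rule_stub <- function(antecedent, consequent, n_ab = 1L, value = NULL,
                      ant_ontology = "L", cons_ontology = "R") {
  rt <- data.table::data.table(
    antecedent = antecedent, consequent = consequent,
    ant_ontology = ant_ontology, cons_ontology = cons_ontology,
    n_ab = as.integer(n_ab),
    n_a = as.integer(pmax(n_ab, 1L)), n_b = as.integer(pmax(n_ab, 1L)),
    N = 1000L, cross_ontology = TRUE, hierarchical = FALSE)
  if (!is.null(value)) rt$value <- value
  class(rt) <- c("rule_table", class(rt))
  rt
}

# counts of the clothing worked example (closed supports)
toy_counts <- list(N = 1000L,
                   items = c(Clothes = 150L, Outerwear = 100L, Jackets = 90L,
                             `Travel Pants` = 15L, `Hiking Boots` = 30L),
                   pairs = c(Clothes = 30L, Outerwear = 20L, Jackets = 15L,
                             `Travel Pants` = 10L))
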