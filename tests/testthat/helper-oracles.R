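# Independent oracles and tiny fixture builders shared across the suite.
# Everything here deliberately avoids the package's own closure/divisibility
# code paths: reachability goes through igraph, primality through trial
# division, set semantics through plain R set operations.

# trial-division primality test
is_prime_trial <- function(n) {
  if (n < 2) return(FALSE)
  if (n < 4) return(TRUE)
  if (n %% 2 == 0) return(FALSE)
  d <- 3
  while (d * d <= n) {
    if (n %% d == 0) return(FALSE)
    d <- d + 2
  }
  TRUE
}

# igraph-based ancestor oracle: all terms reachable upward via closure edges
igraph_ancestors <- function(o, term_id) {
  e <- o$edges[o$edges$relation %in% o$closure_relations, , drop = FALSE]
  e <- e[!o$obsolete[e$child] & !o$obsolete[e$parent], , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    e[, c("child", "parent")], directed = TRUE,
    vertices = data.frame(name = o$ids[!o$obsolete]))
  reach <- igraph::subcomponent(g, term_id, mode = "out")
  sort(setdiff(names(reach), term_id))
}

# OBO text for the canonical 4-term demonstration hierarchy
demo_obo <- function(path = tempfile(fileext = ".obo")) {
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: Term1", "name: root term", "namespace: demo", "",
    "[Term]", "id: Term2", "name: mid term", "namespace: demo",
    "is_a: Term1 ! root term", "",
    "[Term]", "id: Term3", "name: side term", "namespace: demo",
    "synonym: \"lateral term\" EXACT []",
    "relationship: part_of Term2 ! mid term", "",
    "[Term]", "id: Term4", "name: leaf term", "namespace: demo",
    "is_a: Term2"), path)
  path
}

# diamond DAG: D -> {B, C} -> A
diamond_ontology <- function() {
  build_ontology(
    data.frame(id = c("A", "B", "C", "D"),
               name = c("A", "B", "C", "D"), stringsAsFactors = FALSE),
    data.frame(child = c("B", "C", "D", "D"),
               parent = c("A", "A", "B", "C"),
               relation = "is_a", stringsAsFactors = FALSE))
}

# small annotated corpus: a 5-term chain/branch ontology and 4 proteins,
# exercising ancestor-vs-literal retrieval. nb = "nucleotide binding"-like
# parent, atp = its descendant.
binding_corpus <- function() {
  o <- build_ontology(
    data.frame(id = c("mf", "nb", "atp", "fad", "cat"),
               name = c("molecular function", "nucleotide binding",
                        "ATP binding", "FAD binding", "catalytic activity"),
               stringsAsFactors = FALSE),
    data.frame(child = c("nb", "atp", "fad", "cat"),
               parent = c("mf", "nb", "nb", "mf"),
               relation = "is_a", stringsAsFactors = FALSE))
  store <- new_store()
  store$proteins <- list(
    PX = list(name = "PX", annotations = "atp", domains = character()),
    PY = list(name = "PY", annotations = "nb", domains = character()),
    PZ = list(name = "PZ", annotations = "cat", domains = character()),
    PW = list(name = "PW", annotations = c("fad", "cat"),
              domains = character()))
  for (pr in list(c("PX", "PZ"), c("PX", "PY"), c("PW", "PZ"),
                  c("PY", "PW"))) {
    store <- godelppi:::add_interaction(store, pr[1], pr[2])
  }
  list(ontology = o, store = store,
       index = build_index(o, store))
}

# brute-force oracle for DDI-based inference: direct domain-set membership
brute_force_infer <- function(store) {
  pids <- sort(names(store$proteins))
  out <- list()
  if (length(pids) >= 2 && nrow(store$ddis)) {
    for (i in seq_len(length(pids) - 1)) {
      for (j in seq.int(i + 1, length(pids))) {
        da <- store$proteins[[pids[i]]]$domains
        db <- store$proteins[[pids[j]]]$domains
        hit <- any(vapply(seq_len(nrow(store$ddis)), function(r) {
          d1 <- store$ddis$d1[r]; d2 <- store$ddis$d2[r]
          (d1 %in% da && d2 %in% db) || (d2 %in% da && d1 %in% db) ||
            (d1 %in% da && d2 %in% da) || (d1 %in% db && d2 %in% db)
        }, logical(1)))
        if (hit) out[[length(out) + 1]] <- c(pids[i], pids[j])
      }
    }
  }
  out
}
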