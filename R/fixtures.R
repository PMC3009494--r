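#' Reconstruct the worked micro-examples of the encoding
#'
#' Builds, in memory, the canonical four-term demonstration hierarchy
#' (Term1 the root; Term2 is_a Term1; Term3 part_of Term2; Term4 is_a
#' Term2) with primes 2, 3, 5, 7; the corresponding positional
#' natural-number coding (`is_a` = 1, `part_of` = 2, Term1..Term4 = 3..6)
#' used to demonstrate why positional Gödel numbers cannot express DAG
#' ancestry; and the domain-arithmetic demonstration corpus (domainA = 11,
#' domainB = 13, ProteinA = 17, ProteinB = 19, with ProteinA has domainA,
#' ProteinB has domainB, and domainA interacting with domainB).
#'
#' @return A list with elements `ontology`, `assignment` (terms only),
#'   `store`, `index` (built over ontology + store, so the Table-3-style
#'   domain codes are available), and `natural_numbers` (the positional
#'   coding: relation and term symbols to natural numbers).
#' @export
make_worked_examples <- function() {
  terms <- data.frame(
    id = c("Term1", "Term2", "Term3", "Term4"),
    name = c("Term1", "Term2", "Term3", "Term4"),
    namespace = "demo",
    obsolete = FALSE, stringsAsFactors = FALSE)
  edges <- data.frame(
    child = c("Term2", "Term3", "Term4"),
    parent = c("Term1", "Term2", "Term2"),
    relation = c("is_a", "part_of", "is_a"), stringsAsFactors = FALSE)
  o <- build_ontology(terms, edges)
  pa <- assign_primes(o)  # lex: Term1..Term4 -> 2,3,5,7

  store <- new_store()
  store$proteins[["ProteinA"]] <- list(name = "ProteinA",
                                       annotations = character(),
                                       domains = "domainA")
  store$proteins[["ProteinB"]] <- list(name = "ProteinB",
                                       annotations = character(),
                                       domains = "domainB")
  store$ddis <- data.frame(d1 = "domainA", d2 = "domainB",
                           stringsAsFactors = FALSE)

  index <- build_index(o, store)

  natural <- c(is_a = 1, part_of = 2,
               Term1 = 3, Term2 = 4, Term3 = 5, Term4 = 6)

  list(ontology = o, assignment = pa, store = store, index = index,
       natural_numbers = natural)
}

#' Specification for a seeded synthetic corpus
#'
#' Describes a random ontology DAG plus an annotated, interacting protein
#' corpus with optional domain tables. All randomness is driven by `seed`
#' through R's integer sampler, so a spec generates byte-identical output
#' across runs and platforms.
#'
#' @param seed Integer RNG seed.
#' @param n_terms Number of ontology terms (>= n_namespaces).
#' @param max_parents Maximum closure parents per term; values >= 2 enable
#'   diamonds, 1 yields a forest.
#' @param n_namespaces Number of independent hierarchies (each with its own
#'   root).
#' @param n_proteins Number of proteins.
#' @param annotations_per_protein Length-2 integer range, annotations drawn
#'   per protein.
#' @param n_interactions Number of (attempted) protein pair draws; after
#'   canonical deduplication the stored count may be slightly smaller.
#' @param n_domains,n_ddis Domain universe and domain-domain interaction
#'   counts (0 disables the domain tables).
#' @param annotation_bias `"uniform"` over non-root terms or `"leaf"`
#'   (leafward-weighted, mimicking how curated corpora favour specific
#'   terms).
#' @return Object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed = 1L, n_terms = 50L, max_parents = 2L,
                         n_namespaces = 1L, n_proteins = 20L,
                         annotations_per_protein = c(1L, 3L),
                         n_interactions = 30L, n_domains = 0L,
                         n_ddis = 0L,
                         annotation_bias = c("uniform", "leaf")) {
  annotation_bias <- match.arg(annotation_bias)
  spec <- list(seed = as.integer(seed), n_terms = as.integer(n_terms),
               max_parents = as.integer(max_parents),
               n_namespaces = as.integer(n_namespaces),
               n_proteins = as.integer(n_proteins),
               annotations_per_protein = as.integer(annotations_per_protein),
               n_interactions = as.integer(n_interactions),
               n_domains = as.integer(n_domains),
               n_ddis = as.integer(n_ddis),
               annotation_bias = annotation_bias)
  with(spec, {
    if (n_terms < 1 || n_namespaces < 1 || max_parents < 1)
      stop("infeasible fixture spec: counts must be positive")
    if (n_terms < n_namespaces)
      stop("infeasible fixture spec: fewer terms than namespaces")
    if (length(annotations_per_protein) != 2L ||
        any(annotations_per_protein < 0) ||
        annotations_per_protein[1] > annotations_per_protein[2])
      stop("infeasible fixture spec: bad annotation range")
    if (n_ddis > n_domains * (n_domains - 1) / 2)
      stop("infeasible fixture spec: more DDIs than domain pairs")
  })
  structure(spec, class = "fixture_spec")
}

# sample() guards against its scalar-x surprise
sample_safe <- function(x, k, prob = NULL) {
  if (length(x) == 1L) return(rep(x, min(k, 1L)))
  sample(x, k, prob = prob)
}

#' Generate a synthetic corpus from a fixture spec
#'
#' Draws a random acyclic term hierarchy (each term's parents are sampled
#' only among earlier-created terms of its namespace, so the DAG is acyclic
#' by construction), annotates proteins, draws interactions, and optionally
#' domain tables. When `dir` is given the corpus is also written to disk in
#' the package's file dialects (OBO, annotation/interaction/domain TSVs and
#' a JSON manifest recording the spec).
#'
#' @param spec A `"fixture_spec"`.
#' @param dir Optional output directory (created if missing).
#' @return A list: `ontology`, `store`, `spec`, and (when written) `paths`.
#' @export
generate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  n <- spec$n_terms
  ids <- sprintf("T:%05d", seq_len(n))
  ns_of <- sprintf("ns%02d",
                   c(seq_len(spec$n_namespaces),
                     if (n > spec$n_namespaces)
                       sample.int(spec$n_namespaces,
                                  n - spec$n_namespaces, replace = TRUE)))
  # depth proxy for leaf-weighted annotation draws
  depth <- integer(n)
  edges <- list()
  for (i in seq_len(n)) {
    earlier <- which(seq_len(i - 1L) > 0 & ns_of[seq_len(max(i - 1L, 0))] ==
                       ns_of[i])
    if (i <= spec$n_namespaces || !length(earlier)) next  # a root
    k <- sample.int(min(spec$max_parents, length(earlier)), 1L)
    ps <- sample_safe(earlier, k)
    depth[i] <- max(depth[ps]) + 1L
    for (p in ps) {
      rel <- if (stats::runif(1) < 0.25) "part_of" else "is_a"
      edges[[length(edges) + 1L]] <- c(ids[i], ids[p], rel)
    }
  }
  terms <- data.frame(id = ids, name = paste("term", ids),
                      namespace = ns_of, obsolete = FALSE,
                      stringsAsFactors = FALSE)
  edges_df <- if (length(edges)) {
    e <- do.call(rbind, edges)
    data.frame(child = e[, 1], parent = e[, 2], relation = e[, 3],
               stringsAsFactors = FALSE)
  } else {
    data.frame(child = character(), parent = character(),
               relation = character(), stringsAsFactors = FALSE)
  }
  o <- build_ontology(terms, edges_df)

  non_root <- setdiff(ids, o$roots)
  if (!length(non_root)) non_root <- ids
  w <- if (spec$annotation_bias == "leaf") {
    (depth[match(non_root, ids)] + 1)
  } else {
    rep(1, length(non_root))
  }

  store <- new_store()
  pids <- sprintf("P:%04d", seq_len(spec$n_proteins))
  ann_rows <- list()
  for (pid in pids) {
    k <- sample_safe(seq(spec$annotations_per_protein[1],
                         spec$annotations_per_protein[2]), 1L)
    ann <- if (k > 0) {
      sample_safe(non_root, min(k, length(non_root)), prob = w)
    } else character()
    store$proteins[[pid]] <- list(name = pid, annotations = ann,
                                  domains = character())
    for (a in ann) ann_rows[[length(ann_rows) + 1L]] <- c(pid, a)
  }
  if (spec$n_proteins >= 2L) {
    for (r in seq_len(spec$n_interactions)) {
      pair <- pids[sample.int(spec$n_proteins, 2L)]
      store <- add_interaction(store, pair[1], pair[2], "synthetic")
    }
  }

  dom_rows <- list()
  if (spec$n_domains > 0) {
    doms <- sprintf("D:%03d", seq_len(spec$n_domains))
    for (pid in pids) {
      kd <- sample.int(min(2L, spec$n_domains), 1L)
      dd <- sample_safe(doms, kd)
      store$proteins[[pid]]$domains <- sort(dd)
      for (d in sort(dd)) dom_rows[[length(dom_rows) + 1L]] <- c(pid, d)
    }
    if (spec$n_ddis > 0) {
      all_pairs <- t(utils::combn(doms, 2L))
      pick <- sample.int(nrow(all_pairs), spec$n_ddis)
      for (r in sort(pick)) {
        store$ddis <- rbind(store$ddis,
                            data.frame(d1 = all_pairs[r, 1],
                                       d2 = all_pairs[r, 2],
                                       stringsAsFactors = FALSE))
      }
    }
  }

  out <- list(ontology = o, store = store, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      obo = file.path(dir, "ontology.obo"),
      annotations = file.path(dir, "annotations.tsv"),
      interactions = file.path(dir, "interactions.tsv"),
      protein_domains = file.path(dir, "protein_domains.tsv"),
      ddis = file.path(dir, "ddis.tsv"),
      manifest = file.path(dir, "manifest.json"))
    write_obo(o, paths$obo)
    writeLines(c("# protein_id\tterm_id",
                 vapply(ann_rows, paste, character(1), collapse = "\t")),
               paths$annotations)
    writeLines(c("# protein_a\tprotein_b",
                 if (nrow(store$interactions))
                   paste(store$interactions$a, store$interactions$b,
                         sep = "\t")),
               paths$interactions)
    writeLines(c("# protein_id\tdomain_id",
                 vapply(dom_rows, paste, character(1), collapse = "\t")),
               paths$protein_domains)
    writeLines(c("# domain_a\tdomain_b",
                 if (nrow(store$ddis))
                   paste(store$ddis$d1, store$ddis$d2, sep = "\t")),
               paths$ddis)
    jsonlite::write_json(unclass(spec), paths$manifest, auto_unbox = TRUE)
    out$paths <- paths
  }
  out
}

#' Write an ontology as an OBO flat file
#'
#' Minimal OBO 1.2 serialization of the terms and edges (is_a lines for
#' `is_a`, relationship lines otherwise); the round-trip companion of
#' [parse_obo()].
#'
#' @param o An `"ontology"`.
#' @param path Output path.
#' @export
write_obo <- function(o, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (id in o$ids) {
    writeLines(c("", "[Term]", paste0("id: ", id),
                 paste0("name: ", o$name[[id]])), con)
    if (!is.na(o$namespace[[id]])) {
      writeLines(paste0("namespace: ", o$namespace[[id]]), con)
    }
    for (s in o$synonyms[[id]]) {
      writeLines(sprintf("synonym: \"%s\" EXACT []", s), con)
    }
    e <- o$edges[o$edges$child == id, , drop = FALSE]
    for (r in seq_len(nrow(e))) {
      if (e$relation[r] == "is_a") {
        writeLines(paste0("is_a: ", e$parent[r]), con)
      } else {
        writeLines(paste0("relationship: ", e$relation[r], " ",
                          e$parent[r]), con)
      }
    }
    if (o$obsolete[[id]]) writeLines("is_obsolete: true", con)
  }
  invisible(path)
}
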