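#' Construct and validate an ontology DAG
#'
#' The central container for a term hierarchy: terms with typed parent edges,
#' of which a configurable subset of relation types (`closure_relations`,
#' by default `is_a` and `part_of`) define ancestry. On construction the
#' closure subgraph is checked for cycles and dangling references, the roots
#' are identified, and the ancestor closure of every non-obsolete term is
#' precomputed bottom-up in topological order (each ancestor appears once,
#' however many paths reach it).
#'
#' @param terms data.frame with columns `id`, `name`, and optionally
#'   `namespace`, `obsolete` (logical); one row per term. A `synonyms`
#'   list-column (character vectors) is honoured if present.
#' @param edges data.frame with columns `child`, `parent`, `relation`;
#'   one row per typed parent edge. May have zero rows.
#' @param closure_relations character vector of relation types treated as
#'   ancestry; other relation types are retained but excluded from closures.
#' @return An object of class `"ontology"`.
#' @export
build_ontology <- function(terms, edges,
                           closure_relations = c("is_a", "part_of")) {
  stopifnot(is.data.frame(terms), is.data.frame(edges))
  if (!length(closure_relations)) stop("'closure_relations' must be non-empty")
  ids <- as.character(terms$id)
  if (any(!nzchar(ids)) || anyNA(ids)) stop("term ids must be non-empty")
  if (anyDuplicated(ids)) {
    stop("duplicate term id: ", ids[duplicated(ids)][1L])
  }
  nm <- if ("name" %in% names(terms)) as.character(terms$name) else ids
  ns <- if ("namespace" %in% names(terms)) as.character(terms$namespace)
        else rep(NA_character_, length(ids))
  obs <- if ("obsolete" %in% names(terms)) as.logical(terms$obsolete)
         else rep(FALSE, length(ids))
  obs[is.na(obs)] <- FALSE
  syn <- if ("synonyms" %in% names(terms)) terms$synonyms
         else rep(list(character()), length(ids))

  edges <- data.frame(
    child = as.character(edges$child),
    parent = as.character(edges$parent),
    relation = as.character(edges$relation),
    stringsAsFactors = FALSE
  )
  missing_ref <- setdiff(unique(c(edges$child, edges$parent)), ids)
  if (length(missing_ref)) {
    stop("edge refers to unknown term id: ", missing_ref[1L])
  }

  o <- structure(list(
    ids = ids,
    name = stats::setNames(nm, ids),
    namespace = stats::setNames(ns, ids),
    synonyms = stats::setNames(syn, ids),
    obsolete = stats::setNames(obs, ids),
    edges = edges,
    closure_relations = closure_relations
  ), class = "ontology")
  validate_ontology(o)
}

# cycle check, root identification and bottom-up ancestor precomputation.
# Obsolete terms are kept in the object but take no part in the closure graph.
validate_ontology <- function(o) {
  ids <- o$ids
  active <- ids[!o$obsolete]
  idx <- stats::setNames(seq_along(ids), ids)

  ce <- o$edges[o$edges$relation %in% o$closure_relations, , drop = FALSE]
  ce <- ce[!o$obsolete[ce$child] & !o$obsolete[ce$parent], , drop = FALSE]

  parent_idx <- rep(list(integer()), length(ids))
  if (nrow(ce)) {
    sp <- split(unname(idx[ce$parent]), ce$child)
    parent_idx[idx[names(sp)]] <- lapply(sp, function(v) sort(unique(v)))
  }

  # Kahn topological sort over the child -> parent closure graph
  child_idx <- rep(list(integer()), length(ids))
  if (nrow(ce)) {
    sc <- split(unname(idx[ce$child]), ce$parent)
    child_idx[idx[names(sc)]] <- lapply(sc, function(v) sort(unique(v)))
  }
  indeg <- lengths(parent_idx)              # number of unprocessed parents
  indeg[o$obsolete[ids]] <- NA_integer_
  queue <- which(indeg == 0L)               # roots first
  topo <- integer(0)
  indeg2 <- indeg
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    topo <- c(topo, v)
    for (c in child_idx[[v]]) {
      indeg2[c] <- indeg2[c] - 1L
      if (indeg2[c] == 0L) queue <- c(queue, c)
    }
  }
  n_active <- sum(!o$obsolete)
  if (length(topo) < n_active) {
    left <- setdiff(which(!o$obsolete[ids]), topo)
    stop("cycle detected among closure relations: ",
         paste(find_cycle(parent_idx, left[1L], ids), collapse = " -> "))
  }

  # ancestors, parents-first order guarantees parent closures are ready
  anc <- rep(list(integer()), length(ids))
  for (v in topo) {
    ps <- parent_idx[[v]]
    if (length(ps)) {
      anc[[v]] <- sort(unique(c(ps, unlist(anc[ps]))))
    }
  }

  o$parent_idx <- parent_idx
  o$anc_idx <- anc
  o$roots <- ids[!o$obsolete & lengths(parent_idx) == 0L]
  o
}

# walk parent pointers from a node known to sit on/above a cycle until a
# repeat is seen; returns the cycle as a term-id path for the error message
find_cycle <- function(parent_idx, start, ids) {
  path <- integer(0)
  v <- start
  repeat {
    if (v %in% path) {
      cyc <- c(path[which(path == v)[1L]:length(path)], v)
      return(ids[cyc])
    }
    path <- c(path, v)
    nxt <- parent_idx[[v]]
    nxt <- nxt[vapply(nxt, function(p) length(parent_idx[[p]]) > 0L ||
                        p %in% path, logical(1))]
    if (!length(nxt)) nxt <- parent_idx[[v]]
    v <- nxt[[1L]]
  }
}

#' @export
print.ontology <- function(x, ...) {
  cat("<ontology> ", sum(!x$obsolete), " terms (",
      sum(x$obsolete), " obsolete), ",
      nrow(x$edges), " edges, ", length(x$roots), " root(s); closure over {",
      paste(x$closure_relations, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Parse an OBO flat file into an ontology
#'
#' Reads OBO 1.2/1.4 `[Term]` stanzas (keys: `id`, `name`, `namespace`,
#' `synonym`, `is_a`, `relationship`, `is_obsolete`). `is_a` lines and
#' `relationship` lines whose type is in `closure_relations` become ancestry
#' edges; other relationship types are recorded but excluded from closures.
#' Obsolete terms are retained, flagged, and excluded from encoding and
#' search.
#'
#' @param path Path to an OBO flat file.
#' @inheritParams build_ontology
#' @return An `"ontology"` object.
#' @export
parse_obo <- function(path, closure_relations = c("is_a", "part_of")) {
  if (!file.exists(path)) stop("cannot read OBO file: ", path)
  lines <- readLines(path, warn = FALSE)

  cur <- NULL
  in_term <- FALSE
  terms <- list()
  edges <- list()
  flush <- function(cur) {
    if (is.null(cur$id)) stop("[Term] stanza without an id")
    terms[[length(terms) + 1L]] <<- cur
  }
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (grepl("^\\[", ln)) {
      if (in_term) flush(cur)
      in_term <- identical(ln, "[Term]")
      cur <- list(synonyms = character())
      next
    }
    if (!in_term || !nzchar(ln)) next
    m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) < 3L) next
    key <- m[2L]; val <- m[3L]
    val <- sub("\\s+!.*$", "", val)  # strip trailing '! comment'
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_obsolete") cur$obsolete <- identical(val, "true")
    else if (key == "synonym") {
      sm <- regmatches(val, regexec("^\"(.*)\"", val))[[1L]]
      if (length(sm) == 2L) cur$synonyms <- c(cur$synonyms, sm[2L])
    } else if (key == "is_a") {
      edges[[length(edges) + 1L]] <- c(cur$id, val, "is_a")
    } else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1L]]
      if (length(parts) >= 2L) {
        edges[[length(edges) + 1L]] <- c(cur$id, parts[2L], parts[1L])
      }
    }
  }
  if (in_term) flush(cur)
  if (!length(terms)) stop("no [Term] stanzas found in ", path)

  terms_df <- data.frame(
    id = vapply(terms, function(t) t$id, character(1)),
    name = vapply(terms, function(t) t$name %||% t$id, character(1)),
    namespace = vapply(terms, function(t) t$namespace %||% NA_character_,
                       character(1)),
    obsolete = vapply(terms, function(t) isTRUE(t$obsolete), logical(1)),
    stringsAsFactors = FALSE
  )
  terms_df$synonyms <- lapply(terms, function(t) t$synonyms)
  # stanza ids may repeat edges; edge list may be empty
  edges_df <- if (length(edges)) {
    e <- do.call(rbind, edges)
    data.frame(child = e[, 1L], parent = e[, 2L], relation = e[, 3L],
               stringsAsFactors = FALSE)
  } else {
    data.frame(child = character(), parent = character(),
               relation = character(), stringsAsFactors = FALSE)
  }
  build_ontology(terms_df, edges_df, closure_relations)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ancestor closure of a term
#'
#' All terms reachable from `term_id` by following closure-relation edges
#' upward, excluding `term_id` itself. Each ancestor appears exactly once
#' even when reachable along multiple paths.
#'
#' @param o An `"ontology"`.
#' @param term_id Term identifier (must be present and non-obsolete).
#' @return Character vector of ancestor term ids (sorted).
#' @export
ancestors <- function(o, term_id) {
  i <- match(term_id, o$ids)
  if (is.na(i)) stop("unknown term id: ", term_id)
  if (o$obsolete[[i]]) stop("term is obsolete: ", term_id)
  sort(o$ids[o$anc_idx[[i]]])
}

#' Descendant set of a term
#'
#' Inverse of [ancestors()]: every non-obsolete term whose ancestor closure
#' contains `term_id`.
#'
#' @inheritParams ancestors
#' @return Character vector of descendant term ids (sorted, excluding
#'   `term_id`).
#' @export
descendants <- function(o, term_id) {
  i <- match(term_id, o$ids)
  if (is.na(i)) stop("unknown term id: ", term_id)
  hit <- vapply(seq_along(o$ids), function(j) {
    !o$obsolete[[j]] && i %in% o$anc_idx[[j]]
  }, logical(1))
  sort(setdiff(o$ids[hit], term_id))
}

#' Dump the ontology DAG as an edge list
#'
#' Debug export of every recorded edge as a 3-column table
#' (`child`, `parent`, `relation`), sorted for reproducibility. Used for
#' round-trip checks and for feeding external graph tooling.
#'
#' @param o An `"ontology"`.
#' @param path Optional file path; when given, written as TSV.
#' @return The edge data.frame, invisibly when `path` is given.
#' @export
dump_edges <- function(o, path = NULL) {
  e <- o$edges
  e <- e[order(e$child, e$parent, e$relation), , drop = FALSE]
  rownames(e) <- NULL
  if (!is.null(path)) {
    utils::write.table(e, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(e))
  }
  e
}
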