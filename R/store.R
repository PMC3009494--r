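#' Create an empty interaction store
#'
#' Holds the searchable corpus: proteins with their annotation and domain
#' sets, protein-protein interactions (undirected, canonicalized), and
#' domain-domain interactions.
#'
#' @return Object of class `"ppi_store"`.
#' @export
new_store <- function() {
  structure(list(
    proteins = list(),        # id -> list(name, annotations, domains)
    interactions = data.frame(a = character(), b = character(),
                              source = character(),
                              self_interaction = logical(),
                              stringsAsFactors = FALSE),
    ddis = data.frame(d1 = character(), d2 = character(),
                      stringsAsFactors = FALSE)
  ), class = "ppi_store")
}

#' @export
print.ppi_store <- function(x, ...) {
  cat("<ppi_store> ", length(x$proteins), " proteins, ",
      nrow(x$interactions), " interactions, ",
      nrow(x$ddis), " domain-domain interactions\n", sep = "")
  invisible(x)
}

# shared TSV reader: tab-separated, '#' comments, no header, no quoting
read_tsv_rows <- function(path, min_cols) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) {
    return(matrix(character(), ncol = min_cols, nrow = 0))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < min_cols)
  if (length(bad)) {
    stop("malformed row ", bad[1L], " in ", path,
         " (expected >= ", min_cols, " tab-separated fields)")
  }
  t(vapply(parts, function(p) p[seq_len(min_cols)], character(min_cols)))
}

#' Load protein annotations from a TSV file
#'
#' Rows `protein_id TAB term_id [TAB name]`; rows for the same protein
#' aggregate into one annotation set (deduplicated). In `strict` mode an
#' annotation term absent from the ontology (or obsolete) aborts the load
#' naming the row; in `lenient` mode the protein is kept, the annotation is
#' dropped, and a warning is raised.
#'
#' @param path Annotation TSV path.
#' @param o The `"ontology"` annotations must resolve in.
#' @param mode `"strict"` or `"lenient"`.
#' @param store An existing `"ppi_store"` to add to (default: fresh store).
#' @return The updated `"ppi_store"`.
#' @export
load_annotations <- function(path, o, mode = c("strict", "lenient"),
                             store = new_store()) {
  mode <- match.arg(mode)
  rows <- read_tsv_rows(path, 2L)
  known <- o$ids[!o$obsolete]
  for (r in seq_len(nrow(rows))) {
    pid <- rows[r, 1L]; tid <- rows[r, 2L]
    if (!pid %in% names(store$proteins)) {
      store$proteins[[pid]] <- list(name = pid, annotations = character(),
                                    domains = character())
    }
    if (!tid %in% known) {
      if (mode == "strict") {
        stop("row ", r, " of ", path, ": annotation term '", tid,
             "' does not resolve in the ontology")
      }
      warning("dropping unresolved annotation '", tid, "' for protein '",
              pid, "' (row ", r, ")")
      next
    }
    store$proteins[[pid]]$annotations <-
      union(store$proteins[[pid]]$annotations, tid)
  }
  store
}

#' Load protein-protein interactions from a TSV file
#'
#' Rows `protein_id TAB protein_id [TAB source]`. Interactions are stored
#' undirected: each pair is canonicalized to lexicographic order and
#' deduplicated. Self-interactions are permitted and flagged. Endpoints
#' must already be in the store (strict) or the row is skipped with a
#' warning (lenient).
#'
#' @param path Interaction TSV path.
#' @param store A `"ppi_store"` holding the endpoint proteins.
#' @param mode `"strict"` or `"lenient"`.
#' @return The updated `"ppi_store"`.
#' @export
load_interactions <- function(path, store, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(store)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) stop("malformed row ", bad[1L], " in ", path)
  for (r in seq_along(parts)) {
    p <- parts[[r]]
    a <- p[1L]; b <- p[2L]
    src <- if (length(p) >= 3L) p[3L] else "loaded"
    missing <- setdiff(c(a, b), names(store$proteins))
    if (length(missing)) {
      if (mode == "strict") {
        stop("row ", r, " of ", path, ": endpoint '", missing[1L],
             "' not in store")
      }
      warning("skipping interaction row ", r, ": unknown endpoint '",
              missing[1L], "'")
      next
    }
    store <- add_interaction(store, a, b, src)
  }
  store
}

add_interaction <- function(store, a, b, source = "loaded") {
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  key <- paste0(store$interactions$a, "\r", store$interactions$b)
  if (paste0(a, "\r", b) %in% key) return(store)
  store$interactions <- rbind(store$interactions, data.frame(
    a = a, b = b, source = source, self_interaction = identical(a, b),
    stringsAsFactors = FALSE))
  store
}

#' Load protein-domain membership from a TSV file
#'
#' Rows `protein_id TAB domain_id` (has-a relation). Unknown proteins are
#' created on the fly: the domain tables may describe proteins absent from
#' the annotation corpus.
#'
#' @inheritParams load_interactions
#' @return The updated `"ppi_store"`.
#' @export
load_protein_domains <- function(path, store) {
  rows <- read_tsv_rows(path, 2L)
  for (r in seq_len(nrow(rows))) {
    pid <- rows[r, 1L]; did <- rows[r, 2L]
    if (!pid %in% names(store$proteins)) {
      store$proteins[[pid]] <- list(name = pid, annotations = character(),
                                    domains = character())
    }
    store$proteins[[pid]]$domains <-
      union(store$proteins[[pid]]$domains, did)
  }
  store
}

#' Load domain-domain interactions from a TSV file
#'
#' Rows `domain_id TAB domain_id`; canonicalized to lexicographic order and
#' deduplicated.
#'
#' @inheritParams load_interactions
#' @return The updated `"ppi_store"`.
#' @export
load_domain_interactions <- function(path, store) {
  rows <- read_tsv_rows(path, 2L)
  for (r in seq_len(nrow(rows))) {
    d1 <- rows[r, 1L]; d2 <- rows[r, 2L]
    if (d1 > d2) { tmp <- d1; d1 <- d2; d2 <- tmp }
    if (!any(store$ddis$d1 == d1 & store$ddis$d2 == d2)) {
      store$ddis <- rbind(store$ddis,
                          data.frame(d1 = d1, d2 = d2,
                                     stringsAsFactors = FALSE))
    }
  }
  store
}

#' Write interactions as PSI-MI 2.5 XML
#'
#' Emits a single-entry PSI-MI 2.5 document: an `interactorList` with each
#' participating protein once (identity xref = protein id) and an
#' `interactionList` with participant references. Element order is sorted
#' by id, so output is deterministic.
#'
#' @param store A `"ppi_store"` (resolves interactor names).
#' @param path Output path.
#' @param interactions Optional interaction data.frame (columns `a`, `b`);
#'   defaults to the store's interactions.
#' @return `path`, invisibly.
#' @export
write_psimi <- function(store, path, interactions = NULL) {
  if (is.null(interactions)) interactions <- store$interactions
  prot_ids <- sort_c(unique(c(interactions$a, interactions$b)))
  missing <- setdiff(prot_ids, names(store$proteins))
  if (length(missing)) stop("interaction endpoint not in store: ",
                            missing[1L])
  doc <- xml2::xml_new_root("entrySet",
                            xmlns = "net:sf:psidev:mi",
                            level = "2", version = "5", minorVersion = "4")
  entry <- xml2::xml_add_child(doc, "entry")
  ilist <- xml2::xml_add_child(entry, "interactorList")
  iid <- stats::setNames(seq_along(prot_ids), prot_ids)
  for (pid in prot_ids) {
    it <- xml2::xml_add_child(ilist, "interactor", id = as.character(iid[[pid]]))
    nms <- xml2::xml_add_child(it, "names")
    xml2::xml_add_child(nms, "shortLabel", store$proteins[[pid]]$name)
    xr <- xml2::xml_add_child(it, "xref")
    xml2::xml_add_child(xr, "primaryRef", db = "local", id = pid)
  }
  xlist <- xml2::xml_add_child(entry, "interactionList")
  if (nrow(interactions)) {
    interactions <- interactions[order(interactions$a, interactions$b), ,
                                 drop = FALSE]
    for (r in seq_len(nrow(interactions))) {
      xi <- xml2::xml_add_child(xlist, "interaction",
                                id = as.character(length(prot_ids) + r))
      pl <- xml2::xml_add_child(xi, "participantList")
      for (end in c(interactions$a[r], interactions$b[r])) {
        pp <- xml2::xml_add_child(pl, "participant")
        xml2::xml_add_child(pp, "interactorRef", as.character(iid[[end]]))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read interactions back from a PSI-MI 2.5 document
#'
#' Round-trip companion to [write_psimi()]: resolves participant
#' `interactorRef`s through the interactor xrefs and returns the canonical
#' (lexicographically ordered, deduplicated) pair set.
#'
#' @param path PSI-MI XML path.
#' @return data.frame with columns `a`, `b`.
#' @export
read_psimi <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  its <- xml2::xml_find_all(doc, ".//interactorList/interactor")
  ids <- xml2::xml_attr(its, "id")
  refs <- xml2::xml_attr(xml2::xml_find_first(its, ".//xref/primaryRef"),
                         "id")
  lut <- stats::setNames(refs, ids)
  xs <- xml2::xml_find_all(doc, ".//interactionList/interaction")
  pairs <- lapply(xs, function(x) {
    rr <- xml2::xml_text(xml2::xml_find_all(x, ".//interactorRef"))
    sort(lut[rr])
  })
  pairs <- pairs[lengths(pairs) == 2L]
  if (!length(pairs)) {
    return(data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, pairs)
  df <- unique(data.frame(a = m[, 1L], b = m[, 2L],
                          stringsAsFactors = FALSE))
  df <- df[order(df$a, df$b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write interactions as a SIF edge list
#'
#' `a TAB pp TAB b`, sorted; the dialect Cytoscape-style network viewers
#' read directly.
#'
#' @inheritParams write_psimi
#' @export
write_sif <- function(store, path, interactions = NULL) {
  if (is.null(interactions)) interactions <- store$interactions
  interactions <- interactions[order(interactions$a, interactions$b), ,
                               drop = FALSE]
  writeLines(paste(interactions$a, "pp", interactions$b, sep = "\t"), path)
  invisible(path)
}
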