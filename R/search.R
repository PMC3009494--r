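#' Build the Gödel-code index over an ontology and a corpus
#'
#' Assigns primes to ontology terms, encodes every term, and derives the
#' entity codes of the corpus: each protein's annotation code (the lcm of
#' its annotation-term codes) and, when domain tables are loaded, the
#' domain-arithmetic codes — domains receive the primes after the
#' ontology's, proteins the primes after the domains', a protein's domain
#' code is its own prime times its domains' primes, and each DDI's code is
#' the product of the two domain primes.
#'
#' @param o An `"ontology"`.
#' @param store Optional `"ppi_store"` with the corpus.
#' @param order Term ordering for prime assignment, see [assign_primes()].
#' @return Object of class `"godel_index"`.
#' @export
build_index <- function(o, store = NULL, order = c("lex", "insertion")) {
  order <- match.arg(order)
  pa <- assign_primes(o, order)
  codes <- encode_ontology(o, pa)
  idx <- list(ontology = o, assignment = pa, term_codes = codes,
              entity_codes = NULL, domain_assignment = NULL,
              ddi_codes = NULL, protein_domain_codes = NULL,
              ac = build_autocomplete(o))
  if (!is.null(store)) {
    pids <- sort_c(names(store$proteins))
    ent <- vector("list", length(pids))
    names(ent) <- pids
    for (pid in pids) {
      ann <- store$proteins[[pid]]$annotations
      ent[[pid]] <- if (length(ann)) {
        entity_code(lapply(ann, function(t) code_of(codes, t)), owner = pid)
      } else {
        godel_code(1L, owner = pid, factors = numeric())
      }
    }
    idx$entity_codes <- ent

    domains <- sort_c(unique(unlist(c(
      lapply(store$proteins, `[[`, "domains"),
      list(store$ddis$d1, store$ddis$d2)))))
    if (length(domains)) {
      pa2 <- extend_assignment(pa, domains)
      pa2 <- extend_assignment(pa2, pids)
      idx$domain_assignment <- pa2
      if (nrow(store$ddis)) {
        idx$ddi_codes <- lapply(seq_len(nrow(store$ddis)), function(r) {
          ps <- sort(as.numeric(pa2[c(store$ddis$d1[r], store$ddis$d2[r])]))
          godel_code(prod_primes(ps),
                     owner = paste0(store$ddis$d1[r], "-", store$ddis$d2[r]),
                     factors = ps)
        })
      } else {
        idx$ddi_codes <- list()
      }
      idx$protein_domain_codes <- lapply(stats::setNames(pids, pids),
        function(pid) {
          ps <- sort(as.numeric(pa2[c(pid, store$proteins[[pid]]$domains)]))
          godel_code(prod_primes(ps), owner = pid, factors = ps)
        })
    }
  }
  structure(idx, class = "godel_index")
}

#' @export
print.godel_index <- function(x, ...) {
  cat("<godel_index> ", length(x$term_codes$term_id), " terms encoded",
      if (!is.null(x$entity_codes))
        paste0(", ", length(x$entity_codes), " proteins"),
      if (!is.null(x$ddi_codes))
        paste0(", ", length(x$ddi_codes), " DDIs"),
      "\n", sep = "")
  invisible(x)
}

#' A conjunctive query condition
#'
#' One or more term ids that a protein must satisfy simultaneously; a
#' protein satisfies a term when any one of its annotations is the term or
#' a descendant of it (different annotations may satisfy different terms).
#' `target` selects which side of an interaction the condition constrains.
#'
#' @param terms Non-empty character vector of term ids.
#' @param target `"either"`, `"query"` or `"partner"`.
#' @return Object of class `"query_condition"`.
#' @export
query_condition <- function(terms, target = c("either", "query", "partner")) {
  target <- match.arg(target)
  terms <- as.character(terms)
  if (!length(terms)) stop("a query condition needs at least one term")
  structure(list(terms = terms, target = target),
            class = "query_condition")
}

# prime of a term, erroring on unknown/unassigned ids
term_prime <- function(index, term_id) {
  p <- index$assignment[term_id]
  if (is.na(p)) stop("unknown or unassigned term id: ", term_id)
  as.numeric(p)
}

# does this protein satisfy term q (annotated with q or a descendant)?
# Divisibility of the entity code by prime(q) is the source of truth.
protein_satisfies <- function(index, protein_id, term_id) {
  p <- term_prime(index, term_id)
  ec <- index$entity_codes[[protein_id]]
  if (is.null(ec)) stop("unknown protein: ", protein_id)
  (ec$value %% openssl::bignum(sprintf("%.0f", p))) == 0L
}

protein_satisfies_all <- function(index, protein_id, terms) {
  all(vapply(terms, function(tt) protein_satisfies(index, protein_id, tt),
             logical(1)))
}

# which annotations of the protein are responsible for satisfying term q
matching_annotations <- function(store, index, protein_id, term_id) {
  q <- code_of(index$term_codes, term_id)
  ann <- store$proteins[[protein_id]]$annotations
  ann[vapply(ann, function(a) {
    subsumes(q, code_of(index$term_codes, a))
  }, logical(1))]
}

#' Ontology-aware protein retrieval
#'
#' Every protein whose entity code is divisible by the query term's prime —
#' i.e. annotated with the term or with any descendant of it. This is the
#' true-path-rule search the encoding exists for.
#'
#' @param store A `"ppi_store"`.
#' @param index A `"godel_index"` built over the store.
#' @param term_id Query term id.
#' @return Sorted character vector of protein ids.
#' @export
find_proteins_by_term <- function(store, index, term_id) {
  term_prime(index, term_id)  # validates
  pids <- names(index$entity_codes)
  sort_c(pids[vapply(pids, function(p) {
    protein_satisfies(index, p, term_id)
  }, logical(1))])
}

#' ID-matching baseline retrieval
#'
#' The syntactic comparator: proteins whose annotation set literally
#' contains the query term, with no ontology closure. Always a subset of
#' [find_proteins_by_term()]; provided so the ontology-vs-ID comparison can
#' be reproduced on any corpus.
#'
#' @inheritParams find_proteins_by_term
#' @return Sorted character vector of protein ids.
#' @export
keyword_search_baseline <- function(store, index, term_id) {
  term_prime(index, term_id)
  pids <- names(store$proteins)
  sort_c(pids[vapply(pids, function(p) {
    term_id %in% store$proteins[[p]]$annotations
  }, logical(1))])
}

new_search_result <- function(interactions, matched, cond) {
  interactions <- interactions[order(interactions$a, interactions$b), ,
                               drop = FALSE]
  rownames(interactions) <- NULL
  structure(list(interactions = interactions,
                 matched_proteins = matched,
                 query_echo = cond),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result> ", nrow(x$interactions), " interaction(s)",
      if (!is.null(x$query_echo))
        paste0(" for condition {",
               paste(x$query_echo$terms, collapse = " AND "), "} on ",
               x$query_echo$target),
      "\n", sep = "")
  invisible(x)
}

# record, per retained protein, which annotation satisfied each term
explain_matches <- function(store, index, protein_ids, terms) {
  out <- list()
  for (p in protein_ids) {
    out[[p]] <- stats::setNames(
      lapply(terms, function(tt) matching_annotations(store, index, p, tt)),
      terms)
  }
  out
}

#' Interaction partners of a protein, optionally filtered by condition
#'
#' All interactions incident to `protein_id`; when a condition is given the
#' conditioned side (default: the partner) must satisfy every condition
#' term conjunctively, by the divisibility test. Results are sorted by
#' partner id and explained: the matched-annotation map states which
#' annotation satisfied which term.
#'
#' @inheritParams find_proteins_by_term
#' @param protein_id The query protein.
#' @param cond Optional `"query_condition"`.
#' @return A `"search_result"`.
#' @export
find_partners <- function(store, index, protein_id, cond = NULL) {
  if (!protein_id %in% names(store$proteins)) {
    stop("unknown protein: ", protein_id)
  }
  ia <- store$interactions
  inc <- ia[ia$a == protein_id | ia$b == protein_id, , drop = FALSE]
  if (!is.null(cond)) {
    side <- if (identical(cond$target, "query")) {
      rep(protein_id, nrow(inc))
    } else {
      ifelse(inc$a == protein_id, inc$b, inc$a)  # the partner
    }
    keep <- vapply(side, function(p) {
      protein_satisfies_all(index, p, cond$terms)
    }, logical(1))
    inc <- inc[keep, , drop = FALSE]
    matched <- explain_matches(store, index,
                               unique(side[keep]), cond$terms)
  } else {
    matched <- list()
  }
  new_search_result(inc, matched, cond)
}

#' Conjunctive multi-term interaction search
#'
#' Every interaction with an endpoint (per the condition's target;
#' `"either"` by default) satisfying all condition terms. Equals the
#' intersection over terms of the single-term searches; an interaction is
#' counted once even when both endpoints qualify.
#'
#' @inheritParams find_proteins_by_term
#' @param cond A `"query_condition"`.
#' @return A `"search_result"`.
#' @export
multi_condition_search <- function(store, index, cond) {
  stopifnot(inherits(cond, "query_condition"))
  ia <- store$interactions
  if (!nrow(ia)) return(new_search_result(ia, list(), cond))
  sat <- function(p) protein_satisfies_all(index, p, cond$terms)
  ok_a <- vapply(ia$a, sat, logical(1))
  ok_b <- vapply(ia$b, sat, logical(1))
  keep <- switch(cond$target,
                 either = ok_a | ok_b,
                 query = ok_a,
                 partner = ok_b)
  kept <- ia[keep, , drop = FALSE]
  qual <- unique(c(kept$a[ok_a[keep]], kept$b[ok_b[keep]]))
  matched <- explain_matches(store, index, sort_c(qual), cond$terms)
  new_search_result(kept, matched, cond)
}

#' Infer protein-protein interactions from domain-domain interactions
#'
#' For every unordered protein pair and every loaded DDI, the pair is
#' emitted iff the product of the two protein codes is divisible by the
#' DDI code (see [infer_ppi_from_ddi()]). Pairs are deduplicated; the
#' provenance tag lists every supporting DDI.
#'
#' @inheritParams find_proteins_by_term
#' @return data.frame of inferred interactions
#'   (`a`, `b`, `source`, `self_interaction`).
#' @export
infer_interactions <- function(store, index) {
  if (is.null(index$protein_domain_codes)) {
    stop("no protein-domain / domain-domain tables loaded in this index")
  }
  pids <- names(index$protein_domain_codes)
  out <- list()
  if (length(index$ddi_codes) && length(pids) >= 2L) {
    for (i in seq_len(length(pids) - 1L)) {
      for (j in seq.int(i + 1L, length(pids))) {
        a <- pids[i]; b <- pids[j]
        support <- character()
        for (d in index$ddi_codes) {
          if (infer_ppi_from_ddi(index$protein_domain_codes[[a]],
                                 index$protein_domain_codes[[b]], d)) {
            support <- c(support, d$owner)
          }
        }
        if (length(support)) {
          out[[length(out) + 1L]] <- data.frame(
            a = a, b = b,
            source = paste0("ddi:", paste(support, collapse = ";")),
            self_interaction = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(a = character(), b = character(),
                      source = character(), self_interaction = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$a, res$b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# prefix index over names and synonyms of non-obsolete terms
build_autocomplete <- function(o) {
  ids <- o$ids[!o$obsolete]
  labels <- c(stats::setNames(as.character(o$name[ids]), ids),
              unlist(lapply(ids, function(i) {
                stats::setNames(o$synonyms[[i]],
                                rep(i, length(o$synonyms[[i]])))
              })))
  data.frame(term_id = names(labels), label = unname(labels),
             key = tolower(unname(labels)), stringsAsFactors = FALSE)
}

#' Autocomplete a partial term name
#'
#' Case-insensitive prefix match over term names and synonyms,
#' deduplicated by term id, ordered by matched string then term id. An
#' empty prefix returns an empty result.
#'
#' @param index A `"godel_index"` (or an `"ontology"`).
#' @param prefix Partial term text.
#' @param limit Maximum number of results.
#' @return data.frame with columns `term_id`, `name`, `matched`.
#' @export
autocomplete <- function(index, prefix, limit = 10L) {
  ac <- if (inherits(index, "godel_index")) index$ac
        else build_autocomplete(index)
  o <- if (inherits(index, "godel_index")) index$ontology else index
  empty <- data.frame(term_id = character(), name = character(),
                      matched = character(), stringsAsFactors = FALSE)
  if (!nzchar(prefix)) return(empty)
  hit <- ac[startsWith(ac$key, tolower(prefix)), , drop = FALSE]
  if (!nrow(hit)) return(empty)
  hit <- hit[order(hit$key, hit$term_id, method = "radix"), , drop = FALSE]
  hit <- hit[!duplicated(hit$term_id), , drop = FALSE]
  hit <- utils::head(hit, limit)
  data.frame(term_id = hit$term_id,
             name = as.character(o$name[hit$term_id]),
             matched = hit$label, stringsAsFactors = FALSE)
}

#' Export a search result as TSV
#'
#' Columns mirror a query-protein/partner listing: query protein, the
#' annotation(s) that satisfied the condition, partner, and the partner's
#' annotations.
#'
#' @param res A `"search_result"`.
#' @param store The `"ppi_store"` the result came from.
#' @param path Output path.
#' @param header Optional `# `-prefixed provenance lines.
#' @export
write_result_tsv <- function(res, store, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines("query_protein\tquery_annotations\tpartner_protein\tpartner_annotations",
             con)
  ia <- res$interactions
  fmt_ann <- function(p) {
    m <- res$matched_proteins[[p]]
    if (!is.null(m)) paste(unique(unlist(m)), collapse = ",")
    else paste(store$proteins[[p]]$annotations, collapse = ",")
  }
  if (nrow(ia)) {
    writeLines(vapply(seq_len(nrow(ia)), function(r) {
      paste(ia$a[r], fmt_ann(ia$a[r]), ia$b[r], fmt_ann(ia$b[r]),
            sep = "\t")
    }, character(1)), con)
  }
  invisible(path)
}
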