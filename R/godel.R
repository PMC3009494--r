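#' Assign primes to ontology terms
#'
#' Non-obsolete terms, sorted by a deterministic order (default
#' lexicographic by term id), receive the first G primes in ascending order.
#' Determinism of this step is what makes codes reproducible across runs.
#'
#' @param o An `"ontology"`.
#' @param order `"lex"` (lexicographic term id, C collation) or
#'   `"insertion"` (order of appearance in the source).
#' @param offset Skip the first `offset` primes (used when several entity
#'   classes share one prime universe).
#' @return Object of class `"prime_assignment"`: a named numeric vector of
#'   primes keyed by term id, with attributes `order` and `offset`.
#' @export
assign_primes <- function(o, order = c("lex", "insertion"), offset = 0L) {
  order <- match.arg(order)
  active <- o$ids[!o$obsolete]
  if (!length(active)) stop("ontology has no non-obsolete terms")
  ordered <- if (order == "lex") sort_c(active) else active
  new_prime_assignment(ordered, order = order, offset = offset)
}

# locale-independent lexicographic sort, so codes do not depend on LC_COLLATE
sort_c <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  sort(x)
}

new_prime_assignment <- function(ordered_ids, order = "lex", offset = 0L) {
  ps <- generate_primes(offset + length(ordered_ids))
  ps <- ps[(offset + 1L):(offset + length(ordered_ids))]
  structure(stats::setNames(ps, ordered_ids),
            order = order, offset = offset, class = "prime_assignment")
}

#' Extend a prime assignment to a further class of entities
#'
#' Appends entities (e.g. protein domains, then proteins) to an existing
#' assignment: the new ids, sorted lexicographically, receive the next
#' unused primes. Keeping ontology terms, domains and proteins in one prime
#' universe is what lets term-, domain- and protein-level codes be mixed in
#' a single divisibility test.
#'
#' @param pa A `"prime_assignment"`.
#' @param ids Character vector of new entity ids (must be disjoint from
#'   those already assigned).
#' @return The extended `"prime_assignment"`.
#' @export
extend_assignment <- function(pa, ids) {
  if (!length(ids)) return(pa)
  ids <- sort_c(unique(as.character(ids)))
  clash <- intersect(ids, names(pa))
  if (length(clash)) stop("id already prime-assigned: ", clash[1L])
  offset <- attr(pa, "offset")
  total <- offset + length(pa) + length(ids)
  ps <- generate_primes(total)
  new_ps <- ps[(offset + length(pa) + 1L):total]
  structure(c(stats::setNames(as.numeric(pa), names(pa)),
              stats::setNames(new_ps, ids)),
            order = attr(pa, "order"), offset = offset,
            class = "prime_assignment")
}

#' @export
print.prime_assignment <- function(x, ...) {
  cat("<prime_assignment> ", length(x), " entities, primes ",
      x[[1L]], "..", x[[length(x)]], " (order = ", attr(x, "order"),
      ")\n", sep = "")
  invisible(x)
}

#' Gödel code objects
#'
#' A `"godel_code"` wraps an exact arbitrary-precision squarefree integer:
#' the product of distinct primes over an ancestor closure (for a term) or
#' an annotation closure (for an entity). `factors` caches the prime set so
#' hot paths may use set membership; the integer is the source of truth.
#'
#' @param value An `openssl::bignum`, or anything coercible (integer or
#'   decimal string).
#' @param owner Term or entity id the code belongs to (or `NA`).
#' @param factors Numeric vector of the distinct primes whose product is
#'   `value` (optional cache).
#' @return Object of class `"godel_code"` with fields `value`, `owner`,
#'   `factors`.
#' @export
godel_code <- function(value, owner = NA_character_, factors = NULL) {
  v <- if (inherits(value, "bignum")) value else openssl::bignum(value)
  structure(list(value = v, owner = owner,
                 factors = if (is.null(factors)) NULL else sort(factors)),
            class = "godel_code")
}

#' @export
print.godel_code <- function(x, ...) {
  cat("<godel_code", if (!is.na(x$owner)) paste0(" ", x$owner), "> ",
      as.character(x$value),
      if (!is.null(x$factors))
        paste0(" = ", paste(format(x$factors, scientific = FALSE,
                                   trim = TRUE), collapse = " x ")),
      "\n", sep = "")
  invisible(x)
}

#' Format a Gödel code value as a decimal string
#' @param x A `"godel_code"`.
#' @param ... Unused.
#' @export
as.character.godel_code <- function(x, ...) as.character(x$value)

# coerce godel_code | bignum | number | string to bignum
code_value <- function(x) {
  if (inherits(x, "godel_code")) x$value
  else if (inherits(x, "bignum")) x
  else openssl::bignum(x)
}

#' Modified Gödel number of a term
#'
#' The squarefree product of the primes assigned to `term_id` and every
#' term in its ancestor closure — each prime exactly once, however many
#' paths reach the ancestor. Divisibility between two such codes is
#' equivalent to ancestry: `code(q)` divides `code(t)` iff `q` is an
#' ancestor of `t` or `t` itself.
#'
#' @param o An `"ontology"`.
#' @param pa A `"prime_assignment"` covering the ontology's terms.
#' @param term_id Non-obsolete term id.
#' @return A `"godel_code"`.
#' @export
modified_godel <- function(o, pa, term_id) {
  i <- match(term_id, o$ids)
  if (is.na(i)) stop("unknown term id: ", term_id)
  if (o$obsolete[[i]]) stop("term is obsolete: ", term_id)
  closure <- c(term_id, o$ids[o$anc_idx[[i]]])
  ps <- pa[closure]
  if (anyNA(ps)) stop("term not prime-assigned: ",
                      closure[is.na(ps)][1L])
  ps <- sort(as.numeric(ps))
  godel_code(prod_primes(ps), owner = term_id, factors = ps)
}

#' Encode every term of an ontology
#'
#' Computes the modified Gödel number of every non-obsolete term, using the
#' precomputed ancestor closures (bottom-up, memoized set union) rather than
#' per-term recursive traversal; output is identical to computing each term
#' independently.
#'
#' @inheritParams modified_godel
#' @return Object of class `"godel_codes"`: parallel fields `term_id`,
#'   `prime`, `value` (list of bignums) and `factors` (list of prime sets),
#'   plus the assignment.
#' @export
encode_ontology <- function(o, pa) {
  active <- names(pa)[names(pa) %in% o$ids]
  idx <- match(active, o$ids)
  factors <- vector("list", length(active))
  values <- vector("list", length(active))
  for (k in seq_along(active)) {
    closure <- c(active[k], o$ids[o$anc_idx[[idx[k]]]])
    ps <- sort(as.numeric(pa[closure]))
    factors[[k]] <- ps
    values[[k]] <- prod_primes(ps)
  }
  structure(list(term_id = active,
                 prime = as.numeric(pa[active]),
                 value = values,
                 factors = factors,
                 assignment = pa),
            class = "godel_codes")
}

#' @export
print.godel_codes <- function(x, ...) {
  cat("<godel_codes> ", length(x$term_id), " terms encoded; largest code ",
      max(vapply(x$value, function(v) nchar(as.character(v)), integer(1))),
      " decimal digits\n", sep = "")
  invisible(x)
}

#' Look up one term's code in an encoded ontology
#' @param codes A `"godel_codes"` object.
#' @param term_id Term id.
#' @return A `"godel_code"`.
#' @export
code_of <- function(codes, term_id) {
  i <- match(term_id, codes$term_id)
  if (is.na(i)) stop("term not encoded: ", term_id)
  godel_code(codes$value[[i]], owner = term_id, factors = codes$factors[[i]])
}

#' Write a code table to TSV
#'
#' Columns `term_id`, `prime`, `modified_godel`; codes as exact decimal
#' strings. The table is the regression-snapshot form of an encoding.
#'
#' @param codes A `"godel_codes"`.
#' @param path Output file path.
#' @param header Optional character vector of `# `-prefixed provenance
#'   lines written before the table.
#' @export
write_code_table <- function(codes, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines("term_id\tprime\tmodified_godel", con)
  writeLines(paste(codes$term_id,
                   format(codes$prime, scientific = FALSE, trim = TRUE),
                   vapply(codes$value, as.character, character(1)),
                   sep = "\t"), con)
  invisible(path)
}

#' Original (positional) Gödel number of an integer list
#'
#' Encodes a list of natural numbers `a_1..a_n` as
#' `prod_k p_k^{a_k}` with `p_k` the k-th prime. Unique by the fundamental
#' theorem of arithmetic, but positional: it encodes one relation at a time
#' and cannot express DAG ancestry — kept as a demonstrator of why the
#' squarefree closure encoding is needed.
#'
#' @param codes Numeric vector of integers, all `>= 1`.
#' @return An `openssl::bignum`.
#' @export
original_godel <- function(codes) {
  if (!length(codes)) stop("'codes' must be non-empty")
  if (any(codes < 1 | codes != floor(codes))) {
    stop("all codes must be integers >= 1")
  }
  ps <- generate_primes(length(codes))
  val <- openssl::bignum(1L)
  for (k in seq_along(codes)) {
    val <- val * bignum_pow(openssl::bignum(sprintf("%.0f", ps[k])),
                            codes[k])
  }
  val
}

#' Subsumption by divisibility
#'
#' `TRUE` iff the code of `t` is divisible by the code of `q`. For term
#' codes built by [modified_godel()] this is exactly "q is an
#' ancestor-or-self of t"; for entity codes it means the entity's closure
#' contains q's closure.
#'
#' @param q_code,t_code `"godel_code"` objects (or bignums / numbers).
#' @return Logical scalar.
#' @export
subsumes <- function(q_code, t_code) {
  (code_value(t_code) %% code_value(q_code)) == 0L
}

#' Entity code from annotation codes
#'
#' The code of an annotated entity (protein) is the least common multiple
#' of its annotation-term codes — equivalently the squarefree product of
#' the union of their prime sets. A query term q then satisfies the entity
#' iff `prime(q)` divides the entity code.
#'
#' @param annotation_codes Non-empty list of `"godel_code"` objects carrying
#'   factor sets.
#' @param owner Optional entity id for the resulting code.
#' @return A `"godel_code"`.
#' @export
entity_code <- function(annotation_codes, owner = NA_character_) {
  if (!length(annotation_codes)) stop("'annotation_codes' must be non-empty")
  fs <- lapply(annotation_codes, function(cd) {
    if (is.null(cd$factors)) stop("annotation code lacks its factor set")
    cd$factors
  })
  ps <- sort(unique(unlist(fs)))
  godel_code(prod_primes(ps), owner = owner, factors = ps)
}

#' Test a protein-protein interaction hypothesis against one DDI
#'
#' A protein's code is the product of its own prime and its domains'
#' primes; a domain-domain interaction (DDI) is the product of the two
#' domain primes. The hypothesis "A interacts with B" holds under the DDI
#' iff the product of the two protein codes is divisible by the DDI code —
#' i.e. one protein carries one domain of the pair and the other carries
#' the other.
#'
#' @param protA_code,protB_code Protein `"godel_code"`s.
#' @param ddi_code DDI `"godel_code"`; must be the product of exactly two
#'   distinct domain primes (enforced when the factor cache is present).
#' @return Logical scalar.
#' @export
infer_ppi_from_ddi <- function(protA_code, protB_code, ddi_code) {
  if (inherits(ddi_code, "godel_code") && !is.null(ddi_code$factors)) {
    if (length(ddi_code$factors) != 2L ||
        ddi_code$factors[1L] == ddi_code$factors[2L]) {
      stop("DDI code must be the product of two distinct domain primes")
    }
  }
  hyp <- code_value(protA_code) * code_value(protB_code)
  (hyp %% code_value(ddi_code)) == 0L
}
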