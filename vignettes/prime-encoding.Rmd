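---
title: "Prime-number encoding of ontology DAGs and divisibility-based interaction search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prime-number encoding of ontology DAGs and divisibility-based interaction search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(godelppi)
```

## The problem

Protein–protein interaction (PPI) databases are usually queried by literal
keyword or identifier matching. That search is purely syntactic: a query for
*nucleotide binding* misses every protein annotated only with *ATP binding*,
even though ATP binding is a kind of nucleotide binding in the Gene Ontology
(GO). The true-path rule of GO — an annotation to a term implies annotation
to all of its ancestors — is exactly what literal matching ignores.

`godelppi` operationalizes the true-path rule arithmetically. Every ontology
term receives a distinct prime number, and every term is represented by the
**squarefree product of the primes of the term and all of its ancestors** in
the DAG (its *modified Gödel number*). Because a squarefree integer is, by
unique factorization, just a set of primes, divisibility between two such
codes is set containment between two ancestor closures:

$$\mathrm{code}(t) = \prod_{u \,\in\, \{t\}\,\cup\,\mathrm{anc}(t)} p_u,
\qquad
\mathrm{code}(q) \mid \mathrm{code}(t) \;\Longleftrightarrow\;
q \in \{t\} \cup \mathrm{anc}(t).$$

A protein annotated with terms $A = \{a_1, \dots, a_k\}$ gets the entity
code $\mathrm{lcm}(\mathrm{code}(a_1), \dots, \mathrm{code}(a_k))$ — the
squarefree product over the union of the closures. A query term $q$ is then
satisfied by the protein iff $p_q$ divides the entity code, i.e. iff some
annotation is $q$ or a descendant of $q$. All search operations reduce to
exact integer division and modulo on arbitrary-precision integers
(`openssl::bignum`); no fixed-width arithmetic appears anywhere in the
divisibility path.

### Why not the classical positional Gödel numbering?

The classical numbering encodes a *list* $(a_1, \dots, a_n)$ as
$\prod_k p_k^{a_k}$: the $k$-th prime marks the *position*, not the symbol.
One relation at a time can be recovered exactly by factorization, but a
relation's code carries nothing about the ancestors of its participants, so
transitive ancestry across a DAG cannot be queried. `original_godel()` is
retained purely as this demonstrator; the test suite shows that a root
term's symbol never appears in the factorization of a grandchild's relation
code, while the closure encoding answers the same question with one modulo.

## The worked micro-example

```{r}
pt <- make_worked_examples()
modified_godel(pt$ontology, pt$assignment, "Term4")  # 7 x 3 x 2 = 42
subsumes(modified_godel(pt$ontology, pt$assignment, "Term2"),
         modified_godel(pt$ontology, pt$assignment, "Term4"))
```

The same arithmetic predicts interactions from domain–domain interactions
(DDIs). Domains and proteins join the term prime universe (see *Design
choices*); a protein's domain code is its own prime times its domains'
primes, a DDI's code is the product of the two domain primes, and the
hypothesis "A interacts with B" holds under a DDI iff
$\mathrm{code}(A)\cdot\mathrm{code}(B) \equiv 0 \pmod{\mathrm{code}(DDI)}$:

```{r}
ca <- pt$index$protein_domain_codes$ProteinA   # 17 x 11 = 187
cb <- pt$index$protein_domain_codes$ProteinB   # 19 x 13 = 247
ddi <- pt$index$ddi_codes[[1]]                 # 11 x 13 = 143
infer_ppi_from_ddi(ca, cb, ddi)                # 46189 mod 143 == 0
```

## Tunable parameters

* `closure_relations` (default `{is_a, part_of}`): the relation types that
  define ancestry. Both defaults participate in ancestor closures; other
  relationship types found in an OBO file (e.g. `regulates`) are recorded
  but excluded unless opted in. They can be added per call
  (`parse_obo(..., closure_relations = c("is_a", "part_of", "regulates"))`).
* `order` (default `"lex"`): the deterministic term order used to hand out
  primes. Lexicographic order over term ids under C collation is
  locale-independent, so the same ontology yields bit-identical codes on
  any machine; `"insertion"` preserves source order instead.
* `mode` (`"strict"`/`"lenient"`): whether an annotation term that does not
  resolve in the ontology aborts the load (naming the row) or is dropped
  with a warning.
* `target` of a query condition (`"either"`, `"query"`, `"partner"`): which
  side of an interaction must satisfy the condition (see below).
* Autocomplete `limit` (default 10) bounds response size; an empty prefix
  deliberately returns an empty result rather than the full vocabulary.

## Query semantics

Multiple condition terms are conjunctive: the conditioned protein must
satisfy *all* of them, where each term may be satisfied by a *different*
annotation (a biological-process condition and a cellular-component
condition can never be met by one annotation). Disjunction is expressed by
issuing separate queries and uniting results.

One subtlety is worth spelling out. With a fixed conditioned side, the
multi-term result is exactly the intersection of the single-term results.
With `target = "either"` that identity weakens to containment: an
interaction can enter each single-term result through *different*
endpoints while neither endpoint satisfies the whole conjunction. The
package implements the conjunction on a single protein (the semantics of
conditioning a query protein) and the test suite pins down both the exact
identity on a fixed side and the containment for `"either"`.

Interactions are undirected, canonicalized to lexicographic endpoint order,
and deduplicated; an interaction is counted once even when both endpoints
satisfy a condition. All search operations are pure and return
lexicographically sorted output.

## Numerical and structural choices

* **Squarefree closure products.** When a diamond makes an ancestor
  reachable along several paths its prime is multiplied in exactly once.
  Divisibility semantics depends only on prime *presence*; repeated factors
  would break the equivalence with reachability.
* **Memoized bottom-up closures.** Ancestor sets are computed once per
  ontology in topological order by set union over parents, rather than by
  per-term recursive descent (which revisits shared ancestors exponentially
  often on dense diamonds). The output is identical to the recursion's.
* **Staged prime assignment.** Ontology terms take the first primes, then
  protein domains, then proteins, each class sorted lexicographically. One
  shared prime universe is what allows term-, domain- and protein-level
  codes to meet in a single divisibility test; staging by class keeps the
  assignment stable when a corpus is loaded against an existing ontology
  encoding.
* **Factor-set cache.** Every code carries the set of primes whose product
  it is; the integer remains the source of truth and tests assert the two
  representations agree (trial division recovers exactly the cached set).
* **Sieve bound.** `generate_primes(n)` sieves up to
  $n(\log n + \log\log n)$ and doubles the limit if the estimate falls
  short; the 26,000th prime (300,023) is well within double-precision
  exactness, so primes are stored as plain numerics while code values are
  arbitrary precision.
* **Degenerate inputs.** Empty ontologies, empty annotation lists, empty
  interaction files and empty DDI tables are all defined: loaders return
  empty-but-valid stores and searches return empty results rather than
  errors. A DDI code that is not a product of two distinct domain primes is
  rejected before any arithmetic.

## The synthetic corpus generator

Real GO snapshots and curated PPI corpora are large downloads with
licensing and versioning baggage; the test suite instead runs on seeded
synthetic corpora from `generate_fixture()`. The generator emulates the
*structural* features the encoding cares about:

* a DAG grown by sampling each term's parents (1 to `max_parents`,
  diamonds arise naturally for `max_parents >= 2`) uniformly among
  earlier-created terms of the same namespace — acyclic by construction,
  no rejection sampling; about a quarter of edges are typed `part_of`,
  the rest `is_a`;
* one root per namespace, mirroring GO's three independent hierarchies;
* proteins annotated with 1–3 non-root terms by default, optionally
  leafward-weighted (`annotation_bias = "leaf"`) to mimic curators'
  preference for specific terms — the regime in which ontology-aware and
  literal search differ most;
* uniformly drawn interaction pairs and, optionally, domain tables.

It does **not** emulate GO's actual topology statistics (fan-in/fan-out
distributions, depth profile), annotation evidence codes, or the social
structure of curated interactomes (hubs, study bias). Passing property
tests therefore certify the *logic* — divisibility ≡ reachability,
monotonicity along the DAG, baseline ⊆ ontology search — on arbitrary
DAGs, not any statistical claim about real corpora. Counts reported
against a particular database snapshot are reproducible only with that
snapshot, which is out of scope here.

Problem sizes used by the automated checks: the reachability equivalence
runs on 100 random DAGs of 20–500 terms; the search properties on corpora
of 25–40 terms and 10–15 proteins; the scale smoke test encodes a
10,000-term ontology completely (mean ancestor closure ≈ 45, deepest codes
of several hundred decimal digits, far beyond 64-bit range) and re-checks
divisibility against an independent graph-reachability oracle.

## Known limitations

* Obsolete terms are parsed and flagged but excluded from encoding and
  search; merged/alternate ids (`alt_id`) are not resolved.
* No semantic-similarity scores (Resnik, Lin, …) — subsumption is boolean.
* Re-encoding after an ontology edit is a full re-encode; primes are not
  reassigned incrementally.
* OWL input and full OBO header/typedef semantics are not supported.
* The PSI-MI 2.5 writer emits a compact dialect (identity xrefs only), not
  the full controlled-vocabulary apparatus.
* Protein superfamily vocabularies are supported only as "another
  ontology" through the same generic interface; no superfamily-specific
  file formats are parsed.
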