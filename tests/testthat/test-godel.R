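test_that("generate_primes matches small cases and the sieve bound extends", {
  expect_equal(generate_primes(1), 2)
  expect_equal(generate_primes(4), c(2, 3, 5, 7))
  expect_error(generate_primes(0), "integer >= 1")
  ps <- generate_primes(1000)
  expect_length(ps, 1000)
  expect_true(all(diff(ps) > 0))
  spot <- sample(ps, 25)
  expect_true(all(vapply(spot, is_prime_trial, logical(1))))
})

test_that("the 26,000th prime agrees with an independent generator", {
  ps <- generate_primes(26000)
  # 300023 computed with an independent primality-test-based generator
  expect_equal(ps[26000], 300023)
  expect_true(is_prime_trial(ps[26000]))
})

test_that("assign_primes gives the k-th prime to the k-th term, skipping obsoletes", {
  o <- parse_obo(demo_obo())
  pa <- assign_primes(o)
  expect_equal(as.numeric(pa[c("Term1", "Term2", "Term3", "Term4")]),
               c(2, 3, 5, 7))
  solo <- build_ontology(data.frame(id = "r", name = "r"),
                         data.frame(child = character(),
                                    parent = character(),
                                    relation = character()))
  expect_equal(as.numeric(assign_primes(solo)), 2)
})

test_that("staged assignment reproduces the domain/protein prime layout", {
  pt <- make_worked_examples()
  pa2 <- pt$index$domain_assignment
  expect_equal(as.numeric(pa2[c("domainA", "domainB",
                                "ProteinA", "ProteinB")]),
               c(11, 13, 17, 19))
  expect_error(extend_assignment(pa2, "domainA"), "already prime-assigned")
})

test_that("modified Gödel numbers reproduce the worked hierarchy codes", {
  pt <- make_worked_examples()
  o <- pt$ontology; pa <- pt$assignment
  expect_equal(as.character(modified_godel(o, pa, "Term2")), "6")
  expect_equal(as.character(modified_godel(o, pa, "Term3")), "30")
  expect_equal(as.character(modified_godel(o, pa, "Term4")), "42")
  expect_equal(as.character(modified_godel(o, pa, "Term1")), "2")
  expect_error(modified_godel(o, pa, "TermX"), "unknown term")
})

test_that("diamond closures are squarefree: shared ancestors count once", {
  d <- diamond_ontology()
  pa <- assign_primes(d)  # A=2 B=3 C=5 D=7
  cd <- modified_godel(d, pa, "D")
  expect_equal(as.character(cd), "210")
  expect_equal(cd$factors, c(2, 3, 5, 7))
})

test_that("original (positional) Gödel numbers reproduce the demonstrator values", {
  expect_equal(as.character(original_godel(c(4, 1, 3))), "6000")
  expect_equal(as.character(original_godel(c(5, 2, 4))), "180000")
  expect_equal(as.character(original_godel(c(6, 1, 4))), "120000")
  expect_equal(as.character(original_godel(1)), "2")
  expect_error(original_godel(numeric()), "non-empty")
  expect_error(original_godel(c(1, 0)), "integers >= 1")
})

test_that("the positional coding cannot express transitive DAG ancestry", {
  # the three demonstration relations get distinct codes (injectivity) ...
  r1 <- original_godel(c(4, 1, 3))   # Term2 is_a Term1
  r2 <- original_godel(c(5, 2, 4))   # Term3 part_of Term2
  r3 <- original_godel(c(6, 1, 4))   # Term4 is_a Term2
  expect_length(unique(c(as.character(r1), as.character(r2),
                         as.character(r3))), 3)
  # ... and unique factorization recovers exactly the one encoded relation:
  # exponents of 120000 over primes 2,3,5 are (6,1,4) = Term4, is_a, Term2
  recover <- function(code) {
    vapply(c(2, 3, 5), function(p) {
      e <- 0L
      while ((code %% openssl::bignum(p)) == 0) {
        code <<- code %/% openssl::bignum(p)
        e <- e + 1L
      }
      e
    }, integer(1))
  }
  expect_equal(recover(r3), c(6L, 1L, 4L))
  # Term1 (natural number 3) appears nowhere in R3's decoding, so a
  # positional-code query on Term1 cannot retrieve the transitive
  # Term4-under-Term1 relation ...
  expect_false(3L %in% recover(r3))
  # ... whereas the closure encoding carries it as plain divisibility
  pt <- make_worked_examples()
  expect_true(subsumes(modified_godel(pt$ontology, pt$assignment, "Term1"),
                       modified_godel(pt$ontology, pt$assignment, "Term4")))
})

test_that("subsumes is divisibility: ancestor-or-self true, siblings false", {
  pt <- make_worked_examples()
  o <- pt$ontology; pa <- pt$assignment
  c2 <- modified_godel(o, pa, "Term2")
  c3 <- modified_godel(o, pa, "Term3")
  c4 <- modified_godel(o, pa, "Term4")
  expect_true(subsumes(c2, c4))    # 42 mod 6 == 0
  expect_true(subsumes(c4, c4))    # self
  expect_false(subsumes(c3, c4))   # siblings
  expect_false(subsumes(c4, c2))   # antisymmetry direction
})

test_that("factorization fidelity: trial division recovers exactly the closure primes", {
  fx <- generate_fixture(fixture_spec(seed = 11, n_terms = 40,
                                      max_parents = 3, n_proteins = 2,
                                      n_interactions = 1))
  o <- fx$ontology
  pa <- assign_primes(o)
  codes <- encode_ontology(o, pa)
  for (id in sample(o$ids, 8)) {
    cd <- code_of(codes, id)
    expected <- sort(as.numeric(pa[c(id, ancestors(o, id))]))
    # divide out each expected prime exactly once; remainder must be 1
    v <- cd$value
    for (p in expected) {
      expect_true((v %% openssl::bignum(p)) == 0)
      v <- v %/% openssl::bignum(p)
    }
    expect_equal(as.character(v), "1")   # squarefree, nothing extra
    expect_equal(cd$factors, expected)
  }
})

test_that("subsumes is equivalent to graph reachability on random DAGs", {
  skip_if_not_installed("igraph")
  for (seed in 1:4) {
    fx <- generate_fixture(fixture_spec(seed = seed, n_terms = 50,
                                        max_parents = 3, n_proteins = 2,
                                        n_interactions = 1))
    o <- fx$ontology
    codes <- encode_ontology(o, assign_primes(o))
    pairs <- cbind(sample(o$ids, 50, replace = TRUE),
                   sample(o$ids, 50, replace = TRUE))
    for (r in seq_len(nrow(pairs))) {
      q <- pairs[r, 1]; t <- pairs[r, 2]
      reach <- q == t || q %in% igraph_ancestors(o, t)
      expect_identical(subsumes(code_of(codes, q), code_of(codes, t)),
                       reach)
    }
  }
})

test_that("single-prime shortcut: prime(q) | code(t) iff code(q) | code(t)", {
  fx <- generate_fixture(fixture_spec(seed = 3, n_terms = 60,
                                      max_parents = 3, n_proteins = 2,
                                      n_interactions = 1))
  o <- fx$ontology
  pa <- assign_primes(o)
  codes <- encode_ontology(o, pa)
  for (r in 1:60) {
    q <- sample(o$ids, 1); t <- sample(o$ids, 1)
    by_prime <- (code_of(codes, t)$value %%
                   openssl::bignum(as.numeric(pa[q]))) == 0
    by_code <- subsumes(code_of(codes, q), code_of(codes, t))
    expect_identical(by_prime, by_code)
  }
})

test_that("mutual subsumption implies equal codes (antisymmetry)", {
  fx <- generate_fixture(fixture_spec(seed = 7, n_terms = 40,
                                      max_parents = 2, n_proteins = 2,
                                      n_interactions = 1))
  o <- fx$ontology
  codes <- encode_ontology(o, assign_primes(o))
  for (r in 1:40) {
    q <- sample(o$ids, 1); t <- sample(o$ids, 1)
    a <- code_of(codes, q); b <- code_of(codes, t)
    if (subsumes(a, b) && subsumes(b, a)) {
      expect_true(a$value == b$value)
    }
  }
})

test_that("entity codes are the lcm of annotation codes", {
  pt <- make_worked_examples()
  o <- pt$ontology; pa <- pt$assignment
  c2 <- modified_godel(o, pa, "Term2")
  c3 <- modified_godel(o, pa, "Term3")
  c4 <- modified_godel(o, pa, "Term4")
  expect_equal(as.character(entity_code(list(c4))), "42")
  expect_equal(as.character(entity_code(list(c3, c4))), "210")
  expect_equal(as.character(entity_code(list(c2, c4))), "42")
  expect_error(entity_code(list()), "non-empty")
})

test_that("DDI arithmetic: the worked inference example and its negatives", {
  da <- godel_code(187, factors = c(11, 17))
  db <- godel_code(247, factors = c(13, 19))
  ddi <- godel_code(143, factors = c(11, 13))
  expect_true(infer_ppi_from_ddi(da, db, ddi))      # 46189 mod 143 == 0
  other <- godel_code(19 * 23, factors = c(19, 23)) # no shared domain pair
  expect_false(infer_ppi_from_ddi(da, other, ddi))
  expect_error(infer_ppi_from_ddi(da, db, godel_code(11, factors = 11)),
               "two distinct domain primes")
})

test_that("code tables are deterministic across independent runs", {
  fx <- generate_fixture(fixture_spec(seed = 5, n_terms = 30,
                                      max_parents = 2, n_proteins = 2,
                                      n_interactions = 1))
  run <- function() {
    codes <- encode_ontology(fx$ontology, assign_primes(fx$ontology))
    p <- tempfile()
    write_code_table(codes, p)
    readLines(p)
  }
  expect_identical(run(), run())
})
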