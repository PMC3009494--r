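#' Generate the first n prime numbers
#'
#' Sieve of Eratosthenes with the standard asymptotic upper bound
#' `n * (log n + log log n)` on the n-th prime; the sieve limit doubles
#' automatically in the (rare) case the bound falls short.
#'
#' @param n Number of primes to generate (positive integer).
#' @return Numeric vector of the first `n` primes in ascending order. Values
#'   are exact: even the 26,000th prime (300,023) is far below 2^53.
#' @examples
#' generate_primes(4)  # 2 3 5 7
#' @export
generate_primes <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1 || n != floor(n)) {
    stop("'n' must be a single integer >= 1")
  }
  n <- as.integer(n)
  limit <- if (n < 6L) 15L else ceiling(n * (log(n) + log(log(n)))) + 10L
  repeat {
    primes <- sieve_upto(limit)
    if (length(primes) >= n) return(primes[seq_len(n)])
    limit <- limit * 2L
  }
}

# plain Eratosthenes sieve: all primes <= limit
sieve_upto <- function(limit) {
  is_p <- rep(TRUE, limit)
  is_p[1L] <- FALSE
  p <- 2L
  while (p * p <= limit) {
    if (is_p[p]) is_p[seq.int(p * p, limit, by = p)] <- FALSE
    p <- p + 1L
  }
  as.numeric(which(is_p))
}

# exact product of a vector of small primes as an arbitrary-precision integer.
# Consecutive primes are first multiplied in double precision while the
# partial product stays below 2^52 (exact), cutting bignum calls ~3x.
prod_primes <- function(ps) {
  acc <- openssl::bignum(1L)
  if (!length(ps)) return(acc)
  cur <- 1
  for (p in ps) {
    if (cur * p < 2^52) {
      cur <- cur * p
    } else {
      acc <- acc * openssl::bignum(sprintf("%.0f", cur))
      cur <- p
    }
  }
  acc * openssl::bignum(sprintf("%.0f", cur))
}

# big-integer power by repeated squaring (exponent a small non-negative int)
bignum_pow <- function(base, a) {
  res <- openssl::bignum(1L)
  b <- base
  while (a > 0) {
    if (a %% 2 == 1) res <- res * b
    a <- a %/% 2
    if (a > 0) b <- b * b
  }
  res
}
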