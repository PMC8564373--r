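# Independent oracles, kept deliberately naive: direct enumeration and
# summation routes against which the package's closed forms and simulations
# are checked.

# Expected (draws - distinct)/draws by full enumeration of all b^n ordered
# tuples of draws (feasible for b <= 4, n <= 5).
brute_force_collision_rate <- function(probs, n) {
  b <- length(probs)
  tuples <- as.matrix(expand.grid(rep(list(seq_len(b)), n)))
  weight <- apply(tuples, 1, function(tp) prod(probs[tp]))
  distinct <- apply(tuples, 1, function(tp) length(unique(tp)))
  sum(weight * (n - distinct)) / n
}

# Entropy by direct summation over a frequency vector.
entropy_direct <- function(counts) {
  f <- counts / sum(counts)
  tot <- 0
  for (fi in f) if (fi > 0) tot <- tot - fi * log2(fi)
  tot
}

# E[animals] via the pmf of the maximum of L geometrics: P(A = a) =
# F(a)^L - F(a-1)^L with F(a) = 1 - (1-q)^a, summed term by term.
animals_mean_by_pmf <- function(L, q, tol = 1e-12) {
  total <- 0
  a <- 1
  repeat {
    pa <- (1 - (1 - q)^a)^L - (1 - (1 - q)^(a - 1))^L
    total <- total + a * pa
    if (a > 10 && (1 - (1 - (1 - q)^a)^L) < tol) break
    a <- a + 1
    if (a > 1e6) stop("oracle series failed to converge")
  }
  total
}

# Count of nonzero binary vectors of length n via the binomial route.
nonzero_vector_count <- function(n) sum(choose(n, seq_len(n)))
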