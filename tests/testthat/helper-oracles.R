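# Independent oracles used across tests. These never call the package's own
# code paths.

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration with
# binomial coefficients.
enum_fisher_p <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; k <- a + c
  if (n1 == 0 || n2 == 0) return(NA_real_)
  xs <- max(0, k - n2):min(k, n1)
  probs <- choose(n1, xs) * choose(n2, k - xs) / choose(n1 + n2, k)
  obs <- probs[xs == a]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# BH step-up by hand: q_(i) = min_{j >= i} p_(j) * m / j
bh_ref <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exact upper-tail binomial P(X >= k): direct term summation with exact
# binomial coefficients (exact integers up to n = 50).
binom_tail_ref <- function(k, n, p) {
  if (k > n) return(0)
  i <- k:n
  sum(choose(n, i) * p^i * (1 - p)^(n - i))
}

# Hypergeometric overlap upper tail P(|A ∩ B| >= ov) by complete subset
# enumeration (small universes only).
enum_overlap_p <- function(ov, size_a, size_b, universe_n) {
  A <- seq_len(size_a)
  combos <- utils::combn(universe_n, size_b)
  mean(colSums(combos <= size_a) >= ov)
}

# Naive O(n*m) 1 bp-overlap scan on 0-based half-open intervals
naive_overlap <- function(regions, track) {
  vapply(seq_len(nrow(regions)), function(i) {
    any(track$chrom == regions$chrom[i] &
          track$start < regions$end[i] &
          track$end > regions$start[i])
  }, logical(1))
}
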