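# Independent oracles. These re-derive expected results from first principles
# (exhaustive enumeration / direct definitions) and never call the code paths
# they check.

# Maximal-scoring-segment decomposition (Ruzzo-Tompa semantics) by direct
# recursive enumeration. For density d, site bp k scores value[k] - d and
# every gap bp scores -d; the decomposition repeatedly takes the
# highest-scoring site segment (exhaustive search over all O(n^2) segments;
# positive score required) and recurses on the left and right flanks.
mss_at_density <- function(pos, val, d) {
  csum <- c(0, cumsum(val))
  decompose <- function(lo, hi) {
    if (lo > hi) return(character(0))
    best <- c(-Inf, NA, NA)
    for (a in lo:hi) {
      b <- a:hi
      sc <- (csum[b + 1] - csum[a]) - d * (pos[b] - pos[a] + 1)
      k <- which.max(sc)
      if (sc[k] > best[1]) best <- c(sc[k], a, b[k])
    }
    if (best[1] <= 0) return(character(0))
    a <- best[2]; b <- best[3]
    c(decompose(lo, a - 1), paste0(pos[a], ":", pos[b]), decompose(b + 1, hi))
  }
  sort(decompose(1, length(pos)))
}

# hierarchy slice at density d, same key set
hierarchy_at_density <- function(hier, d) {
  hit <- hier[hier$min_density <= d & d < hier$max_density, , drop = FALSE]
  if (nrow(hit) == 0L) return(character(0))
  sort(paste0(hit$start, ":", hit$end))
}

# Fisher two-sided p by full enumeration of all tables with the observed
# margins, from the hypergeometric pmf written out explicitly.
fisher_p_enumeration <- function(a, b, c_, d) {
  m <- a + b; n2 <- c_ + d; k <- a + c_
  table_prob <- function(x) {
    # P(table) = C(m,x) C(n2,k-x) / C(m+n2,k)
    exp(lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k))
  }
  support <- max(0, k - n2):min(m, k)
  probs <- vapply(support, table_prob, numeric(1))
  p_obs <- table_prob(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Expected Shannon entropy (bits) of a symmetric Dirichlet(1,...,1) usage
# vector with k = 2, by numeric integration: p ~ Uniform(0,1).
dirichlet2_entropy_expectation <- function() {
  f <- function(p) ifelse(p <= 0 | p >= 1, 0,
                          -(p * log2(p) + (1 - p) * log2(1 - p)))
  stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
}
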