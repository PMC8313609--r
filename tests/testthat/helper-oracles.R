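# Independent brute-force oracles; deliberately naive implementations that
# share no code with the package internals.

oracleJaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

# Upper tail by direct summation of binomial-coefficient terms.
oracleHypergeomTail <- function(k, n, K, N) {
  js <- k:min(n, K)
  if (k > min(n, K)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# BH step-up evaluated literally: q_(i) = min_{j >= i} m p_(j) / j on the
# sorted p-values, mapped back to input order.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Rand index by an explicit double loop over item pairs.
oracleRand <- function(l1, l2) {
  n <- length(l1)
  agree <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same1 <- l1[i] == l1[j]
      same2 <- l2[i] == l2[j]
      if (same1 == same2) agree <- agree + 1
    }
  }
  agree / choose(n, 2)
}

randomLabels <- function(n, k) sample(seq_len(k), n, replace = TRUE)

# Small planted study used across modules: 36 diseases in subgroups of
# 8/11/11/6 over disjoint cluster pools.
plantedSpec <- function(seed, coreFraction = 1, sharedFraction = 0, ...) {
  syntheticSpec(coreFraction = coreFraction, sharedFraction = sharedFraction,
                seed = seed, ...)
}

# Build the standard benchmark annotation themes: one ubiquitous theme on
# the shared pool plus one private theme per cluster.
benchmarkThemes <- function(nClusters = 4, nSets = 5, setSize = 40) {
  data.frame(
    theme = c("ubiquitous", sprintf("private%d", seq_len(nClusters))),
    pool = c("shared", sprintf("cluster%d", seq_len(nClusters))),
    nSets = nSets, setSize = setSize, stringsAsFactors = FALSE)
}

quietly <- function(expr) suppressMessages(expr)
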