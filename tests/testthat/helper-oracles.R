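# Independent brute-force oracles for the combinatorics and the
# information-theoretic measures. These deliberately avoid the package's
# code paths: the substructure relation is materialized as an explicit
# pairwise matrix (dot-product characterization), entropies are computed
# from full joint contingency tables in natural log, and monotonicity is
# checked by counting violating pairs.

# S[i, j] == TRUE iff structure i - 1 is a substructure of structure j - 1:
# containment of true-sets, via dot(i, j) == |true(i)|
oracle_submatrix <- function(n) {
  B <- all_structures(n) * 1L
  (B %*% t(B)) == matrix(rowSums(B), nrow(B), nrow(B))
}

.plogp <- function(p) ifelse(p > 0, p * log(p), 0)

# H(q) - H(q | y) ratio degree from the joint table of (q, y), natural log
oracle_degree <- function(q, y) {
  tab <- table(factor(q, levels = c(FALSE, TRUE)), y)
  p <- tab / sum(tab)
  pq <- rowSums(p)
  hq <- -sum(.plogp(pq))
  if (hq == 0) return(1)
  py <- colSums(p)
  hqy <- -sum(.plogp(p)) - (-sum(.plogp(py)))
  1 - hqy / hq
}

oracle_up_degree <- function(q) {
  n <- as.integer(round(log2(length(q))))
  S <- oracle_submatrix(n)
  y <- as.vector(t(S) %*% q) > 0   # has a true substructure (incl. self)
  oracle_degree(q, y)
}

oracle_down_degree <- function(q) {
  n <- as.integer(round(log2(length(q))))
  S <- oracle_submatrix(n)
  y <- as.vector(S %*% q) > 0      # has a true superstructure (incl. self)
  oracle_degree(q, y)
}

oracle_mon_degree <- function(q) {
  q <- as.logical(q)
  max(oracle_up_degree(q), oracle_down_degree(q),
      oracle_up_degree(!q), oracle_down_degree(!q))
}

oracle_qua_degree <- function(q) {
  n <- as.integer(round(log2(length(q))))
  oracle_degree(as.logical(q), rowSums(all_structures(n)))
}

# binary monotonicity by counting violating comparable pairs
oracle_is_monotone <- function(q, direction) {
  n <- as.integer(round(log2(length(q))))
  S <- oracle_submatrix(n)
  q <- as.logical(q)
  if (direction == "up") {
    # violation: i substructure of j, q true at i, false at j
    viol <- sum(S[q, !q, drop = FALSE])
  } else {
    viol <- sum(S[!q, q, drop = FALSE])
  }
  viol == 0
}

oracle_is_quantitative <- function(q) {
  n <- as.integer(round(log2(length(q))))
  cnt <- rowSums(all_structures(n))
  all(vapply(split(as.logical(q), cnt), function(v) {
    length(unique(v)) == 1L
  }, logical(1)))
}

# uniformly random truth table under the current RNG
random_table <- function(n) runif(2^n) < 0.5
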