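# Independent brute-force oracles. These deliberately avoid the package's
# computational paths: diversity statistics by literal all-pairs loops,
# the selection recursion by term-by-term genotype enumeration, integrals by
# fine-grid Riemann sums.

# expected next-generation frequency by literal enumeration of the k+1
# genotype classes, indexed (as an independent check) by ancestral count i
oracle_expected_frequency <- function(p, k, s, H) {
  tau <- 10^(-H)
  num <- 0; den <- 0
  for (i in 0:k) {            # i ancestral copies, d = k - i derived
    d <- k - i
    h_d <- if (d == 0) 0 else if (d == k) 1 else (d / k)^tau
    w <- choose(k, i) * p^(k - i) * (1 - p)^i
    num <- num + w * ((k - i) / k) * (1 + h_d * s)
    den <- den + w * (1 + h_d * s)
  }
  num / den
}

# per-window pi by looping over every haplotype pair and every site
oracle_pi <- function(mat, positions, start, end) {
  m <- nrow(mat)
  tot <- 0
  for (a in 1:(m - 1)) for (b in (a + 1):m) {
    for (j in seq_len(ncol(mat))) {
      if (positions[j] >= start && positions[j] < end) {
        tot <- tot + (mat[a, j] != mat[b, j])
      }
    }
  }
  tot / choose(m, 2) / (end - start)
}

oracle_S <- function(mat, positions, start, end) {
  n <- nrow(mat)
  S <- 0
  for (j in seq_len(ncol(mat))) {
    if (positions[j] >= start && positions[j] < end) {
      c1 <- sum(mat[, j])
      if (c1 > 0 && c1 < n) S <- S + 1
    }
  }
  S
}

oracle_tajima_d <- function(mat, positions, start, end) {
  n <- nrow(mat)
  S <- oracle_S(mat, positions, start, end)
  if (S == 0) return(NA_real_)
  pi_sum <- oracle_pi(mat, positions, start, end) * (end - start)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi_sum - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# fine-grid Riemann midpoint integral of a piecewise-linear profile
oracle_auc <- function(positions, values, lo, hi, n_grid = 2e5) {
  h <- (hi - lo) / n_grid
  xs <- lo + (seq_len(n_grid) - 0.5) * h
  ys <- approx(positions, values, xs)$y
  sum(ys) * h
}

# deterministic toy haplotype matrix for round-trip and statistics tests
toy_matrix <- function(mat, positions, n1 = nrow(mat), n2 = 0, k = 2,
                       L = 1000) {
  polysweep:::new_hap_matrix(mat, positions, n1, n2, k, L)
}

# random toy matrix: every column segregating
random_matrix <- function(n_hap, n_site, L = 1000) {
  mat <- matrix(0L, n_hap, n_site)
  for (j in seq_len(n_site)) {
    c1 <- sample(1:(n_hap - 1), 1)
    mat[sample(n_hap, c1), j] <- 1L
  }
  toy_matrix(mat, sort(runif(n_site, 0, L)), L = L)
}
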