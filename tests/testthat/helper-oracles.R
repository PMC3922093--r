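# Independent oracles used across tests. These deliberately avoid the code
# paths they check: brute-force formulas and exhaustive enumeration only.

# BH step-up by direct evaluation of q_i = min_{j: p_(j) >= p_(i)} m p_(j) / j
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- which(p[ord] >= p[i] - 1e-15)
    q[i] <- min(1, min(m * p[ord][js] / js))
  }
  q
}

# upper-tail hypergeometric by the explicit combinatorial sum
hyper_tail_sum <- function(a, K, n, N) {
  ks <- a:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# upper-tail hypergeometric by exhaustive enumeration of all C(N, n) draws
hyper_tail_enum <- function(a, K, n, N) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= a)   # items 1..K are the term members
}

# exact two-sided Mann-Whitney p by enumeration over all label assignments
mw_enum <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  idx <- utils::combn(n, n1)
  us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# small planted two-class matrix for classifier/selection tests
planted_matrix <- function(n_features = 20, n_planted = 5, delta = 6,
                           noise_sd = 0.5, seed = 2) {
  set.seed(seed)
  x <- matrix(rnorm(n_features * 45, 0, noise_sd), n_features, 45,
              dimnames = list(sprintf("f%02d", seq_len(n_features)),
                              paste0("s", 1:45)))
  lab <- rep(c("non_recurrent", "metastatic"), c(33, 12))
  x[seq_len(n_planted), lab == "metastatic"] <-
    x[seq_len(n_planted), lab == "metastatic"] - delta
  list(x = x, labels = lab, planted = rownames(x)[seq_len(n_planted)])
}
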