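# fixtures built in code: small labelled graphs and random generators

# symmetric zero-diagonal matrix from an upper-triangle weight vector
sym_matrix <- function(w_upper, labels) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- w_upper
  m + t(m)
}

# random signed graph with weights uniform in [wmin, wmax]
rand_signed_graph <- function(n, seed, wmin = -1, wmax = 1) {
  set.seed(seed)
  labels <- sprintf("v%02d", seq_len(n))
  w <- sym_matrix(runif(n * (n - 1) / 2, wmin, wmax), labels)
  signed_difference_graph(w)
}

# random non-negative network
rand_network <- function(n, seed, kind = "generic") {
  set.seed(seed)
  labels <- sprintf("v%02d", seq_len(n))
  weighted_network(sym_matrix(runif(n * (n - 1) / 2), labels), kind = kind)
}

# unit triangle a-b-c
unit_triangle <- function(labels = c("a", "b", "c")) {
  signed_difference_graph(sym_matrix(c(1, 1, 1), labels))
}

# independent two-sided MW p by explicit bitmask enumeration (test oracle,
# distinct from the package's subset-count DP)
mw_enum_p <- function(x, y) {
  n <- length(x); m <- length(y); nn <- n + m
  r <- rank(c(x, y))
  center <- n * (nn + 1) / 2
  obs <- abs(sum(r[seq_len(n)]) - center)
  subsets <- utils::combn(nn, n)
  devs <- abs(colSums(matrix(r[subsets], nrow = n)) - center)
  mean(devs >= obs - 1e-9)
}

# closed-form one-sided hypergeometric tail P(X >= k) via choose()
hyper_tail <- function(k, K, n, N) {
  kk <- seq(max(k, max(0, n + K - N)), min(K, n))
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
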