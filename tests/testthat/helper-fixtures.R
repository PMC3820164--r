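# Shared fixtures and independent oracles used across test files.

# small named expression matrix from a numeric matrix (default all tumor)
make_expr <- function(values, n_normal = 0) {
  rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  cls <- rep("tumor", ncol(values))
  if (n_normal > 0) {
    cls[seq(ncol(values) - n_normal + 1, ncol(values))] <- "normal"
  }
  expression_matrix(values, cls)
}

# brute-force evaluation of the subtype-specificity statistics for one
# vector of group means (independent of the package implementation)
fc_oracle <- function(mu, k) {
  others <- mu[-k]
  delta <- min(abs(mu[k] - min(others)), abs(mu[k] - max(others)))
  delta_prime <- abs(max(others) - min(others))
  dir <- "none"
  if (all(mu[k] > others)) dir <- "up"
  if (all(mu[k] < others)) dir <- "down"
  list(delta_k = delta, delta_prime_k = delta_prime,
       fc_k = delta - delta_prime, direction = dir)
}

# independent step-up BH implementation
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

# adjusted Rand index between two label vectors (contingency-table form)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_i * sum_j / n
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

# planted two-group fixture: first `n_shift` genes shifted by `delta` in
# group 1; returns expr + labels for detect/moderated tests
make_two_group <- function(n_genes = 60, n1 = 10, n2 = 10, n_shift = 5,
                           delta = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * (n1 + n2)), n_genes, n1 + n2)
  m[seq_len(n_shift), seq_len(n1)] <- m[seq_len(n_shift), seq_len(n1)] + delta
  expr <- make_expr(m)
  labels <- tibble::tibble(
    sample = sample_ids(expr),
    subtype = rep(c(1L, 2L), c(n1, n2)))
  list(expr = expr, labels = labels)
}
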