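# Independent oracles: deliberately avoid the code paths they check.

# Spearman via explicit sum-formula Pearson on average ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  n <- length(x)
  num <- n * sum(rx * ry) - sum(rx) * sum(ry)
  den <- sqrt((n * sum(rx^2) - sum(rx)^2) * (n * sum(ry^2) - sum(ry)^2))
  num / den
}

# Pearson via the same sum formula on raw values.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# Pair-by-pair brute-force correlation vector in canonical (i, j), i < j order.
oracle_cor_vector <- function(expr, genes) {
  out <- numeric(0)
  for (i in seq_along(genes)[-length(genes)]) {
    for (j in (i + 1L):length(genes)) {
      out <- c(out, oracle_spearman(expr[genes[i], ], expr[genes[j], ]))
    }
  }
  out
}

# Euclidean distance by explicit accumulation.
oracle_euclid <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  sqrt(s)
}

# Two-condition dataset: group a simulated under condition_a, group b under
# condition_b, shared defaults otherwise; unique sample ids, labels "a"/"b".
make_two_group <- function(n_a, n_b, condition_a = "normal",
                           condition_b = "normal", seed = 1L, ...) {
  seeds <- clockccd:::child_seeds(seed, 2L)
  da <- simulate_clock(sim_config(n_samples = n_a, condition = condition_a,
                                  seed = seeds[1L], ...))
  db <- simulate_clock(sim_config(n_samples = n_b, condition = condition_b,
                                  seed = seeds[2L], ...))
  expr <- cbind(da$expr, db$expr)
  colnames(expr) <- sprintf("s%03d", seq_len(n_a + n_b))
  list(expr = expr, labels = rep(c("a", "b"), c(n_a, n_b)))
}

# One population split into two arbitrary groups of fixed sizes (true null).
make_null_two_group <- function(n_a, n_b, seed = 1L, ...) {
  d <- simulate_clock(sim_config(n_samples = n_a + n_b, seed = seed, ...))
  list(expr = d$expr, labels = rep(c("a", "b"), c(n_a, n_b)))
}
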