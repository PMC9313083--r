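# Independent oracles used to cross-check the package implementations.
# These deliberately use direct/brute-force formulations, not the code paths
# they verify.

# Welch t by direct textbook formula
oracle_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, p = 2 * pt(abs(t), df, lower.tail = FALSE), df = df)
}

# Step-up BH evaluated rank by rank
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Mean local clustering coefficient by explicit triangle enumeration
oracle_cc <- function(A) {
  A <- (A != 0) * 1
  diag(A) <- 0
  n <- nrow(A)
  vals <- c()
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (A[nb[a], nb[b]] == 1) tri <- tri + 1
      }
    }
    vals <- c(vals, 2 * tri / (k * (k - 1)))
  }
  if (!length(vals)) 0 else mean(vals)
}

# Hypergeometric upper tail by exact enumeration of the pmf
oracle_hyper_upper <- function(k, K, n, N) {
  js <- max(k, max(0, n - (N - K))):min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Two-group log-rank O/E/V sums evaluated time point by time point
oracle_logrank <- function(ta, ea, tb, eb) {
  time <- c(ta, tb); event <- c(ea, eb)
  grp <- rep(c("A", "B"), c(length(ta), length(tb)))
  o_sum <- 0; e_sum <- 0; v_sum <- 0
  for (t0 in sort(unique(time[event == 1]))) {
    at_risk <- time >= t0
    n_t <- sum(at_risk); n_a <- sum(at_risk & grp == "A")
    d_t <- sum(time == t0 & event == 1)
    d_a <- sum(time == t0 & event == 1 & grp == "A")
    o_sum <- o_sum + d_a
    e_sum <- e_sum + d_t * n_a / n_t
    if (n_t > 1) {
      v_sum <- v_sum + d_t * (n_a / n_t) * (1 - n_a / n_t) *
        (n_t - d_t) / (n_t - 1)
    }
  }
  chi2 <- if (v_sum > 0) (o_sum - e_sum)^2 / v_sum else 0
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# Random simple undirected adjacency matrix
random_adjacency <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}

# Adjusted Rand index between two labelings (contingency-table formula)
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# Small expression dataset with exact values for IO tests
toy_dataset <- function() {
  m <- matrix(c(1.5, 2.5, 3.5,
                2.0, 3.0, 4.0,
                8.0, 7.0, 6.0,
                9.0, 8.5, 7.5), nrow = 3,
              dimnames = list(c("gA", "gB", "gC"),
                              c("s1", "s2", "s3", "s4")))
  expression_dataset(m, c("control", "control", "case", "case"), "toy", "LC")
}

# Two-module, zero-noise dataset: orthogonal latent patterns give exact
# within-module |r| = 1 and between-module r = 0.
two_module_dataset <- function(n_per_module = 10, n_samples = 8) {
  stopifnot(n_samples %% 4 == 0)
  lat1 <- rep(c(1, -1), n_samples / 2)
  lat2 <- rep(c(1, 1, -1, -1), n_samples / 4)
  vals <- rbind(
    t(sapply(seq_len(n_per_module), function(i) (0.5 + i / 10) * lat1 + i)),
    t(sapply(seq_len(n_per_module), function(i) (0.5 + i / 10) * lat2 - i))
  )
  rownames(vals) <- c(paste0("m1_", seq_len(n_per_module)),
                      paste0("m2_", seq_len(n_per_module)))
  colnames(vals) <- paste0("s", seq_len(n_samples))
  cls <- rep(c("control", "case"), each = n_samples / 2)
  expression_dataset(vals, cls, "planted", "LC")
}

# Build a coexpression network directly from a hand-specified edge list
network_from_edges <- function(nodes, edges) {
  S <- matrix(0.1, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (e in edges) S[e[1], e[2]] <- S[e[2], e[1]] <- 0.9
  diag(S) <- 1
  build_network(S, 0.5)
}
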