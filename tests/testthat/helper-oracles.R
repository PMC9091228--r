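# Brute-force / closed-form oracles, kept deliberately independent of the
# vectorized implementations they check.

# population variance and mean of log-ratios by explicit loops
oracle_log_ratio_stats <- function(v) {
  S <- nrow(v); D <- ncol(v)
  tmat <- matrix(0, D, D); mu <- matrix(0, D, D)
  for (i in seq_len(D)) for (j in seq_len(D)) {
    lr <- numeric(S)
    for (k in seq_len(S)) lr[k] <- log(v[k, i] / v[k, j])
    mu[i, j] <- sum(lr) / S
    tmat[i, j] <- sum((lr - mu[i, j])^2) / S
  }
  list(t = tmat, mu = mu)
}

# basis variances by an explicit summation loop over the t matrix
oracle_basis_variances <- function(tmat) {
  D <- nrow(tmat)
  a <- 2 * D - 3
  b <- 1 / (2 * (D - 1) * (D - 2))
  total <- 0
  for (i in seq_len(D)) for (j in seq_len(D)) total <- total + tmat[i, j]
  omega <- numeric(D)
  for (i in seq_len(D)) {
    rs <- 0
    for (j in seq_len(D)) rs <- rs + tmat[i, j]
    omega[i] <- b * (a + 1) * rs - b * total
  }
  omega
}

# scalar evaluation of one per-sample correlation summand from the raw
# relative-abundance table
oracle_rho_k <- function(v, i, j, k) {
  S <- nrow(v); D <- ncol(v)
  a <- 2 * D - 3
  b <- 1 / (2 * (D - 1) * (D - 2))
  lr <- function(p, q, s) log(v[s, p] / v[s, q])
  mu <- function(p, q) mean(sapply(seq_len(S), function(s) lr(p, q, s)))
  dev2 <- function(p, q) (lr(p, q, k) - mu(p, q))^2
  tmat <- matrix(0, D, D)
  for (p in seq_len(D)) for (q in seq_len(D)) {
    lrs <- sapply(seq_len(S), function(s) lr(p, q, s))
    tmat[p, q] <- mean((lrs - mean(lrs))^2)
  }
  omega2 <- oracle_basis_variances(tmat)
  Ri <- sum(sapply(seq_len(D), function(q) dev2(i, q)))
  Rj <- sum(sapply(seq_len(D), function(p) dev2(p, j)))
  tot <- sum(sapply(seq_len(D), function(p)
    sum(sapply(seq_len(D), function(q) dev2(p, q)))))
  (b * (a + 1) * Ri + b * (a + 1) * Rj - 2 * b * tot - dev2(i, j)) /
    (2 * S * sqrt(omega2[i]) * sqrt(omega2[j]))
}

# AUC by exhaustive concordant-pair counting with half-credit for ties
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# OLS slope/intercept from the normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# exact mean fragility curve of a graph by enumerating all removal orders
oracle_robustness_exhaustive <- function(nodes, edges) {
  N <- length(nodes)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  all_orders <- perms(nodes)
  sig <- matrix(0, length(all_orders), N)
  for (o in seq_along(all_orders)) {
    ord <- all_orders[[o]]
    for (i in seq_len(N)) {
      remaining <- setdiff(nodes, ord[seq_len(i)])
      sig[o, i] <- if (length(remaining) == 0) 0 else
        max(igraph::components(
          igraph::induced_subgraph(g, remaining))$csize) / N
    }
  }
  colMeans(sig)
}

# all permutations of 1..n as an n! x n matrix
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    block <- cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
    out <- rbind(out, block)
  }
  out
}

# --- shared fixtures -------------------------------------------------------

complete_network <- function(N) {
  nodes <- paste0("n", seq_len(N))
  e <- t(utils::combn(nodes, 2))
  micro_network(nodes, data.frame(node_i = e[, 1], node_j = e[, 2],
                                  stringsAsFactors = FALSE))
}

star_network <- function(N) {
  nodes <- paste0("n", seq_len(N))
  micro_network(nodes, data.frame(node_i = nodes[1], node_j = nodes[-1],
                                  stringsAsFactors = FALSE))
}

toy_relative_table <- function(S, D, seed = 1) {
  set.seed(seed)
  v <- matrix(stats::rgamma(S * D, shape = 2), S, D)
  abundance_table(v / rowSums(v), kind = "relative")
}
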