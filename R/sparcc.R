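#' Log-ratio variance statistics
#'
#' For every ordered taxon pair (i, j) computes the mean and the population
#' variance (dividing by the sample count S, not S - 1) of the per-sample
#' log-ratios log(x_i / x_j). These are the sufficient statistics of the
#' SparCC estimator: the variance matrix `t` measures how tightly two taxa
#' co-vary on the log scale regardless of the compositional constraint,
#' and the mean matrix `mu` centres the per-sample contributions used by
#' [sparcc_decompose()].
#'
#' The population normalization is deliberate: the per-sample decomposition
#' carries an explicit 1/S prefactor, and only the population variance makes
#' the sum of per-sample correlations reproduce the cohort correlation
#' exactly.
#'
#' @param tab an [abundance_table()] with `kind = "relative"` and strictly
#'   positive entries (apply [to_relative()] with a pseudocount first).
#' @return A list of class `log_ratio_stats` with elements `t` (D x D
#'   variance matrix, zero diagonal), `mu` (D x D antisymmetric mean
#'   matrix), `clr` (S x D matrix of centred log abundances, kept for the
#'   decomposition), `S` and `D`.
#' @export
log_ratio_stats <- function(tab) {
  stopifnot(inherits(tab, "abundance_table"))
  if (tab$kind != "relative")
    stop("log_ratio_stats expects a relative abundance table; run to_relative() first")
  v <- tab$values
  if (any(v <= 0))
    stop("zero or negative abundances: apply to_relative() with a pseudocount")
  S <- nrow(v); D <- ncol(v)
  Y <- log(v)
  m <- colMeans(Y)
  Z <- sweep(Y, 2L, m)             # centred logs; z_ki - z_kj = y_ij^(k) - mu_ij
  q <- colSums(Z^2)
  G <- crossprod(Z)
  tmat <- (outer(q, q, "+") - 2 * G) / S
  tmat[tmat < 0] <- 0              # numerical dust from cancellation
  diag(tmat) <- 0
  mu <- outer(m, m, "-")
  dimnames(tmat) <- dimnames(mu) <- list(colnames(v), colnames(v))
  structure(list(t = tmat, mu = mu, clr = Z, S = S, D = D),
            class = "log_ratio_stats")
}

#' Basis variances from log-ratio variances
#'
#' Solves for the variances of the latent (absolute, "basis") log
#' abundances under the sparsity assumption that the average pairwise
#' basis correlation is negligible. With a = 2D - 3 and
#' b = 1 / (2 (D - 1)(D - 2)), the closed form is
#' `omega_i^2 = b (a + 1) * rowsum_i(t) - b * totalsum(t)`.
#' Negative estimates (possible when the sparsity assumption is badly
#' violated) are floored at a small positive epsilon with a warning.
#'
#' @param stats a [log_ratio_stats()] object.
#' @param eps floor for non-positive variance estimates.
#' @return A list of class `basis_variances` with `omega_sq` (length-D
#'   vector), constants `a`, `b`, and `n_floored`.
#' @export
basis_variances <- function(stats, eps = 1e-12) {
  stopifnot(inherits(stats, "log_ratio_stats"))
  D <- stats$D
  if (D < 4L)
    stop("basis variance estimation needs D >= 4 taxa ",
         "(a = 2D - 3 and b = 1/(2(D-1)(D-2)) require more pairs than unknowns)")
  a <- 2 * D - 3
  b <- 1 / (2 * (D - 1) * (D - 2))
  omega_sq <- b * (a + 1) * rowSums(stats$t) - b * sum(stats$t)
  n_floored <- sum(omega_sq <= 0)
  if (n_floored > 0) {
    warning(n_floored, " basis variance estimate(s) were non-positive; ",
            "floored at ", eps)
    omega_sq[omega_sq <= 0] <- eps
  }
  names(omega_sq) <- rownames(stats$t)
  structure(list(omega_sq = omega_sq, a = a, b = b, n_floored = n_floored),
            class = "basis_variances")
}

#' SparCC correlation estimate
#'
#' One-pass closed-form SparCC: estimates the correlation of latent basis
#' abundances from a compositional table by inverting
#' `t_ij = omega_i^2 + omega_j^2 - 2 rho_ij omega_i omega_j`
#' with basis variances obtained from [basis_variances()]. The iterative
#' strong-pair-exclusion refinement of the original SparCC is deliberately
#' not applied; the analytic one-pass solution is the estimator this
#' package decomposes per sample.
#'
#' Count tables (or relative tables containing zeros) are converted with
#' [to_relative()] using `pseudocount` first.
#'
#' @param tab an [abundance_table()].
#' @param pseudocount forwarded to [to_relative()] when the table is not
#'   already strictly positive relative abundances.
#' @return An object of class `sparcc_fit`: `rho` (clipped to [-1, 1],
#'   unit diagonal), `rho_raw` (unclipped, used by the per-sample
#'   decomposition so the summation identity holds), `omega_sq`, `stats`,
#'   `taxon_ids`.
#' @examples
#' mod <- basis_model(10, seed = 1)
#' tab <- simulate_counts(mod, S = 50, depth = 1000)
#' fit <- sparcc(tab)
#' fit$rho[1:3, 1:3]
#' @export
sparcc <- function(tab, pseudocount = 0.5) {
  stopifnot(inherits(tab, "abundance_table"))
  if (tab$kind != "relative" || any(tab$values <= 0))
    tab <- to_relative(tab, pseudocount = pseudocount)
  stats <- log_ratio_stats(tab)
  bv <- basis_variances(stats)
  omega <- sqrt(bv$omega_sq)
  rho_raw <- (outer(bv$omega_sq, bv$omega_sq, "+") - stats$t) /
    (2 * outer(omega, omega))
  rho <- pmin(pmax(rho_raw, -1), 1)
  diag(rho) <- 1
  dimnames(rho) <- dimnames(rho_raw) <- dimnames(stats$t)
  structure(list(rho = rho, rho_raw = rho_raw, omega_sq = bv$omega_sq,
                 a = bv$a, b = bv$b, stats = stats,
                 taxon_ids = colnames(tab$values)),
            class = "sparcc_fit")
}

#' @export
print.sparcc_fit <- function(x, ...) {
  off <- x$rho[upper.tri(x$rho)]
  cat(sprintf("sparcc_fit: %d taxa, %d samples\n", length(x$taxon_ids), x$stats$S))
  cat(sprintf("  off-diagonal rho: median %.3f, range [%.3f, %.3f]\n",
              stats::median(off), min(off), max(off)))
  invisible(x)
}
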