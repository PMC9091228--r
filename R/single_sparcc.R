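#' Decompose a SparCC correlation into per-sample contributions
#'
#' The closed-form SparCC correlation is a sum over samples: with centred
#' log abundances z, squared centred log-ratio deviations
#' d_ij^(k) = (z_i^(k) - z_j^(k))^2, their per-sample row sums R_i^(k) and
#' total Tot^(k), each pair's correlation decomposes as
#'
#'   rho_ij^(k) = (b (a+1) (R_i^(k) + R_j^(k)) - 2 b Tot^(k) - d_ij^(k)) /
#'                (2 S omega_i omega_j)
#'
#' so that sum_k rho_ij^(k) equals the (unclipped) cohort estimate exactly.
#' Sample k's slice measures how much that one individual contributes to
#' each pairwise association, turning a population-level correlation method
#' into one network per person. The cohort means and basis variances are
#' estimated once from all S samples, including sample k — no leave-one-out
#' reference set is used.
#'
#' Clipped correlations are not propagated into the tensor: the slices sum
#' to the raw estimate, which is what makes the decomposition an identity.
#'
#' @param tab an [abundance_table()].
#' @param pseudocount forwarded to [sparcc()].
#' @return An object of class `sparcc_tensor`: `rho_k` (S x D x D array),
#'   `fit` (the underlying [sparcc()] fit), `sample_ids`, `taxon_ids`.
#' @export
sparcc_decompose <- function(tab, pseudocount = 0.5) {
  stopifnot(inherits(tab, "abundance_table"))
  if (n_samples(tab) < 2L)
    stop("per-sample decomposition needs S >= 2 samples")
  fit <- sparcc(tab, pseudocount = pseudocount)
  Z <- fit$stats$clr
  S <- nrow(Z); D <- ncol(Z)
  a <- fit$a; b <- fit$b
  omega <- sqrt(fit$omega_sq)
  denom <- 2 * S * outer(omega, omega)
  s_k <- rowSums(Z)
  u_k <- rowSums(Z^2)
  rho_k <- array(NA_real_, dim = c(S, D, D),
                 dimnames = list(rownames(Z), colnames(Z), colnames(Z)))
  for (k in seq_len(S)) {
    z <- Z[k, ]
    d <- outer(z, z, "-")^2
    R <- D * z^2 - 2 * z * s_k[k] + u_k[k]      # row sums of d
    tot <- 2 * D * u_k[k] - 2 * s_k[k]^2        # total sum of d
    rho_k[k, , ] <- (b * (a + 1) * outer(R, R, "+") - 2 * b * tot - d) / denom
  }
  structure(list(rho_k = rho_k, fit = fit,
                 sample_ids = rownames(Z), taxon_ids = colnames(Z)),
            class = "sparcc_tensor")
}

#' @export
print.sparcc_tensor <- function(x, ...) {
  d <- dim(x$rho_k)
  cat(sprintf("sparcc_tensor: %d samples x %d x %d taxa\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Magnitude threshold targeting a median network density
#'
#' Selects the edge threshold tau such that the median, across samples, of
#' the fraction of taxon pairs with |rho^(k)| >= tau equals the target
#' density. A single tau shared by all samples keeps edge counts comparable
#' across individuals while remaining reportable.
#'
#' @param tensor a [sparcc_decompose()] result.
#' @param density target fraction of candidate pairs retained per network
#'   (default 0.1).
#' @return Scalar threshold tau.
#' @export
ssn_threshold <- function(tensor, density = 0.1) {
  stopifnot(inherits(tensor, "sparcc_tensor"))
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  D <- length(tensor$taxon_ids)
  ut <- upper.tri(matrix(0, D, D))
  per_sample <- apply(tensor$rho_k, 1L, function(sl)
    stats::quantile(abs(sl[ut]), probs = 1 - density, names = FALSE))
  stats::median(per_sample)
}

#' Build a single-sample network
#'
#' Extracts one individual's network from the per-sample correlation
#' tensor. Pairs are retained either by magnitude (`|rho^(k)| >= tau`) or
#' as the top-q fraction by magnitude (`top_q`), with deterministic
#' lexicographic tie-breaking. When neither rule is given, tau defaults to
#' [ssn_threshold()] at 10% median density.
#'
#' @param tensor a [sparcc_decompose()] result.
#' @param k sample index or sample id.
#' @param tau magnitude threshold (>= 0), or `NULL`.
#' @param top_q fraction in (0, 1] of pairs to keep by magnitude, or
#'   `NULL`.
#' @param density fallback density for the default threshold.
#' @return An object of class `ssn`: `sample_id`, `taxa`, `edges` (a
#'   data.frame with columns taxon_i, taxon_j, weight, sign), `edge_count`,
#'   `mean_degree` (2 E / D), and the rule applied.
#' @export
build_ssn <- function(tensor, k, tau = NULL, top_q = NULL, density = 0.1) {
  stopifnot(inherits(tensor, "sparcc_tensor"))
  if (is.character(k)) k <- match(k, tensor$sample_ids)
  if (is.na(k) || k < 1L || k > length(tensor$sample_ids))
    stop("invalid sample index")
  if (!is.null(tau) && !is.null(top_q))
    stop("give either tau or top_q, not both")
  sl <- tensor$rho_k[k, , ]
  D <- ncol(sl)
  idx <- which(upper.tri(sl), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]  # lexicographic
  w <- sl[idx]
  if (!is.null(top_q)) {
    if (top_q <= 0 || top_q > 1) stop("top_q must be in (0, 1]")
    n_keep <- ceiling(top_q * length(w))
    ord <- order(-abs(w), idx[, 1L], idx[, 2L])
    keep <- logical(length(w)); keep[ord[seq_len(n_keep)]] <- TRUE
    rule <- list(type = "top_q", top_q = top_q)
  } else {
    if (is.null(tau)) tau <- ssn_threshold(tensor, density)
    if (tau < 0) stop("tau must be >= 0")
    keep <- abs(w) >= tau
    rule <- list(type = "magnitude", tau = tau)
  }
  taxa <- tensor$taxon_ids
  edges <- data.frame(taxon_i = taxa[idx[keep, 1L]],
                      taxon_j = taxa[idx[keep, 2L]],
                      weight = w[keep],
                      sign = ifelse(w[keep] >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  structure(list(sample_id = tensor$sample_ids[k], taxa = taxa,
                 edges = edges, edge_count = nrow(edges),
                 mean_degree = 2 * nrow(edges) / D, rule = rule),
            class = "ssn")
}

#' Build one network per individual
#'
#' @inheritParams build_ssn
#' @param ... forwarded to [build_ssn()].
#' @return A named list of [build_ssn()] networks, one per sample.
#' @export
build_ssn_all <- function(tensor, tau = NULL, top_q = NULL, density = 0.1, ...) {
  if (is.null(tau) && is.null(top_q))
    tau <- ssn_threshold(tensor, density)   # one shared threshold
  out <- lapply(seq_along(tensor$sample_ids), function(k)
    build_ssn(tensor, k, tau = tau, top_q = top_q, ...))
  names(out) <- tensor$sample_ids
  out
}

#' Network attributes of a single-sample network
#'
#' @param net an `ssn`.
#' @return A list with `edge_count` and `mean_degree`.
#' @export
ssn_attributes <- function(net) {
  stopifnot(inherits(net, "ssn"))
  list(edge_count = net$edge_count, mean_degree = net$mean_degree)
}

#' @export
print.ssn <- function(x, ...) {
  cat(sprintf("ssn '%s': %d taxa, %d edges (mean degree %.2f)\n",
              x$sample_id, length(x$taxa), x$edge_count, x$mean_degree))
  invisible(x)
}

#' Convert a network object to igraph
#' @param net an `ssn` or `micro_network`.
#' @return An undirected igraph graph with a `weight` edge attribute where
#'   available.
#' @export
as_igraph <- function(net) UseMethod("as_igraph")

#' @export
as_igraph.ssn <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$taxa))
}
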