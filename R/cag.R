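#' SparCC correlations with resampling significance
#'
#' Recomputes the SparCC correlation over `n_boot` resampled tables and
#' attaches a pseudo p-value to every taxon pair. Two resampling schemes
#' are available:
#'
#' * `"permutation"` (default): each replicate shuffles every taxon column
#'   independently across samples, destroying all between-taxon
#'   association while preserving marginals. The pseudo p-value is the
#'   fraction of null replicates whose |rho*| reaches the observed
#'   magnitude. This gives the null distribution that a significance
#'   cutoff (p < 0.05) requires.
#' * `"bootstrap"`: samples are resampled with replacement and the
#'   p-value measures sign instability of the correlation across
#'   replicates (twice the minority-sign fraction, two-sided).
#'
#' Both are floored at 1/(n_boot + 1) via the add-one rule. Default
#' `n_boot = 100`.
#'
#' @param tab an [abundance_table()].
#' @param n_boot number of replicates (>= 1), default 100.
#' @param seed RNG seed for reproducibility.
#' @param method `"permutation"` or `"bootstrap"`.
#' @param pseudocount forwarded to [sparcc()].
#' @return An object of class `sparcc_boot`: `rho_obs` (observed clipped
#'   correlations), `pvals` (symmetric D x D, zero diagonal set to NA),
#'   `n_boot`, `method`, `seed`.
#' @export
bootstrap_sparcc <- function(tab, n_boot = 100, seed = NULL,
                             method = c("permutation", "bootstrap"),
                             pseudocount = 0.5) {
  stopifnot(inherits(tab, "abundance_table"))
  method <- match.arg(method)
  if (!is.numeric(n_boot) || n_boot < 1) stop("n_boot must be >= 1")
  n_boot <- as.integer(n_boot)
  if (!is.null(seed)) set.seed(seed)
  obs <- sparcc(tab, pseudocount = pseudocount)
  S <- n_samples(tab)
  v <- tab$values
  exceed <- matrix(0, n_taxa(tab), n_taxa(tab))
  neg <- pos <- exceed
  for (r in seq_len(n_boot)) {
    if (method == "permutation") {
      vr <- apply(v, 2L, sample)
      rownames(vr) <- rownames(v)
    } else {
      vr <- v[sample.int(S, S, replace = TRUE), , drop = FALSE]
      rownames(vr) <- paste0("b", seq_len(S))
    }
    rho_r <- suppressWarnings(
      sparcc(abundance_table(vr, kind = tab$kind), pseudocount = pseudocount)$rho)
    if (method == "permutation") {
      exceed <- exceed + (abs(rho_r) >= abs(obs$rho))
    } else {
      neg <- neg + (rho_r < 0)
      pos <- pos + (rho_r > 0)
    }
  }
  pvals <- if (method == "permutation") {
    (exceed + 1) / (n_boot + 1)
  } else {
    (2 * pmin(neg, pos) + 1) / (n_boot + 1)
  }
  pvals <- pmin(pvals, 1)
  diag(pvals) <- NA_real_
  dimnames(pvals) <- dimnames(obs$rho)
  structure(list(rho_obs = obs$rho, pvals = pvals, n_boot = n_boot,
                 method = method, seed = seed, fit = obs),
            class = "sparcc_boot")
}

#' Cluster taxa into co-abundance groups (CAGs)
#'
#' Taxa whose SparCC correlation exceeds `r_thresh` with pseudo p-value
#' below `p_thresh` are linked; CAGs are the connected components of the
#' resulting graph, refined by average-linkage hierarchical clustering on
#' distance 1 - rho within each multi-taxon component (cut at height
#' 1 - r_thresh, so groups whose average mutual correlation stays above
#' the threshold remain together). Taxa with no retained link form
#' singleton CAGs, keeping downstream abundance tables total-preserving.
#'
#' By default only positive correlations above the threshold link taxa
#' (`use_absolute = FALSE`); set `use_absolute = TRUE` to threshold |rho|.
#'
#' @param boot a [bootstrap_sparcc()] result.
#' @param r_thresh correlation threshold, default 0.4.
#' @param p_thresh p-value threshold, default 0.05.
#' @param use_absolute threshold |rho| instead of rho.
#' @return An object of class `cag_partition`: `assignment` (named integer
#'   vector taxon -> CAG), `n_cags`, `cag_ids`, `linkage` (a record of the
#'   criterion used).
#' @export
cluster_cags <- function(boot, r_thresh = 0.4, p_thresh = 0.05,
                         use_absolute = FALSE) {
  stopifnot(inherits(boot, "sparcc_boot"))
  if (r_thresh <= 0 || r_thresh >= 1) stop("r_thresh must be in (0, 1)")
  if (p_thresh <= 0 || p_thresh >= 1) stop("p_thresh must be in (0, 1)")
  rho <- boot$rho_obs
  crit <- if (use_absolute) abs(rho) else rho
  keep <- crit > r_thresh & boot$pvals < p_thresh
  keep[is.na(keep)] <- FALSE
  diag(keep) <- FALSE
  taxa <- rownames(rho)
  g <- igraph::graph_from_adjacency_matrix(keep, mode = "undirected")
  comp <- igraph::components(g)$membership
  assignment <- integer(length(taxa))
  names(assignment) <- taxa
  next_id <- 0L
  for (cid in unique(comp[order(match(names(comp), taxa))])) {
    members <- names(comp)[comp == cid]
    if (length(members) <= 2L) {
      next_id <- next_id + 1L
      assignment[members] <- next_id
    } else {
      d <- stats::as.dist(1 - rho[members, members, drop = FALSE])
      hc <- stats::hclust(d, method = "average")
      sub <- stats::cutree(hc, h = 1 - r_thresh)
      for (s in unique(sub[members])) {
        next_id <- next_id + 1L
        assignment[members[sub[members] == s]] <- next_id
      }
    }
  }
  structure(list(assignment = assignment, n_cags = next_id,
                 cag_ids = paste0("CAG", seq_len(next_id)),
                 linkage = list(method = "components+average",
                                r_thresh = r_thresh, p_thresh = p_thresh,
                                use_absolute = use_absolute,
                                cut_height = 1 - r_thresh)),
            class = "cag_partition")
}

#' @export
print.cag_partition <- function(x, ...) {
  sizes <- table(x$assignment)
  cat(sprintf("cag_partition: %d taxa in %d CAGs (largest %d, %d singletons)\n",
              length(x$assignment), x$n_cags, max(sizes), sum(sizes == 1)))
  invisible(x)
}

#' Aggregate abundances per CAG
#'
#' Sums member abundances within each co-abundance group, producing a
#' samples x CAGs table. Total abundance per sample is preserved exactly,
#' so a relative input stays relative.
#'
#' @param tab an [abundance_table()] whose taxa are all covered by
#'   `partition`.
#' @param partition a [cluster_cags()] result.
#' @return An [abundance_table()] with one column per CAG.
#' @export
cag_abundance <- function(tab, partition) {
  stopifnot(inherits(tab, "abundance_table"),
            inherits(partition, "cag_partition"))
  miss <- setdiff(taxon_ids(tab), names(partition$assignment))
  if (length(miss))
    stop("taxa not covered by the partition: ", paste(miss, collapse = ", "))
  idx <- partition$assignment[taxon_ids(tab)]
  out <- vapply(seq_len(partition$n_cags), function(g)
    rowSums(tab$values[, idx == g, drop = FALSE]),
    numeric(n_samples(tab)))
  out <- matrix(out, nrow = n_samples(tab),
                dimnames = list(sample_ids(tab), partition$cag_ids))
  abundance_table(out, kind = tab$kind)
}

#' Write a CAG assignment as TSV
#' @param partition a [cluster_cags()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cags <- function(partition, path) {
  df <- data.frame(taxon_id = names(partition$assignment),
                   cag_id = partition$cag_ids[partition$assignment])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
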