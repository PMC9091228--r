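#' Build a co-occurrence network from pairwise Spearman correlations
#'
#' Connects two features (typically CAGs) whenever their Spearman rank
#' correlation across samples is significant at `p_thresh`, with no
#' multiplicity adjustment. Edge signs follow the sign of rho. Pairs
#' involving a constant column (undefined rank correlation) yield no edge.
#' P-values come from [stats::cor.test()], which uses the exact
#' distribution at small sample sizes without ties and the t-approximation
#' otherwise.
#'
#' @param tab an [abundance_table()] of features (samples x CAGs or taxa),
#'   S >= 4.
#' @param p_thresh significance threshold, default 0.05.
#' @return An object of class `micro_network`: `nodes`, `edges`
#'   (data.frame node_i, node_j, rho, p, sign), `N` (node count).
#' @export
cooccurrence_network <- function(tab, p_thresh = 0.05) {
  stopifnot(inherits(tab, "abundance_table"))
  if (n_samples(tab) < 4L)
    stop("co-occurrence network needs S >= 4 samples")
  if (p_thresh <= 0 || p_thresh >= 1) stop("p_thresh must be in (0, 1)")
  v <- tab$values
  nodes <- colnames(v)
  D <- ncol(v)
  rows <- list()
  for (i in seq_len(D - 1L)) {
    for (j in seq.int(i + 1L, D)) {
      xi <- v[, i]; xj <- v[, j]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
      ct <- suppressWarnings(
        stats::cor.test(xi, xj, method = "spearman"))
      if (is.na(ct$p.value) || ct$p.value >= p_thresh) next
      rows[[length(rows) + 1L]] <- data.frame(
        node_i = nodes[i], node_j = nodes[j],
        rho = unname(ct$estimate), p = ct$p.value,
        sign = if (ct$estimate >= 0) "positive" else "negative",
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node_i = character(), node_j = character(),
               rho = numeric(), p = numeric(), sign = character(),
               stringsAsFactors = FALSE)
  micro_network(nodes, edges)
}

#' Construct a network object from nodes and edges
#'
#' @param nodes character vector of node identifiers.
#' @param edges data.frame with at least `node_i` and `node_j` columns
#'   (both present in `nodes`, no self-edges); extra columns such as
#'   `rho`, `p`, `sign` are carried through.
#' @return A `micro_network`.
#' @export
micro_network <- function(nodes, edges) {
  if (anyDuplicated(nodes)) stop("duplicate node identifiers")
  if (nrow(edges)) {
    if (any(edges$node_i == edges$node_j)) stop("self-edges are not allowed")
    if (!all(c(edges$node_i, edges$node_j) %in% nodes))
      stop("edge endpoints missing from node set")
  }
  structure(list(nodes = nodes, edges = edges, N = length(nodes)),
            class = "micro_network")
}

#' @export
print.micro_network <- function(x, ...) {
  cat(sprintf("micro_network: %d nodes, %d edges\n", x$N, nrow(x$edges)))
  invisible(x)
}

#' @export
as_igraph.micro_network <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

node_degrees <- function(net) {
  deg <- stats::setNames(integer(net$N), net$nodes)
  if (nrow(net$edges)) {
    tb <- table(c(net$edges$node_i, net$edges$node_j))
    deg[names(tb)] <- as.integer(tb)
  }
  deg
}

#' Topology summary of a network
#'
#' @param net a `micro_network`.
#' @return A list with `edge_count`, `average_degree` (2 E / N) and
#'   `degree_sequence` (named, sorted descending — the raw material for
#'   eyeballing scale-free behaviour; no formal power-law fit is
#'   attempted).
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "micro_network"))
  deg <- node_degrees(net)
  list(edge_count = nrow(net$edges),
       average_degree = 2 * nrow(net$edges) / net$N,
       degree_sequence = sort(deg, decreasing = TRUE))
}

#' Detect hub (keystone) nodes
#'
#' A node is flagged as a hub when it holds more than `share_thresh` of
#' the network's total connections (degree divided by the sum of all
#' degrees). The default 4% share is the conventional keystone-taxa
#' cutoff. Note the degenerate case of a regular graph, where every node
#' carries the same share and all or none are flagged together.
#'
#' @param net a non-empty `micro_network`.
#' @param share_thresh share of total degree above which a node is a hub,
#'   default 0.04.
#' @return A data.frame with columns `node`, `degree`, `share`, `hub`.
#' @export
find_hubs <- function(net, share_thresh = 0.04) {
  stopifnot(inherits(net, "micro_network"))
  if (nrow(net$edges) == 0L) stop("hub detection needs a non-empty edge set")
  deg <- node_degrees(net)
  share <- deg / sum(deg)
  data.frame(node = names(deg), degree = as.integer(deg),
             share = as.numeric(share), hub = share > share_thresh,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Robustness under random node removal
#'
#' Removes the N nodes one by one in a uniformly random order; after each
#' removal records the fragility statistic sigma, the fraction of the
#' original N still inside the largest connected component (0 once the
#' graph is empty). The curve is replicated `n_reps` times, the
#' across-replicate median at each step is taken as the final fragility
#' curve, and the robustness score is its mean:
#' `R = (1/N) * sum_i sigma(i/N)`.
#'
#' For a complete graph the curve is order-independent and
#' R = (N - 1) / (2 N) exactly; sparser topologies fall below it.
#'
#' @param net a `micro_network`.
#' @param n_reps number of random removal orders, default 1000.
#' @param seed RNG seed.
#' @return An object of class `robustness_result`: `fragility_curve`
#'   (data.frame frac_removed, sigma), `R`, `n_reps`, `N`, `seed`.
#' @export
net_robustness <- function(net, n_reps = 1000, seed = NULL) {
  stopifnot(inherits(net, "micro_network"))
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  N <- net$N
  id <- stats::setNames(seq_len(N), net$nodes)
  ei <- id[net$edges$node_i]; ej <- id[net$edges$node_j]
  adj <- vector("list", N)
  for (e in seq_along(ei)) {
    adj[[ei[e]]] <- c(adj[[ei[e]]], ej[e])
    adj[[ej[e]]] <- c(adj[[ej[e]]], ei[e])
  }
  sig <- matrix(0, n_reps, N)
  for (r in seq_len(n_reps)) {
    ord <- sample.int(N)
    # reverse construction with union-find: adding node ord[N], ord[N-1], ...
    parent <- integer(N); csize <- integer(N); present <- logical(N)
    find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    lcc <- 0L
    lcc_at <- integer(N)        # lcc_at[j]: LCC size with j nodes present
    for (j in seq_len(N)) {
      v <- ord[N - j + 1L]
      parent[v] <- v; csize[v] <- 1L; present[v] <- TRUE
      for (u in adj[[v]]) {
        if (!present[u]) next
        ru <- find(u); rv <- find(v)
        if (ru != rv) {
          parent[ru] <- rv
          csize[rv] <- csize[rv] + csize[ru]
        }
      }
      lcc <- max(lcc, csize[find(v)])
      lcc_at[j] <- lcc
    }
    # after i removals, N - i nodes remain; empty graph has sigma = 0
    if (N == 1L) sig[r, 1L] <- 0
    else sig[r, ] <- c(lcc_at[(N - 1L):1L], 0L) / N
  }
  sigma_med <- apply(sig, 2L, stats::median)
  structure(list(
    fragility_curve = data.frame(frac_removed = seq_len(N) / N,
                                 sigma = sigma_med),
    R = mean(sigma_med), n_reps = n_reps, N = N, seed = seed),
    class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("robustness_result: N = %d, R = %.4f (%d replicates)\n",
              x$N, x$R, x$n_reps))
  invisible(x)
}
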