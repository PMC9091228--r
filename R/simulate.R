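#' Define a log-normal basis model
#'
#' The generative model behind all synthetic tables: each taxon has a
#' latent absolute ("basis") abundance that is log-normal, with a sparse
#' correlation structure on the log scale. Observed tables arise by
#' normalizing the basis abundances to proportions and drawing multinomial
#' reads — exactly the setting whose latent correlations SparCC estimates.
#'
#' Correlation structure can be planted as individual pairs
#' (`planted_pairs`) and/or as equicorrelated blocks (`blocks`, the
#' ground truth for co-abundance-group recovery). The assembled matrix is
#' checked for positive semi-definiteness and repaired with
#' [Matrix::nearPD()] when mildly indefinite; repairs beyond
#' `psd_tol` are an error.
#'
#' @param D number of taxa (>= 4).
#' @param log_mean length-D log-scale means; default drawn N(0, 1.5^2),
#'   giving realistically uneven taxon abundances.
#' @param log_sd length-D log-scale standard deviations; default drawn
#'   uniform on [0.5, 1.5].
#' @param planted_pairs data.frame with columns `i`, `j`, `rho` of basis
#'   correlations to plant.
#' @param blocks list of integer vectors (taxon indices) to equicorrelate
#'   at `block_rho`.
#' @param block_rho within-block correlation, default 0.8.
#' @param psd_tol maximum admissible relative change under PSD repair.
#' @param seed RNG seed for the randomly drawn defaults.
#' @return An object of class `basis_model`: `D`, `log_mean`, `log_sd`,
#'   `corr` (the planted basis correlation matrix), `blocks`.
#' @export
basis_model <- function(D, log_mean = NULL, log_sd = NULL,
                        planted_pairs = NULL, blocks = NULL,
                        block_rho = 0.8, psd_tol = 0.1, seed = NULL) {
  if (D < 4L) stop("basis model needs D >= 4 taxa")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(log_mean)) log_mean <- stats::rnorm(D, 0, 1.5)
  if (is.null(log_sd)) log_sd <- stats::runif(D, 0.5, 1.5)
  stopifnot(length(log_mean) == D, length(log_sd) == D, all(log_sd > 0))
  C <- diag(D)
  if (!is.null(blocks)) {
    for (bl in blocks) {
      C[bl, bl] <- block_rho
      diag(C)[bl] <- 1
    }
  }
  if (!is.null(planted_pairs)) {
    for (r in seq_len(nrow(planted_pairs))) {
      i <- planted_pairs$i[r]; j <- planted_pairs$j[r]
      C[i, j] <- C[j, i] <- planted_pairs$rho[r]
    }
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    C2 <- as.matrix(Matrix::nearPD(C, corr = TRUE)$mat)
    if (max(abs(C2 - C)) > psd_tol)
      stop("planted correlation matrix is too far from positive ",
           "semi-definite (max repair ", format(max(abs(C2 - C))), ")")
    message("planted correlation matrix repaired to nearest PSD (max change ",
            format(max(abs(C2 - C)), digits = 3), ")")
    C <- C2
  }
  taxa <- paste0("T", seq_len(D))
  dimnames(C) <- list(taxa, taxa)
  structure(list(D = D, log_mean = log_mean, log_sd = log_sd, corr = C,
                 blocks = blocks, taxon_ids = taxa),
            class = "basis_model")
}

latent_logs <- function(model, S) {
  Sigma <- outer(model$log_sd, model$log_sd) * model$corr
  Y <- MASS::mvrnorm(S, mu = model$log_mean, Sigma = Sigma)
  if (S == 1L) Y <- matrix(Y, nrow = 1L)
  colnames(Y) <- model$taxon_ids
  Y
}

counts_from_logs <- function(Y, depth) {
  P <- exp(Y)
  P <- P / rowSums(P)
  counts <- t(apply(P, 1L, function(p) stats::rmultinom(1L, depth, p)[, 1L]))
  rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  colnames(counts) <- colnames(Y)
  counts
}

#' Simulate a compositional count table
#'
#' Draws per-sample latent log-normal basis abundances with the model's
#' correlation structure, converts them to proportions, and samples
#' multinomial read counts at fixed depth — emulating a table rarefied to
#' equal depth per sample (default 10,000 reads).
#'
#' @param model a [basis_model()].
#' @param S number of samples (>= 2).
#' @param depth reads per sample, default 10000.
#' @param seed RNG seed.
#' @return An [abundance_table()] of counts. The latent log-abundance
#'   draws are attached as attribute `"latent_log"` so generative checks
#'   can compare estimates against the pre-compositional truth.
#' @export
simulate_counts <- function(model, S, depth = 10000, seed = NULL) {
  stopifnot(inherits(model, "basis_model"))
  if (S < 2L) stop("need S >= 2 samples")
  if (depth < 1) stop("depth must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  Y <- latent_logs(model, S)
  tab <- abundance_table(counts_from_logs(Y, depth), kind = "counts")
  attr(tab, "latent_log") <- Y
  tab
}

#' Simulate a cohort with a planted responder effect
#'
#' Generates a trial-scale cohort in which a per-sample latent
#' "connectivity" score couples the microbiome to the phenotype in two
#' ways: (1) it multiplicatively scales the sample's deviation from the
#' cohort mean log composition, which raises the magnitude of that
#' sample's single-sample correlation contributions and hence its network
#' density; and (2) it lowers the hepatic fat change by `effect`
#' percentage points per standard deviation of the score, on top of
#' Gaussian noise. With `effect = 0` the phenotype is independent of the
#' network and responder prediction must collapse to chance.
#'
#' The mean HFC change is positioned so that the expected responder
#' fraction at the -5 cutoff equals `responder_frac`; baseline HFC is
#' uniform on `hfc_baseline_range`.
#'
#' @param model a [basis_model()].
#' @param n cohort size, default 20 (the scale of one intervention arm).
#' @param depth reads per sample, default 10000.
#' @param responder_frac expected fraction of responders, in (0, 1),
#'   default 0.5.
#' @param effect HFC-change decrease (percentage points) per SD of the
#'   connectivity score; 0 disables the coupling. Default 4.
#' @param noise SD of the residual HFC-change noise (percentage points),
#'   default 2.
#' @param conn_scale strength of the connectivity coupling to composition:
#'   sample deviations are scaled by `exp(conn_scale * score)`. Default
#'   0.6.
#' @param hfc_baseline_range range of baseline HFC (%), default c(8, 35).
#' @param cutoff responder cutoff (%), default -5.
#' @param group group label written to the metadata.
#' @param seed RNG seed.
#' @return A list with `table` (an [abundance_table()] of counts) and
#'   `meta` (data.frame sample_id, group, hfc_baseline, hfc_followup,
#'   hfc_change, connectivity).
#' @export
simulate_cohort <- function(model, n = 20, depth = 10000,
                            responder_frac = 0.5, effect = 4, noise = 2,
                            conn_scale = 0.6, hfc_baseline_range = c(8, 35),
                            cutoff = -5, group = "AEx", seed = NULL) {
  stopifnot(inherits(model, "basis_model"))
  if (n < 2L) stop("need n >= 2 samples")
  if (responder_frac <= 0 || responder_frac >= 1)
    stop("responder_frac must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  score <- stats::rnorm(n)
  Y <- latent_logs(model, n)
  dev <- sweep(Y, 2L, model$log_mean)
  Y2 <- sweep(dev, 1L, exp(conn_scale * score), `*`)
  Y2 <- sweep(Y2, 2L, model$log_mean, `+`)
  tab <- abundance_table(counts_from_logs(Y2, depth), kind = "counts")
  attr(tab, "latent_log") <- Y2
  sd_tot <- sqrt(effect^2 + noise^2)
  mu_change <- cutoff - sd_tot * stats::qnorm(responder_frac)
  hfc_change <- mu_change - effect * score + stats::rnorm(n, 0, noise)
  hfc_baseline <- stats::runif(n, hfc_baseline_range[1L], hfc_baseline_range[2L])
  meta <- data.frame(sample_id = sample_ids(tab), group = group,
                     hfc_baseline = hfc_baseline,
                     hfc_followup = hfc_baseline + hfc_change,
                     hfc_change = hfc_change,
                     connectivity = score, stringsAsFactors = FALSE)
  list(table = tab, meta = meta)
}
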