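#' Label intervention responders from hepatic fat change
#'
#' A participant is a responder when their hepatic fat content decreased
#' by more than 5 percentage points, i.e. `hfc_change < cutoff` strictly;
#' a change of exactly the cutoff counts as low/non-responder.
#'
#' @param meta data.frame with columns `sample_id` and `hfc_change` (%).
#' @param cutoff HFC change below which a sample is a responder,
#'   default -5.
#' @return A data.frame `sample_id`, `hfc_change`, `label` (factor with
#'   levels `responder`, `low/non-responder`), with the cutoff stored as
#'   an attribute.
#' @export
label_responders <- function(meta, cutoff = -5) {
  if (!all(c("sample_id", "hfc_change") %in% names(meta)))
    stop("metadata needs sample_id and hfc_change columns")
  bad <- meta$sample_id[!is.finite(meta$hfc_change)]
  if (length(bad))
    stop("missing hfc_change for samples: ", paste(bad, collapse = ", "))
  lab <- factor(ifelse(meta$hfc_change < cutoff, "responder", "low/non-responder"),
                levels = c("responder", "low/non-responder"))
  out <- data.frame(sample_id = meta$sample_id,
                    hfc_change = meta$hfc_change, label = lab,
                    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  out
}

pair_names <- function(taxa) {
  D <- length(taxa)
  idx <- which(upper.tri(diag(D)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  paste(taxa[idx[, 1L]], taxa[idx[, 2L]], sep = "|")
}

#' Edge-feature matrix from a collection of single-sample networks
#'
#' Stacks the per-individual networks into a samples x taxon-pairs matrix:
#' one column per unordered pair (lexicographic order, D(D-1)/2 columns),
#' holding the retained edge weight or 0 where the individual's network
#' has no edge. This matrix is the feature space for responder
#' prediction.
#'
#' @param ssns list of [build_ssn()] networks over an identical taxon set.
#' @return Numeric matrix with sample ids as rownames and `i|j` pair names
#'   as colnames.
#' @export
edge_matrix <- function(ssns) {
  if (!length(ssns)) stop("no networks supplied")
  taxa <- ssns[[1L]]$taxa
  for (s in ssns)
    if (!identical(s$taxa, taxa)) stop("networks have mismatched taxon sets")
  cols <- pair_names(taxa)
  M <- matrix(0, length(ssns), length(cols),
              dimnames = list(unname(vapply(ssns, `[[`, "", "sample_id")), cols))
  for (r in seq_along(ssns)) {
    e <- ssns[[r]]$edges
    if (nrow(e))
      M[r, paste(e$taxon_i, e$taxon_j, sep = "|")] <- e$weight
  }
  M
}

#' ROC analysis of a per-sample attribute
#'
#' Unsupervised classification: a single network attribute (edge count or
#' mean degree) is swept over all thresholds to separate responders from
#' low/non-responders. Higher attribute values are scored toward the
#' responder class; when that orientation is wrong the AUC falls below
#' 0.5 and the `direction` field reports it. The AUC equals the
#' Mann-Whitney rank statistic U / (n1 n2), with midranks handling ties.
#'
#' @param attribute numeric vector, one value per sample.
#' @param labels factor or character as produced by [label_responders()]
#'   (first level / value `"responder"` is the positive class), or a
#'   logical vector with `TRUE` = responder.
#' @return An object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `direction`, `youden` (threshold, sensitivity
#'   and specificity at Youden's J).
#' @export
roc_attribute <- function(attribute, labels) {
  if (is.data.frame(labels)) labels <- labels$label
  pos <- if (is.logical(labels)) labels else labels == "responder"
  if (length(pos) != length(attribute)) stop("length mismatch")
  if (anyNA(attribute) || anyNA(pos)) stop("missing values")
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("ROC needs both classes present")
  r <- rank(attribute)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(-Inf, sort(unique(attribute)), Inf)
  sens <- spec <- numeric(length(thr))
  for (t in seq_along(thr)) {
    pred <- attribute >= thr[t]
    sens[t] <- sum(pred & pos) / n1
    spec[t] <- sum(!pred & !pos) / n0
  }
  j <- which.max(sens + spec - 1)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc,
                 direction = if (auc >= 0.5) "higher_attribute_responder"
                             else "lower_attribute_responder",
                 youden = list(threshold = thr[j], sensitivity = sens[j],
                               specificity = spec[j])),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.3f (%s)\n", x$auc, x$direction))
  invisible(x)
}

#' Penalized regression of post-intervention HFC on edge features
#'
#' Fits an Elastic-Net (mixing 0.5) or LASSO model of the
#' post-intervention hepatic fat level on the per-sample edge features,
#' with the penalty chosen by cross-validation — leave-one-out by default,
#' matching trial-scale cohorts of 10-20 individuals. Features are
#' standardized internally by glmnet. When baseline HFC and true labels
#' are supplied, predictions are converted to predicted HFC change
#' (predicted level minus baseline), thresholded at `cutoff` into
#' predicted responder labels, and scored by ROC against the true labels
#' — both on resubstitution and on the cross-validated (held-out)
#' predictions, reported separately.
#'
#' @param features samples x features numeric matrix ([edge_matrix()]).
#' @param response numeric response, post-intervention HFC level.
#' @param model `"elastic_net"` (alpha = 0.5) or `"lasso"` (alpha = 1).
#' @param cv `"loo"` or `"kfold"`.
#' @param nfolds folds when `cv = "kfold"`, default 5.
#' @param seed RNG seed (fold assignment).
#' @param hfc_baseline optional baseline HFC levels for label conversion.
#' @param true_labels optional labels as in [roc_attribute()].
#' @param cutoff responder cutoff on predicted change, default -5.
#' @return A list of class `penalized_fit`: `fit` (the cv.glmnet object,
#'   or NULL for the degenerate intercept-only case), `lambda`,
#'   `coefficients` (named non-zero coefficients excluding intercept),
#'   `predictions` (data.frame sample_id, resubstitution, cv), and when
#'   labels were supplied `predicted_change`, `predicted_label`,
#'   `roc_resubstitution`, `roc_cv`.
#' @export
fit_penalized <- function(features, response,
                          model = c("elastic_net", "lasso"),
                          cv = c("loo", "kfold"), nfolds = 5, seed = NULL,
                          hfc_baseline = NULL, true_labels = NULL,
                          cutoff = -5) {
  model <- match.arg(model)
  cv <- match.arg(cv)
  features <- as.matrix(features)
  n <- nrow(features)
  if (is.null(rownames(features)))
    rownames(features) <- paste0("s", seq_len(n))
  if (n < 6L) stop("penalized regression needs n >= 6 samples")
  if (length(response) != n) stop("response length mismatch")
  if (stats::sd(response) == 0) stop("constant response: nothing to fit")
  if (!is.null(seed)) set.seed(seed)
  alpha <- if (model == "lasso") 1 else 0.5
  informative <- apply(features, 2L, stats::sd) > 0
  if (sum(informative) < 2L) {
    # no usable predictors: intercept-only model
    pred <- rep(mean(response), n)
    out <- list(fit = NULL, lambda = NA_real_,
                coefficients = stats::setNames(numeric(0), character(0)),
                predictions = data.frame(sample_id = rownames(features),
                                         resubstitution = pred, cv = pred),
                model = model, cv = cv)
  } else {
    x <- features[, informative, drop = FALSE]
    nf <- if (cv == "loo") n else min(nfolds, n)
    cvfit <- glmnet::cv.glmnet(x, response, alpha = alpha, nfolds = nf,
                               grouped = (cv != "loo"), keep = TRUE)
    pred_res <- as.numeric(stats::predict(cvfit, newx = x, s = "lambda.min"))
    il <- match(cvfit$lambda.min, cvfit$lambda)
    pred_cv <- as.numeric(cvfit$fit.preval[, il])
    cf <- as.matrix(stats::coef(cvfit, s = "lambda.min"))[-1L, 1L]
    out <- list(fit = cvfit, lambda = cvfit$lambda.min,
                coefficients = cf[cf != 0],
                predictions = data.frame(sample_id = rownames(features),
                                         resubstitution = pred_res,
                                         cv = pred_cv),
                model = model, cv = cv)
  }
  if (!is.null(hfc_baseline) && !is.null(true_labels)) {
    ch_res <- out$predictions$resubstitution - hfc_baseline
    ch_cv <- out$predictions$cv - hfc_baseline
    out$predicted_change <- data.frame(resubstitution = ch_res, cv = ch_cv)
    out$predicted_label <- data.frame(
      resubstitution = ifelse(ch_res < cutoff, "responder", "low/non-responder"),
      cv = ifelse(ch_cv < cutoff, "responder", "low/non-responder"))
    # lower predicted change scores toward responder
    out$roc_resubstitution <- tryCatch(roc_attribute(-ch_res, true_labels),
                                       error = function(e) NULL)
    out$roc_cv <- tryCatch(roc_attribute(-ch_cv, true_labels),
                           error = function(e) NULL)
  }
  class(out) <- "penalized_fit"
  out
}

#' @export
print.penalized_fit <- function(x, ...) {
  cat(sprintf("penalized_fit (%s, %s CV): %d non-zero coefficients\n",
              x$model, x$cv, length(x$coefficients)))
  if (!is.null(x$roc_cv))
    cat(sprintf("  held-out AUC = %.3f\n", x$roc_cv$auc))
  invisible(x)
}

#' Regress HFC change on a network attribute
#'
#' Ordinary least squares of hepatic fat change on a single per-sample
#' network attribute (e.g. edge count), with the usual two-sided t-test
#' on the slope. No multiple-testing adjustment is applied — the
#' attribute is a single pre-specified predictor.
#'
#' @param attribute numeric predictor, one value per sample.
#' @param hfc_change numeric response (%).
#' @return A list: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
regress_attribute <- function(attribute, hfc_change) {
  n <- length(attribute)
  if (n < 3L) stop("regression needs n >= 3")
  if (length(hfc_change) != n) stop("length mismatch")
  if (stats::sd(attribute) == 0) stop("zero-variance attribute")
  fit <- stats::lm(hfc_change ~ attribute)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2L, 4L],
       n = n)
}
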