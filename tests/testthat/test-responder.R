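test_that("responder labels apply the strict -5% cutoff", {
  meta <- data.frame(sample_id = c("a", "b", "c", "d"),
                     hfc_change = c(-6, 0, -5, -4.99))
  lab <- label_responders(meta)
  expect_equal(as.character(lab$label),
               c("responder", "low/non-responder", "low/non-responder",
                 "low/non-responder"))
  expect_equal(attr(lab, "cutoff"), -5)
  meta$hfc_change[2] <- NA
  expect_error(label_responders(meta), "b")
})

test_that("edge matrices have one lexicographic column per pair", {
  mod <- basis_model(6, seed = 101)
  tab <- simulate_counts(mod, S = 8, depth = 2000, seed = 102)
  tn <- sparcc_decompose(tab)
  ssns <- build_ssn_all(tn, density = 0.3)
  M <- edge_matrix(ssns)
  expect_equal(dim(M), c(8, 15))
  expect_equal(colnames(M)[1:5],
               paste("T1", c("T2", "T3", "T4", "T5", "T6"), sep = "|"))
  # retained edges carry their weights, absent pairs are zero
  s1 <- ssns[[1]]
  key <- paste(s1$edges$taxon_i, s1$edges$taxon_j, sep = "|")
  expect_equal(unname(M[1, key]), s1$edges$weight)
  expect_true(all(M[1, setdiff(colnames(M), key)] == 0))
  # permuting input order permutes rows identically
  M2 <- edge_matrix(ssns[c(3, 1, 2, 4:8)])
  expect_equal(M2, M[c(3, 1, 2, 4:8), ])
  # two taxa -> a single column
  expect_equal(ncol(edge_matrix(list(list(sample_id = "s", taxa = c("A", "B"),
                                          edges = data.frame())))), 1)
  bad <- ssns; bad[[2]]$taxa <- rev(bad[[2]]$taxa)
  expect_error(edge_matrix(bad), "mismatched")
})

test_that("ROC AUC equals exhaustive concordant-pair counting", {
  cases <- list(
    list(score = c(3, 2.5, 2, 1), pos = c(TRUE, TRUE, FALSE, FALSE)),   # perfect
    list(score = rep(1, 6), pos = rep(c(TRUE, FALSE), 3)),              # all ties
    list(score = c(1, 2, 2, 3, 4, 4, 5, 0),
         pos = c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE)),
    list(score = c(-1, 0, 0, 0, 2), pos = c(FALSE, TRUE, FALSE, TRUE, TRUE)))
  for (cs in cases) {
    r <- roc_attribute(cs$score, cs$pos)
    expect_equal(r$auc, oracle_auc(cs$score, cs$pos))
  }
  expect_equal(roc_attribute(c(3, 2.5, 2, 1),
                             c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_attribute(rep(1, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  expect_error(roc_attribute(1:4, rep(TRUE, 4)), "both classes")
})

test_that("ROC AUC agrees with pROC and respects invariances", {
  skip_if_not_installed("pROC")
  set.seed(111)
  for (i in 1:5) {
    score <- round(rnorm(12), 1)          # rounding forces some ties
    pos <- runif(12) < 0.5
    if (!any(pos) || all(pos)) next
    ours <- roc_attribute(score, pos)$auc
    ref <- suppressMessages(
      as.numeric(pROC::auc(pROC::roc(pos, score, direction = "<",
                                     quiet = TRUE))))
    expect_equal(ours, ref)
    # monotone transform invariance and label-flip symmetry
    expect_equal(roc_attribute(exp(score), pos)$auc, ours)
    expect_equal(roc_attribute(score, !pos)$auc, 1 - ours)
  }
})

test_that("penalized regression recovers a planted sparse signal", {
  skip_if_not_installed("glmnet")
  hits <- 0; aucs <- numeric(0)
  for (seed in 1:10) {
    set.seed(seed)
    n <- 40; p <- 300
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("s", 1:n), paste0("f", 1:p)))
    beta <- rep(0, p); beta[1:5] <- 2
    y <- drop(X %*% beta) + rnorm(n, 0, 0.5)
    fit <- fit_penalized(X, y, model = "lasso", cv = "loo", seed = seed)
    found <- sum(paste0("f", 1:5) %in% names(fit$coefficients))
    hits <- hits + (found >= 3)
    lab <- y < median(y)
    aucs <- c(aucs, roc_attribute(-fit$predictions$cv, lab)$auc)
  }
  expect_gte(hits, 6)                      # majority of seeds
  expect_gt(median(aucs), 0.8)
})

test_that("penalized fits are deterministic and handle degenerate input", {
  set.seed(121)
  X <- matrix(rnorm(20 * 10), 20, 10)
  y <- rnorm(20)
  f1 <- fit_penalized(X, y, seed = 5)
  f2 <- fit_penalized(X, y, seed = 5)
  expect_identical(f1$coefficients, f2$coefficients)
  # all-zero features: intercept-only model predicting the mean
  Z <- matrix(0, 20, 10)
  f0 <- fit_penalized(Z, y)
  expect_length(f0$coefficients, 0)
  expect_equal(f0$predictions$resubstitution, rep(mean(y), 20))
  expect_error(fit_penalized(X, rep(1, 20)), "constant response")
  expect_error(fit_penalized(X[1:4, ], y[1:4]), "n >= 6")
})

test_that("attribute regression matches the normal equations", {
  x <- c(1, 2, 3, 4, 5)
  noiseless <- suppressWarnings(regress_attribute(x, 2 * x + 1))
  expect_equal(noiseless[c("slope", "intercept", "r_squared")],
               list(slope = 2, intercept = 1, r_squared = 1))
  expect_equal(suppressWarnings(regress_attribute(x, rep(3, 5)))$slope, 0)
  set.seed(131)
  xr <- rnorm(10); yr <- rnorm(10)
  got <- regress_attribute(xr, yr)
  orc <- oracle_ols(xr, yr)
  expect_equal(got$slope, unname(orc["slope"]), tolerance = 1e-10)
  expect_equal(got$intercept, unname(orc["intercept"]), tolerance = 1e-10)
  expect_error(regress_attribute(rep(1, 5), rnorm(5)), "zero-variance")
})

test_that("the planted responder effect is recoverable end to end", {
  run1 <- function(seed, effect) {
    mod <- basis_model(20, seed = seed)
    sim <- simulate_cohort(mod, n = 20, effect = effect, seed = seed + 1000)
    tn <- sparcc_decompose(sim$table)
    ssns <- build_ssn_all(tn)
    ec <- vapply(ssns, `[[`, 0, "edge_count")
    lab <- label_responders(sim$meta)
    if (nlevels(droplevels(lab$label)) < 2) return(c(NA, NA))
    c(roc_attribute(ec, lab)$auc,
      regress_attribute(ec, sim$meta$hfc_change)$slope)
  }
  eff <- t(vapply(1:15, run1, numeric(2), effect = 4))
  nul <- t(vapply(16:30, run1, numeric(2), effect = 0))
  expect_gte(mean(eff[, 1] > 0.5, na.rm = TRUE), 0.9)
  expect_true(all(eff[, 2] < 0, na.rm = TRUE))    # more edges -> larger HFC drop
  expect_lt(abs(mean(nul[, 1], na.rm = TRUE) - 0.5), 0.12)
})
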