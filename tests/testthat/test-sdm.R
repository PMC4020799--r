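test_that("binomial GLM fit matches the logistic likelihood", {
  # intercept-only on a balanced response: intercept 0, fitted p = 0.5
  bal <- data.frame(occ = rep(c(0, 1), 50))
  f0 <- fit_glm_binomial(bal)
  expect_equal(unname(f0$coefficients[["(Intercept)"]]), 0, tolerance = 1e-8)
  expect_equal(unname(predict_fit(f0, bal)[1]), 0.5, tolerance = 1e-8)

  # hand-computed Bernoulli log-likelihood on 6 observations
  d6 <- data.frame(occ = c(0, 1, 0, 1, 1, 0), x1 = c(-1.2, 0.4, 0.8, 2, 1, -0.5))
  f6 <- fit_glm_binomial(d6, "x1")
  p <- plogis(f6$coefficients[["(Intercept)"]] + f6$coefficients[["x1"]] * d6$x1)
  ll_hand <- sum(d6$occ * log(p) + (1 - d6$occ) * log(1 - p))
  expect_equal(f6$log_likelihood, ll_hand, tolerance = 1e-8)
  expect_equal(f6$aic, -2 * ll_hand + 2 * 2, tolerance = 1e-8)

  # coefficient recovery: estimates within 3 SE of the simulating values
  df <- sim_logistic_df(10000, c(0.5, -1.0), seed = 51)
  fit <- fit_glm_binomial(df, "x1")
  ref <- summary(glm(occ ~ x1, binomial, df))$coefficients
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - 0.5) / ref[1, 2], 3)
  expect_lt(abs(fit$coefficients[["x1"]] + 1.0) / ref[2, 2], 3)

  # single-class response is an error; separation is flagged
  expect_error(fit_glm_binomial(data.frame(occ = rep(1, 5))), "single class")
  sep <- data.frame(occ = rep(c(0, 1), each = 20),
                    x1 = c(rnorm(20, -5), rnorm(20, 5)))
  expect_true(fit_glm_binomial(sep, "x1")$separation)
})

test_that("Akaike weights follow the closed form", {
  expect_equal(akaike_weights(123.4), 1)
  expect_equal(akaike_weights(c(10, 10)), c(0.5, 0.5))
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  # sums to 1 and invariant to a constant shift
  set.seed(52)
  a <- runif(7, 500, 600)
  expect_equal(sum(akaike_weights(a)), 1)
  expect_equal(akaike_weights(a + 1234), akaike_weights(a))
  expect_error(akaike_weights(numeric(0)), "empty")
})

test_that("rank-based AUC equals exhaustive pair counting", {
  auc_pairs <- function(scores, labels) {   # brute-force oracle
    pos <- scores[labels]; neg <- scores[!labels]
    s <- 0
    for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
    s / (length(pos) * length(neg))
  }
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  s <- c(0.1, 0.4, 0.35, 0.8, 0.35, 0.7); l <- c(F, F, T, T, T, F)
  expect_equal(auc(s, l), auc_pairs(s, l))
  set.seed(53)
  for (k in 1:10) {
    sc <- sample(seq(0, 1, 0.1), 12, TRUE)   # forces ties
    lb <- sample(c(TRUE, FALSE), 12, TRUE)
    if (length(unique(lb)) < 2) next
    expect_equal(auc(sc, lb), auc_pairs(sc, lb))
    expect_equal(auc(qlogis(sc / 2 + 0.25), lb), auc(sc, lb)) # monotone invariance
  }
  # label-independent scores: AUC ~ 0.5 at n = 10^4
  sc <- runif(10000); lb <- runif(10000) < 0.5
  expect_lt(abs(auc(sc, lb) - 0.5), 0.02)
  expect_error(auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("rank-based AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(54)
  sc <- rnorm(200); lb <- runif(200) < plogis(sc)
  expect_equal(auc(sc, lb),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE))))
})

test_that("stepwise AIC finds strong predictors and rejects pure noise", {
  hits <- 0
  for (k in 1:10) {
    df <- sim_logistic_df(800, c(0, 1.5, 0, 0, 0, 0), seed = 60 + k)
    sw <- stepwise_aic(df, paste0("x", 1:5))
    hits <- hits + ("x1" %in% sw$best_terms)
  }
  expect_gte(hits, 9)   # the true term is almost always selected

  # all-noise predictors: intercept-only dominates (theoretical rate
  # (1 - P[chisq_1 > 2])^3 ~ 0.6) and few noise terms survive
  n_null <- 0; n_terms <- 0
  for (k in 1:50) {
    df <- sim_logistic_df(2000, c(0, 0, 0, 0), seed = 70 + k)
    sw <- stepwise_aic(df, paste0("x", 1:3))
    n_null <- n_null + (length(sw$best_terms) == 0)
    n_terms <- n_terms + length(sw$best_terms)
  }
  expect_gte(n_null / 50, 0.4)
  expect_lt(n_terms / 50, 1)
})

test_that("stepwise AIC is a fixed point at an optimum and records its path", {
  df <- sim_logistic_df(2000, c(0, 2, -2), seed = 80)
  # start from the already-optimal model: returned unchanged
  sw_opt <- stepwise_aic(df, c("x1", "x2"), start = c("x1", "x2"))
  expect_equal(sw_opt$best_terms, c("x1", "x2"))
  # path contains every evaluated model with finite AIC, best first reachable
  expect_true(all(is.finite(sw_opt$path$aic)))
  expect_true(pengdisp:::model_key(sw_opt$best_terms) %in% sw_opt$path$model)
  # agreement with stats::step (backward-forward from the full model)
  df2 <- sim_logistic_df(1500, c(0.3, 1.2, 0, -0.8, 0), seed = 81)
  sw <- stepwise_aic(df2, paste0("x", 1:4))
  ref <- step(glm(occ ~ x1 + x2 + x3 + x4, binomial, df2),
              direction = "both", trace = 0)
  expect_setequal(sw$best_terms, attr(terms(ref), "term.labels"))
  expect_equal(sw$best_fit$aic, AIC(ref), tolerance = 1e-8)
})

test_that("competing-model table is Delta-filtered, sorted and weighted", {
  df <- sim_logistic_df(600, c(0, 1, 0.2, 0), seed = 82)
  sw <- stepwise_aic(df, paste0("x", 1:3))
  cm <- competing_models(sw, df)
  expect_equal(cm$delta_aic[1], 0)
  expect_true(all(diff(cm$aic) >= 0))         # best-first ordering
  expect_true(all(cm$delta_aic <= 2))
  expect_equal(sum(cm$akaike_weight), 1)
  expect_equal(cm$model[1], pengdisp:::model_key(sw$best_terms))
  # a single retained model carries weight 1
  if (nrow(cm) == 1) expect_equal(cm$akaike_weight, 1)
  # signed formula shows one sign per term
  expect_true(all(grepl("^[+-]|^1$", cm$formula_signed)))
})

test_that("replicate ensemble is deterministic and respects its design", {
  study <- recovery_study(seed = 90)
  pa <- sample_pseudo_absences(study$presences,
                               env_complete_cells(study$stack),
                               study$grid, n_sets = 8, seed = 91)
  e1 <- run_replicates(study$presences, pa, study$stack, n_rep = 8, seed = 92)
  e2 <- run_replicates(study$presences, pa, study$stack, n_rep = 8, seed = 92)
  expect_identical(e1$auc, e2$auc)
  expect_identical(e1$replicates, e2$replicates)
  # train/test partition: disjoint, stratified ~70/30 per class
  r1 <- e1$replicates[[1]]
  expect_length(intersect(r1$train_cells, r1$test_cells), 0L)
  n_pres <- length(study$presences$cells)
  expect_equal(sum(r1$train_cells %in% study$presences$cells),
               round(0.7 * n_pres))
  expect_error(run_replicates(study$presences, pa, study$stack, n_rep = 50,
                              seed = 1),
               "pseudo-absence sets")
})

test_that("term-name aliases normalize to the canonical codes", {
  expect_equal(normalize_terms(c("CHLA.G3", "bat", "Sst")),
               c("CHLa.G3", "BAT", "SST"))
  expect_error(normalize_terms("DEPTH"), "unknown term")
})
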