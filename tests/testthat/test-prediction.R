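# Factor scores, ridge with nested CV, split-half and operative prediction.

test_that("factor-score validities match the closed form and weighting identities", {
  spec <- lst_model("single_trait")
  truth <- c(lambda = 0.7, theta1 = 0.51, theta2 = 0.51, theta3 = 0.51,
             theta4 = 0.51)
  fit <- ml_fit(spec, implied_covariance(spec, truth), n = 400)
  set.seed(80)
  x <- matrix(rnorm(50 * 4), 50, 4)
  fs <- factor_scores(fit, x, "regression")
  # compound-symmetric closed form: validity = sqrt(k lambda^2 / (theta + k lambda^2))
  expect_equal(fs$validity, sqrt(1.96 / 2.47), tolerance = 1e-4)

  fb <- factor_scores(fit, x, "bartlett")
  # conditional unbiasedness: weights recombine the loadings to exactly 1
  expect_equal(sum(fb$weights * 0.7), 1, tolerance = 1e-3)
  expect_true(fb$validity <= fs$validity + 1e-9)

  # Monte-Carlo check of the validity definition: corr(factor, score)
  sp <- uniform_scale_params("s", 4, 0.7, 0.51)
  ep <- uniform_edge_params(1, 0.8, 0.9, 0.36)
  pop <- generate_population(5e4, ep, sp, rho = 0, seed = 81)
  phen <- generate_phenotype(pop, seed = 82)
  cfit <- ml_fit(lst_model("congeneric", n_items = 4),
                 cov(phen$items$s), 5e4)
  sc <- factor_scores(cfit, phen$items$s, "regression")
  expect_equal(cor(sc$scores, pop$eta[, 1]), sc$validity, tolerance = 0.01)

  # noiseless limit: scores proportional to the indicator mean, validity -> 1
  fit0 <- ml_fit(spec, implied_covariance(
    spec, c(lambda = 0.7, theta1 = 1e-6, theta2 = 1e-6, theta3 = 1e-6,
            theta4 = 1e-6)), n = 400)
  s_reg <- factor_scores(fit0, x, "regression")
  s_bar <- factor_scores(fit0, x, "bartlett")
  expect_gt(s_reg$validity, 0.999)
  expect_equal(cor(s_reg$scores, rowMeans(x)), 1, tolerance = 1e-6)
  expect_equal(cor(s_bar$scores, rowMeans(x)), 1, tolerance = 1e-6)
})

test_that("the validity gate separates constructs at the threshold", {
  v <- c(e1 = 0.891, e2 = 0.79, e3 = NA)
  g <- validity_gate(v, 0.80)
  expect_identical(g$retained, "e1")
  expect_setequal(g$flagged, c("e2", "e3"))
  g9 <- validity_gate(v, 0.90)
  expect_true("e1" %in% g9$flagged)
})

test_that("ridge with nested CV shrinks noise and tracks strong signal", {
  set.seed(83)
  # single perfect predictor with a large sample: mild shrinkage, R2 near 1
  y <- rnorm(5000)
  rg <- ridge_cv(matrix(y, ncol = 1), y, seed = 1)
  expect_equal(rg$alpha, 1e3)  # smallest penalty wins
  ytest <- rnorm(500)
  expect_gt(metric_r2(ytest, predict(rg, matrix(ytest, ncol = 1))), 0.9)

  # pure noise: the penalty runs to the top of the grid and mean test R2 <= 0
  r2s <- replicate(20, {
    x <- matrix(rnorm(120 * 10), 120, 10)
    yn <- rnorm(120)
    f <- ridge_cv(x[1:80, ], yn[1:80], seed = 2)
    metric_r2(yn[81:120], predict(f, x[81:120, ]))
  })
  expect_lt(mean(r2s), 0.02)

  # duplicated predictor columns: symmetric coefficients, no failure
  x <- matrix(rnorm(200 * 3), 200, 3)
  yy <- x[, 1] + rnorm(200)
  fd <- ridge_cv(cbind(x, x), yy, seed = 3)
  expect_equal(unname(fd$beta[1:3]), unname(fd$beta[4:6]), tolerance = 1e-10)

  expect_error(ridge_cv(x, rep(1, 200)), "constant")
  expect_error(ridge_cv(x, yy, alpha_grid = numeric(0)), "non-empty")
})

test_that("performance metrics follow their sums-of-squares definitions", {
  y <- c(1, 2, 3)
  expect_equal(metric_r2(y, y), 1)
  expect_equal(metric_r2(y, rep(2, 3)), 0)
  expect_equal(metric_r2(y, c(3, 2, 1)), -3)
  expect_error(metric_r2(c(1, 1, 1), y), "constant")
  expect_error(metric_r2(c(1, 2), c(1, 2)), "at least 3")

  set.seed(84)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(metric_fisher_z(a, b), atanh(cor(a, b)))
  expect_equal(metric_fisher_z(a, -b), -metric_fisher_z(a, b))
  z_clip <- metric_fisher_z(a, a)
  expect_equal(as.numeric(z_clip), atanh(1 - 1e-7))
  expect_identical(attr(z_clip, "clipped"), 1L)  # clipping is flagged
  expect_error(metric_fisher_z(a, rep(1, 100)), "constant")
})

test_that("family-aware folds never split a family and stay balanced", {
  fams <- rep(sprintf("f%03d", 1:80), times = rep_len(c(1, 2, 3), 80))
  folds <- make_family_folds(fams, k = 10, seed = 5)
  expect_length(folds, length(fams))
  expect_setequal(unique(folds), 1:10)
  # each family maps to exactly one fold
  expect_true(all(tapply(folds, fams, function(x) length(unique(x))) == 1))
  sizes <- table(folds)
  expect_lt(max(sizes) - min(sizes), 4)
  expect_error(make_family_folds(rep("f1", 10), k = 3), "fewer families")
})

test_that("operative prediction is the conditional-normal formula and matches OLS for saturated moments", {
  # hand-substitution case: univariate slope 0.5
  fit <- list(spec = list(family = "saturated"),
              implied = matrix(c(1, 0.5, 0.5, 1), 2, 2),
              means = c(0, 0), converged = TRUE)
  expect_equal(drop(operative_predict(fit, 2, x_idx = 1, y_idx = 2)), 1.0)
  # centring case: x0 at the mean predicts the response mean
  expect_equal(drop(operative_predict(fit, 0, x_idx = 1, y_idx = 2)), 0)

  set.seed(86)
  for (i in 1:5) {
    n <- 60; px <- 3
    x <- matrix(rnorm(n * px), n, px)
    y <- x %*% runif(px) + rnorm(n)
    dat <- cbind(x, y)
    sf <- saturated_fit(dat)
    pred_op <- operative_predict(sf, x, x_idx = 1:px, y_idx = px + 1)
    pred_ols <- fitted(lm(y ~ x))
    expect_equal(drop(pred_op), unname(pred_ols), tolerance = 1e-8)
  }
})

test_that("split-half bookkeeping yields two folds per repeat and all four variants", {
  ep <- uniform_edge_params(8, 0.75, 0.9, c(0.3, 0.6, 0.3, 0.6))
  sp <- uniform_scale_params("cog", 5, 0.7, 0.6)
  pop <- generate_population(240, ep, sp, rho = 0.4, n_families = 240, seed = 90)
  panel <- generate_edge_panel(pop, seed = 91)
  phen <- generate_phenotype(pop, seed = 92)
  res <- split_half_experiment(panel, phen, repeats = 2, seed = 93,
                               min_n = 100)
  expect_setequal(unique(res$method),
                  c("avg_to_sum", "fs_to_sum", "avg_to_fs", "fs_to_fs"))
  counts <- table(res$method)
  expect_true(all(counts == 4))  # 2 repeats x 2 folds
  expect_true(all(res$r_squared <= 1, na.rm = TRUE))
  # identical configuration reproduces identical metrics
  res2 <- split_half_experiment(panel, phen, repeats = 2, seed = 93,
                                min_n = 100)
  expect_identical(res, res2)
  expect_error(split_half_experiment(panel, phen, repeats = 1, seed = 1,
                                     min_n = 200), "too few subjects")
})

test_that("training in the split-half experiment is isolated from the test half", {
  ep <- uniform_edge_params(6, 0.75, 0.9, c(0.3, 0.6, 0.3, 0.6))
  sp <- uniform_scale_params("cog", 5, 0.7, 0.6)
  pop <- generate_population(220, ep, sp, rho = 0.4, n_families = 220, seed = 94)
  panel <- generate_edge_panel(pop, seed = 95)
  phen <- generate_phenotype(pop, seed = 96)
  subj <- sort(unique(panel$subject_id))
  split1 <- seq_along(subj) <= 110
  res1 <- split_half_experiment(panel, phen, repeats = 1, seed = 97,
                                min_n = 100, splits = list(split1),
                                diagnostics = TRUE)
  # transform every observation of the test half (second half of the split)
  # with maps that leave model establishment there unchanged - a common
  # positive rescale of the scan indicators and a location shift of the
  # items - so any change in the trained models would be an information leak
  panel2 <- panel
  te_ids <- subj[!split1]
  rows <- panel2$subject_id %in% te_ids
  for (q in paste0("rsfc_q", 1:4)) {
    panel2[[q]][rows] <- panel2[[q]][rows] * 1.7
  }
  panel2$mean_z <- rowMeans(panel2[, paste0("rsfc_q", 1:4)])
  phen2 <- phen
  phen2$items$cog[match(te_ids, phen2$sum_scores$subject_id), ] <-
    phen2$items$cog[match(te_ids, phen2$sum_scores$subject_id), ] + 5
  phen2$sum_scores$cog <- rowSums(phen2$items$cog)
  res2 <- split_half_experiment(panel2, phen2, repeats = 1, seed = 97,
                                min_n = 100, splits = list(split1),
                                diagnostics = TRUE)
  d1 <- attr(res1, "diagnostics")
  d2 <- attr(res2, "diagnostics")
  # fold 1 trains on the unperturbed first half: fitted ridge models agree
  f1 <- Filter(function(x) x$fold == 1, d1)
  f2 <- Filter(function(x) x$fold == 1, d2)
  for (i in seq_along(f1)) {
    expect_identical(f1[[i]]$alpha, f2[[i]]$alpha)
    expect_equal(f1[[i]]$beta, f2[[i]]$beta, tolerance = 1e-12)
  }
})

test_that("the operative pipeline compares combined and direct ridge per fold", {
  ep <- uniform_edge_params(5, 0.8, 0.9, 0.4)
  sp <- uniform_scale_params("asr", 5, 0.7, 0.7)
  pop <- generate_population(240, ep, sp, rho = 0.4, n_families = 120, seed = 98)
  panel <- generate_edge_panel(pop, seed = 99)
  phen <- generate_phenotype(pop, seed = 100)
  fams <- setNames(pop$subjects$family_id, pop$subjects$subject_id)
  res <- operative_pipeline(panel, phen, fams, folds = 4, seed = 101)
  expect_setequal(unique(res$method), c("operative_ridge", "direct_ridge"))
  expect_identical(nrow(res), 8L)  # 4 folds x 2 methods x 1 scale
  expect_true(all(res$n_edges_used <= 5))
  # the two routes track each other on well-specified data
  agg <- tapply(res$fisher_z, res$method, mean)
  expect_lt(abs(agg[["operative_ridge"]] - agg[["direct_ridge"]]), 0.2)
})
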