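# The ML covariance-structure engine: implied moments, degrees of freedom,
# fitting, fit indices and likelihood-ratio tests.

msst_truth <- c(lambda_s = 0.8, lambda_t = 0.9,
                theta1 = 0.36, theta2 = 0.36, theta3 = 0.36, theta4 = 0.36)

test_that("implied covariances match hand algebra for every family", {
  s1 <- implied_covariance(lst_model("single_trait"),
                           c(lambda = 0.7, theta1 = 0.51, theta2 = 0.51,
                             theta3 = 0.51, theta4 = 0.51))
  expect_equal(unname(diag(s1)), rep(1, 4))
  expect_equal(unname(s1[upper.tri(s1)]), rep(0.49, 6))

  sm <- implied_covariance(lst_model("msst"), msst_truth)
  expect_equal(sm[1, 2], 0.64)   # same day
  expect_equal(sm[3, 4], 0.64)
  expect_equal(sm[1, 3], 0.5184) # cross day: lambda_s^2 lambda_t^2
  expect_equal(unname(diag(sm)), rep(1, 4))

  # bi-factor parameterization g^2 = ls^2 lt^2, s^2 = ls^2 (1 - lt^2)
  sb <- implied_covariance(lst_model("bifactor"),
                           c(g = sqrt(0.5184), s = sqrt(0.64 * 0.19),
                             theta1 = 0.36, theta2 = 0.36, theta3 = 0.36,
                             theta4 = 0.36))
  expect_equal(unname(sb), unname(sm), tolerance = 1e-12)

  # method factor adds m^2 on same-order pairs (Q1,Q3), (Q2,Q4) and diagonal
  smm <- implied_covariance(lst_model("msst_method"), c(msst_truth, m = 0.3))
  expect_equal(smm[1, 3], 0.5184 + 0.09)
  expect_equal(smm[2, 4], 0.5184 + 0.09)
  expect_equal(smm[1, 4], 0.5184)
  expect_equal(smm[1, 2], 0.64)
  expect_equal(smm[1, 1], 1.09)

  sc <- implied_covariance(lst_model("congeneric", n_items = 3),
                           c(nu1 = 0.5, nu2 = 0.6, nu3 = 0.7,
                             theta1 = 0.75, theta2 = 0.64, theta3 = 0.51))
  expect_equal(sc[1, 2], 0.30)
  expect_equal(sc[2, 3], 0.42)
  expect_equal(unname(diag(sc)), c(1, 1, 1))
})

test_that("model degrees of freedom follow the moment-count arithmetic", {
  expect_identical(model_df(lst_model("single_trait")), 5L)
  expect_identical(model_df(lst_model("msst")), 4L)
  expect_identical(model_df(lst_model("bifactor")), 4L)
  expect_identical(model_df(lst_model("msst_method")), 3L)
  expect_identical(model_df(lst_model("congeneric", n_items = 7)), 14L)
  expect_identical(model_df(lst_model("congeneric", n_items = 3)), 0L)
  expect_identical(model_df(lst_model("congeneric", n_items = 12)), 54L)
  expect_error(lst_model("congeneric", n_items = 2), "at least 3")
})

test_that("a sample covariance equal to an implied covariance is fit perfectly", {
  spec <- lst_model("single_trait")
  s <- implied_covariance(spec, c(lambda = 0.7, theta1 = 0.51, theta2 = 0.51,
                                  theta3 = 0.51, theta4 = 0.51))
  fit <- ml_fit(spec, s, n = 500)
  expect_true(fit$converged)
  expect_lt(fit$chisq, 1e-5)
  expect_equal(unname(fit$estimates[["lambda"]]), 0.7, tolerance = 1e-3)
  expect_equal(unname(fit$estimates[["theta1"]]), 0.51, tolerance = 1e-3)
})

test_that("equal-loading fit on an exchangeable covariance puts lambda^2 at the mean off-diagonal", {
  # with a compound-symmetric sample covariance the ML optimum is symmetric,
  # so lambda^2 equals the common off-diagonal element exactly
  s <- matrix(0.37, 4, 4)
  diag(s) <- 0.95
  fit <- ml_fit(lst_model("single_trait"), s, n = 300)
  expect_equal(unname(fit$estimates[["lambda"]])^2, 0.37, tolerance = 1e-4)
  expect_lt(fit$chisq, 1e-6)
})

test_that("msst parameters are recovered from a large-sample draw", {
  spec <- lst_model("msst")
  sigma <- implied_covariance(spec, msst_truth)
  set.seed(42)
  x <- matrix(rnorm(1e5 * 4), ncol = 4) %*% chol(sigma)
  fit <- ml_fit(spec, cov(x), n = 1e5)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates[1:2]), c(0.8, 0.9), tolerance = 0.01)
  expect_equal(unname(fit$estimates[3:6]), rep(0.36, 4), tolerance = 0.01)
})

test_that("ml_fit matches an independent matrix-algebra Nelder-Mead oracle", {
  fams <- c("single_trait", "msst", "bifactor", "congeneric")
  for (i in 1:10) {
    fam <- fams[(i - 1) %% 4 + 1]
    prob <- random_problem(fam, seed = 100 + i, n = 150, k = 5)
    fit <- ml_fit(prob$spec, prob$s, prob$n)
    expect_true(fit$converged)
    oracle <- oracle_min_fml(fam, prob$s, k = 5)
    expect_equal(fit$fml, oracle, tolerance = 1e-4,
                 label = paste("fml for", fam, "problem", i))
    expect_gte(fit$fml, -1e-10)
  }
})

test_that("msst and bi-factor reach the same minimized discrepancy at interior optima", {
  for (i in 1:5) {
    prob <- random_problem("msst", seed = 200 + i, n = 300)
    f1 <- ml_fit(lst_model("msst"), prob$s, prob$n)
    f2 <- ml_fit(lst_model("bifactor"), prob$s, prob$n)
    if (!f1$boundary && !f2$boundary) {
      expect_equal(f1$fml, f2$fml, tolerance = 1e-5)
    }
  }
})

test_that("chi-square is invariant to congeneric indicator reordering", {
  prob <- random_problem("congeneric", seed = 321, n = 250, k = 5)
  perm <- c(3, 1, 5, 2, 4)
  f1 <- ml_fit(lst_model("congeneric", n_items = 5), prob$s, prob$n)
  f2 <- ml_fit(lst_model("congeneric", n_items = 5), prob$s[perm, perm], prob$n)
  expect_equal(f1$chisq, f2$chisq, tolerance = 1e-5)
})

test_that("fit indices follow their definitions", {
  spec <- lst_model("msst")
  sigma <- implied_covariance(spec, msst_truth)
  perfect <- ml_fit(spec, sigma, n = 400)
  idx <- fit_indices(perfect)
  expect_equal(idx$srmr, 0, tolerance = 1e-5)
  expect_equal(idx$rmsea, 0, tolerance = 1e-5)
  expect_equal(idx$cfi, 1)

  # hand arithmetic: chisq 20, df 4, n 201, baseline 200 on 6 df
  fake <- structure(list(spec = spec, chisq = 20, df = 4, n = 201,
                         s = sigma, implied = sigma, converged = TRUE),
                    class = "lst_fit")
  idx2 <- fit_indices(fake, baseline = list(chisq = 200, df = 6))
  expect_equal(idx2$rmsea, sqrt(16 / 800), tolerance = 1e-12)
  expect_equal(idx2$cfi, 1 - 16 / 194, tolerance = 1e-12)

  # chisq = df clamps RMSEA at zero
  fake$chisq <- 4
  expect_equal(fit_indices(fake, baseline = list(chisq = 200, df = 6))$rmsea, 0)
})

test_that("likelihood-ratio test compares nested fits on the chi-square scale", {
  spec_n <- lst_model("single_trait")
  spec_f <- lst_model("msst")
  fake <- function(spec, chisq) {
    structure(list(spec = spec, chisq = chisq, df = model_df(spec),
                   converged = TRUE), class = "lst_fit")
  }
  out <- lrt(fake(spec_n, 20), fake(spec_f, 8))
  expect_equal(out$delta_chisq, 12)
  expect_equal(out$delta_df, 1)
  expect_lt(out$p_value, 0.001)  # 12 exceeds the 10.83 critical value

  same <- lrt(fake(spec_n, 8), fake(spec_f, 8))
  expect_equal(same$delta_chisq, 0)
  expect_equal(same$p_value, 1)

  expect_warning(neg <- lrt(fake(spec_n, 5), fake(spec_f, 8)), "negative")
  expect_equal(neg$delta_chisq, 0)
  expect_true(neg$negative)
})

test_that("the chi-square(1) upper-tail critical value at p = .001 is 10.83", {
  expect_equal(round(qchisq(0.999, df = 1), 2), 10.83)
})

test_that("boundary solutions are flagged", {
  # data with essentially no common variance forces loadings to the floor
  s <- diag(4) * 0.8
  fit <- ml_fit(lst_model("single_trait"), s, n = 200)
  expect_true(fit$converged)
  expect_true(fit$boundary)
})
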