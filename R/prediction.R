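# SEM-informed prediction: factor-score estimation (regression and Bartlett
# weights) with validity coefficients, closed-form ridge regression with
# nested cross-validation, the four-variant repeated split-half experiment,
# and operative (conditional-normal) prediction under family-aware folds.

# Effective loadings of the indicators on the target (trait/general) factor.
trait_loadings <- function(fit) {
  est <- fit$estimates
  switch(fit$spec$family,
    single_trait = rep(est[["lambda"]], 4),
    msst = , msst_method = rep(est[["lambda_s"]] * est[["lambda_t"]], 4),
    bifactor = rep(est[["g"]], 4),
    congeneric = unname(est[paste0("nu", seq_len(fit$spec$n_items))]),
    stop("no trait loadings for family ", fit$spec$family))
}

#' Factor scores and validity coefficient from a fitted measurement model
#'
#' Computes per-subject estimates of the latent trait/general factor from the
#' centered indicators, by either the regression (Thurstone) method - weights
#' `Sigma^-1 Lambda` with model-implied validity
#' `sqrt(Lambda' Sigma^-1 Lambda)` (unit factor variance) - or the Bartlett
#' method - weights `(Lambda' U^-1 Lambda)^-1 Lambda' U^-1` with
#' `U = Sigma - Lambda Lambda'` the residual covariance given the factor,
#' which is conditionally unbiased, with validity
#' `sqrt(d / (1 + d))` for `d = Lambda' U^-1 Lambda`. The validity
#' coefficient is the model-implied correlation between the factor and its
#' score estimate; values above 0.80 are conventionally recommended (0.90
#' preferable) for use in subsequent analyses.
#'
#' @param fit a converged [ml_fit()] result (measurement family).
#' @param data n x p matrix of raw indicator values (same order as the fit's
#'   indicators).
#' @param method `"regression"` or `"bartlett"`.
#' @return list of class `lst_factor_scores`: `scores` (length n), `weights`,
#'   `validity`, `method`.
#' @export
factor_scores <- function(fit, data, method = c("regression", "bartlett")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "lst_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  data <- as.matrix(data)
  lam <- trait_loadings(fit)
  if (ncol(data) != length(lam)) stop("data has wrong number of indicators")
  sigma <- fit$implied
  centered <- sweep(data, 2, colMeans(data))
  if (method == "regression") {
    w <- tryCatch(solve(sigma, lam), error = function(e)
      stop("implied covariance is singular"))
    validity <- sqrt(min(sum(lam * w), 1))
  } else {
    u <- sigma - tcrossprod(lam)
    a <- tryCatch(solve(u, lam), error = function(e)
      stop("residual covariance is singular"))
    d <- sum(lam * a)
    if (d <= 0) stop("non-positive Bartlett information")
    w <- a / d
    validity <- sqrt(d / (1 + d))
  }
  structure(list(scores = drop(centered %*% w), weights = w,
                 validity = validity, method = method),
            class = "lst_factor_scores")
}

#' Gate factor-score sets on their validity coefficient
#'
#' @param validities named numeric vector of validity coefficients (one per
#'   construct, e.g. per edge).
#' @param threshold minimum acceptable validity (default 0.80).
#' @return list with `retained` and `flagged` construct names.
#' @export
validity_gate <- function(validities, threshold = 0.80) {
  flagged <- names(validities)[is.na(validities) | validities < threshold]
  list(retained = setdiff(names(validities), flagged), flagged = flagged)
}

# Standardize columns on the given statistics; zero-variance columns map to
# zero so excluded/imputed predictors contribute nothing.
scale_cols <- function(x, center, scale) {
  scale[scale == 0 | !is.finite(scale)] <- 1
  sweep(sweep(x, 2, center), 2, scale, "/")
}

ridge_solve <- function(xs, yc, alpha) {
  p <- ncol(xs)
  solve(crossprod(xs) + diag(alpha, p), crossprod(xs, yc))
}

#' Ridge regression with nested cross-validation over the penalty
#'
#' Closed-form ridge on training-standardized predictors; the penalty `alpha`
#' is selected by inner cross-validated mean squared error over a log-spaced
#' grid spanning 1e3 to 1e7 (9 points by default), then the model is refit on
#' the full training split. Ties favor the larger penalty. Standardization
#' statistics come from the training data only; zero-variance predictor
#' columns (e.g. zero-imputed edges) are inert.
#'
#' @param x n x p predictor matrix.
#' @param y response vector (non-constant).
#' @param alpha_grid penalty grid.
#' @param inner_folds number of inner folds (>= 2).
#' @param seed RNG seed for the inner fold assignment.
#' @return object of class `lst_ridge` with the chosen `alpha`,
#'   coefficients, and standardization statistics; see
#'   [predict.lst_ridge()].
#' @export
ridge_cv <- function(x, y, alpha_grid = 10^seq(3, 7, length.out = 9),
                     inner_folds = 5, seed = 1) {
  x <- as.matrix(x)
  if (length(alpha_grid) == 0) stop("alpha grid must be non-empty")
  if (inner_folds < 2) stop("need at least 2 inner folds")
  if (stats::sd(y) == 0) stop("constant response")
  n <- nrow(x)
  folds <- with_seed(seed, sample(rep_len(seq_len(inner_folds), n)))
  mse <- matrix(NA_real_, inner_folds, length(alpha_grid))
  for (f in seq_len(inner_folds)) {
    tr <- folds != f
    ctr <- colMeans(x[tr, , drop = FALSE])
    scl <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    xs <- scale_cols(x[tr, , drop = FALSE], ctr, scl)
    xt <- scale_cols(x[!tr, , drop = FALSE], ctr, scl)
    ym <- mean(y[tr]); yc <- y[tr] - ym
    for (a in seq_along(alpha_grid)) {
      beta <- ridge_solve(xs, yc, alpha_grid[a])
      pred <- drop(xt %*% beta) + ym
      mse[f, a] <- mean((y[!tr] - pred)^2)
    }
  }
  m <- colMeans(mse)
  best <- max(which(m <= min(m) + 1e-12))  # tie -> larger penalty
  ctr <- colMeans(x); scl <- apply(x, 2, stats::sd)
  xs <- scale_cols(x, ctr, scl)
  ym <- mean(y)
  beta <- ridge_solve(xs, y - ym, alpha_grid[best])
  structure(list(alpha = alpha_grid[best], beta = drop(beta), center = ctr,
                 scale = scl, y_mean = ym, alpha_grid = alpha_grid,
                 inner_mse = m), class = "lst_ridge")
}

#' Predict from a fitted ridge model
#'
#' @param object an [ridge_cv()] fit.
#' @param newdata matrix of predictors in training column order.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.lst_ridge <- function(object, newdata, ...) {
  xs <- scale_cols(as.matrix(newdata), object$center, object$scale)
  drop(xs %*% object$beta) + object$y_mean
}

#' Coefficient of determination from sums of squares
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`; ranges over (-Inf, 1] and
#' does not generally equal the squared Pearson correlation.
#'
#' @param y true values (non-constant, length >= 3).
#' @param yhat predicted values.
#' @return R-squared value.
#' @export
metric_r2 <- function(y, yhat) {
  if (length(y) < 3) stop("need at least 3 observations")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("constant response")
  1 - sum((y - yhat)^2) / sst
}

#' Fisher-z transformed Pearson correlation of prediction and truth
#'
#' @param y true values.
#' @param yhat predicted values (both non-constant).
#' @return `atanh(r)`, clipped at `atanh(1 - 1e-7)`.
#' @export
metric_fisher_z <- function(y, yhat) {
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    stop("correlation undefined for constant input")
  }
  unname(fisher_z(stats::cor(y, yhat)))
}

#' Family-aware fold assignment
#'
#' Assigns whole families to folds greedily (largest family first, ties and
#' order seed-shuffled, always into the currently smallest fold) so that no
#' family is split across folds and fold sizes stay balanced.
#'
#' @param families character vector of family labels, one per subject.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold id per subject (same order as `families`).
#' @export
make_family_folds <- function(families, k = 10, seed = 1) {
  fam_ids <- unique(families)
  if (length(fam_ids) < k) stop("fewer families than folds")
  sizes <- table(families)
  with_seed(seed, {
    ord <- sample(fam_ids)
    ord <- ord[order(-sizes[ord])]
    fold_of <- integer(0)
    load <- integer(k)
    for (f in ord) {
      tgt <- which.min(load)
      fold_of[f] <- tgt
      load[tgt] <- load[tgt] + sizes[[f]]
    }
    unname(fold_of[families])
  })
}

# Metrics that degrade to NA (e.g. all predictors zero-imputed -> constant
# predictions) instead of erroring inside long experiment loops.
safe_fisher_z <- function(y, yhat) {
  tryCatch(metric_fisher_z(y, yhat), error = function(e) NA_real_)
}
safe_r2 <- function(y, yhat) {
  tryCatch(metric_r2(y, yhat), error = function(e) NA_real_)
}

# Fit the msst CFA for one edge on a subject x 4 matrix and return regression
# factor scores, or NULL when the model fails selection (callers zero-impute).
# Validity is reported for gating by the caller.
edge_scores_or_null <- function(q, thresholds) {
  fit <- ml_fit(lst_model("msst"), stats::cov(q), nrow(q))
  if (!isTRUE(fit$converged)) return(NULL)
  if (!select_model(fit, thresholds = thresholds)$pass) return(NULL)
  tryCatch(factor_scores(fit, q, "regression"), error = function(e) NULL)
}

#' Repeated split-half factor-score prediction experiment
#'
#' For each repeat the (unrelated) subjects are split into random halves and
#' each half serves once as training set. Measurement models are fitted in
#' the training and test halves independently; edges whose multistate
#' single-trait model fails selection in either half are zero-imputed.
#' Validity coefficients are computed per edge and gated with
#' [validity_gate()]; by default edges below the gate are flagged and
#' counted (the operative exclusion being the network filter), with
#' `validity_action = "exclude"` additionally zero-imputing them. Four
#' ridge-regression variants are evaluated per phenotype scale: average
#' scores or regression factor scores of the edges as predictors, crossed
#' with sum scores or Bartlett factor scores of the phenotype as target.
#'
#' @param panel edge panel (unrelated subjects).
#' @param phenotypes an `lst_phenotype_panel` for the same subjects.
#' @param repeats number of split-half repeats.
#' @param seed RNG seed governing splits and inner CV.
#' @param scales scales to evaluate (default: all in the panel).
#' @param exclude_networks edges whose network pair mentions any of these
#'   labels are dropped before modeling.
#' @param validity_threshold factor-score validity gate.
#' @param thresholds measurement selection thresholds.
#' @param alpha_grid,inner_folds ridge settings, see [ridge_cv()].
#' @param min_n smallest permissible half size.
#' @param splits optional list (length `repeats`) of logical vectors
#'   pre-assigning subjects to the first half, overriding the random splits.
#' @param diagnostics if `TRUE`, attach per-fold fitted objects for
#'   leakage auditing.
#' @return long data frame: `method` (avg_to_sum, fs_to_sum, avg_to_fs,
#'   fs_to_fs), `scale_id`, `repeat_`, `fold`, `fisher_z`, `r_squared`,
#'   `n_edges`, `n_zero_imputed`.
#' @export
split_half_experiment <- function(panel, phenotypes, repeats = 10, seed = 1,
                                  scales = NULL,
                                  exclude_networks = c("limbic", "subcortex"),
                                  validity_threshold = 0.80,
                                  validity_action = c("flag", "exclude"),
                                  thresholds = selection_thresholds(),
                                  alpha_grid = 10^seq(3, 7, length.out = 9),
                                  inner_folds = 5, min_n = 100,
                                  splits = NULL, diagnostics = FALSE) {
  stopifnot(inherits(phenotypes, "lst_phenotype_panel"))
  validity_action = match.arg(validity_action)
  scales <- scales %||% names(phenotypes$items)
  if (length(exclude_networks) > 0 && !all(is.na(panel$network_pair))) {
    drop <- Reduce(`|`, lapply(exclude_networks, function(nw)
      grepl(nw, panel$network_pair, fixed = TRUE)))
    panel <- panel[!drop, , drop = FALSE]
  }
  subj <- sort(unique(panel$subject_id))
  n <- length(subj)
  if (n < 2 * min_n) {
    stop("too few subjects for split-half CFA (need at least ", 2 * min_n, ")")
  }
  edge_ids <- sort(unique(panel$edge_id))
  # subject x edge matrices of each indicator and of the mean
  wide <- function(col) {
    m <- matrix(NA_real_, n, length(edge_ids),
                dimnames = list(subj, edge_ids))
    m[cbind(match(panel$subject_id, subj), match(panel$edge_id, edge_ids))] <-
      panel[[col]]
    m
  }
  q_arr <- lapply(paste0("rsfc_q", 1:4), wide)
  mean_z <- wide("mean_z")

  half_assignments <- with_seed(seed, {
    lapply(seq_len(repeats), function(i) {
      if (!is.null(splits)) return(splits[[i]])
      a <- logical(n); a[sample.int(n, floor(n / 2))] <- TRUE
      a
    })
  })
  inner_seed <- function(r, f, v) ((seed + 7L * r + 13L * f + 29L * v) %% 100000L) + 1L

  half_model <- function(idx) {
    # per-edge CFA + factor scores within one half; NULL entries are failures
    scores <- matrix(0, sum(idx), length(edge_ids),
                     dimnames = list(subj[idx], edge_ids))
    ok <- logical(length(edge_ids))
    validity <- rep(NA_real_, length(edge_ids))
    for (e in seq_along(edge_ids)) {
      q <- vapply(q_arr, function(m) m[idx, e], numeric(sum(idx)))
      fs <- edge_scores_or_null(q, thresholds)
      if (!is.null(fs)) {
        scores[, e] <- fs$scores
        ok[e] <- TRUE
        validity[e] <- fs$validity
      }
    }
    names(validity) <- edge_ids
    phen <- lapply(scales, function(sid) {
      it <- phenotypes$items[[sid]][match(subj[idx], phenotypes$sum_scores$subject_id), ,
                                    drop = FALSE]
      fit <- ml_fit(lst_model("congeneric", n_items = ncol(it)),
                    stats::cov(it), nrow(it))
      if (!isTRUE(fit$converged)) return(NULL)
      tryCatch(factor_scores(fit, it, "bartlett"), error = function(e) NULL)
    })
    names(phen) <- scales
    list(scores = scores, ok = ok, validity = validity, phen = phen)
  }

  out <- list()
  diag_store <- list()
  for (r in seq_len(repeats)) {
    first <- half_assignments[[r]]
    for (fold in 1:2) {
      tr_idx <- if (fold == 1) first else !first
      te_idx <- !tr_idx
      if (sum(tr_idx) < min_n || sum(te_idx) < min_n) {
        stop("half too small for CFA (n < ", min_n, ")")
      }
      tr <- half_model(tr_idx)
      te <- half_model(te_idx)
      both_ok <- tr$ok & te$ok
      gate <- validity_gate(tr$validity, validity_threshold)
      if (validity_action == "exclude") {
        both_ok <- both_ok & !(edge_ids %in% gate$flagged)
      }
      # zero-impute edges failing in either half
      x_fs_tr <- tr$scores; x_fs_tr[, !both_ok] <- 0
      x_fs_te <- te$scores; x_fs_te[, !both_ok] <- 0
      x_avg_tr <- mean_z[tr_idx, , drop = FALSE]
      x_avg_te <- mean_z[te_idx, , drop = FALSE]
      for (sid in scales) {
        if (is.null(tr$phen[[sid]]) || is.null(te$phen[[sid]])) next
        ysum_tr <- phenotypes$sum_scores[[sid]][
          match(subj[tr_idx], phenotypes$sum_scores$subject_id)]
        ysum_te <- phenotypes$sum_scores[[sid]][
          match(subj[te_idx], phenotypes$sum_scores$subject_id)]
        targets <- list(sum = list(tr = ysum_tr, te = ysum_te),
                        fs = list(tr = tr$phen[[sid]]$scores,
                                  te = te$phen[[sid]]$scores))
        preds <- list(avg = list(tr = x_avg_tr, te = x_avg_te),
                      fs = list(tr = x_fs_tr, te = x_fs_te))
        v <- 0L
        for (pn in names(preds)) for (tn in names(targets)) {
          v <- v + 1L
          rg <- ridge_cv(preds[[pn]]$tr, targets[[tn]]$tr, alpha_grid,
                         inner_folds, seed = inner_seed(r, fold, v))
          yhat <- predict(rg, preds[[pn]]$te)
          out[[length(out) + 1L]] <- data.frame(
            method = paste0(pn, "_to_", tn), scale_id = sid,
            repeat_ = r, fold = fold,
            fisher_z = safe_fisher_z(targets[[tn]]$te, yhat),
            r_squared = safe_r2(targets[[tn]]$te, yhat),
            n_edges = length(edge_ids), n_zero_imputed = sum(!both_ok),
            n_below_validity = length(gate$flagged),
            mean_validity = mean(tr$validity, na.rm = TRUE))
          if (diagnostics) {
            diag_store[[length(diag_store) + 1L]] <- list(
              repeat_ = r, fold = fold, method = paste0(pn, "_to_", tn),
              scale_id = sid, alpha = rg$alpha, beta = rg$beta)
          }
        }
      }
    }
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  if (diagnostics) attr(res, "diagnostics") <- diag_store
  res
}

#' Operative prediction from model-implied moments
#'
#' Conditional-normal prediction of the response indicators from a new
#' subject's predictor indicators:
#' `yhat = mu_y + Sigma_xy' Sigma_xx^-1 (x0 - mu_x)`, with all moments taken
#' from the fitted model (saturated mean structure, so the implied means are
#' the sample means). With a saturated covariance model this reduces to
#' ordinary least-squares prediction.
#'
#' @param fit a converged joint-family [ml_fit()] with `mean_structure`, or
#'   any `lst_fit`-like object with `implied` and `means` plus explicit
#'   `x_idx`/`y_idx`.
#' @param x0 matrix (or vector) of new predictor observations.
#' @param x_idx,y_idx integer indices of predictor and response variables in
#'   the fit's indicator order; defaulted from a joint spec (predictors =
#'   the four scan indicators, responses = the phenotype items).
#' @return matrix of predicted response indicator values.
#' @export
operative_predict <- function(fit, x0, x_idx = NULL, y_idx = NULL) {
  if (is.null(fit$implied) || is.null(fit$means)) {
    stop("operative prediction needs a converged fit with mean structure")
  }
  if (is.null(x_idx)) {
    if (!identical(fit$spec$family, "joint")) {
      stop("x_idx/y_idx required for non-joint fits")
    }
    x_idx <- 1:4
    y_idx <- 4 + seq_len(fit$spec$n_items)
  }
  x0 <- if (is.null(dim(x0))) matrix(x0, nrow = 1) else as.matrix(x0)
  sxx <- fit$implied[x_idx, x_idx, drop = FALSE]
  sxy <- fit$implied[x_idx, y_idx, drop = FALSE]
  w <- tryCatch(solve(sxx, sxy), error = function(e)
    stop("singular predictor covariance"))
  mu_x <- fit$means[x_idx]
  mu_y <- fit$means[y_idx]
  sweep(sweep(x0, 2, mu_x) %*% w, 2, mu_y, "+")
}

#' Saturated joint moments for operative prediction
#'
#' Wraps the sample moments of a data matrix as a fit object usable with
#' [operative_predict()]; predictions then equal ordinary least squares.
#'
#' @param data n x p matrix.
#' @return minimal fit-like list with `implied` (sample covariance) and
#'   `means`.
#' @export
saturated_fit <- function(data) {
  data <- as.matrix(data)
  list(spec = list(family = "saturated"), implied = stats::cov(data),
       means = colMeans(data), converged = TRUE)
}

# Joint fit plus the exclusion rules used for association/operative work.
joint_fit_checked <- function(q, items, thresholds = selection_thresholds(),
                              mean_structure = FALSE) {
  n <- nrow(q)
  k <- ncol(items)
  reasons <- character(0)
  m_fit <- ml_fit(lst_model("msst"), stats::cov(q), n)
  if (!select_model(m_fit, thresholds = thresholds)$pass) {
    reasons <- c(reasons, "rsfc_model_failed")
  }
  obs <- cbind(q, items)
  spec <- lst_model("joint", n_items = k, mean_structure = mean_structure)
  fit <- ml_fit(spec, stats::cov(obs), n,
                means = if (mean_structure) colMeans(obs))
  if (!isTRUE(fit$converged)) {
    reasons <- c(reasons, "joint_non_convergence")
  } else {
    psi <- fit$estimates[["psi"]]
    if (abs(psi) >= 1) reasons <- c(reasons, "improper_structural_correlation")
    nu <- fit$estimates[paste0("nu", seq_len(k))]
    nu_std <- nu / sqrt(diag(fit$implied)[4 + seq_len(k)])
    if (any(nu_std < 0 | nu_std > 1)) {
      reasons <- c(reasons, "phenotype_loading_outside_0_1")
    }
  }
  list(fit = fit, pass = length(reasons) == 0, reasons = reasons)
}

#' Operative prediction pipeline under family-aware cross-validation
#'
#' For each fold (families never split across train and test): per retained
#' edge, the joint structural model with saturated means is fitted on the
#' training subjects and each test (and training) subject's phenotype
#' indicators are predicted from their four scan indicators by
#' [operative_predict()]; indicator predictions are summed to a predicted
#' scale score. A ridge regression over the per-edge predicted scores
#' (trained on the training split) collapses them to one prediction per
#' subject, and is compared against a direct ridge on the per-edge 4-scan
#' mean z values.
#'
#' @param panel edge panel.
#' @param phenotypes `lst_phenotype_panel` for the same subjects.
#' @param families family label per subject (named by subject id).
#' @param scales scales to evaluate.
#' @param folds number of folds.
#' @param seed RNG seed.
#' @param exclude_networks network filter, as in [split_half_experiment()].
#' @param thresholds measurement selection thresholds.
#' @param alpha_grid,inner_folds ridge settings.
#' @return long data frame: `method` (operative_ridge, direct_ridge),
#'   `scale_id`, `fold`, `fisher_z`, `r_squared`, `n_edges_used`.
#' @export
operative_pipeline <- function(panel, phenotypes, families, scales = NULL,
                               folds = 10, seed = 1,
                               exclude_networks = c("limbic", "subcortex"),
                               thresholds = selection_thresholds(),
                               alpha_grid = 10^seq(3, 7, length.out = 9),
                               inner_folds = 5) {
  stopifnot(inherits(phenotypes, "lst_phenotype_panel"))
  scales <- scales %||% names(phenotypes$items)
  if (length(exclude_networks) > 0 && !all(is.na(panel$network_pair))) {
    drop <- Reduce(`|`, lapply(exclude_networks, function(nw)
      grepl(nw, panel$network_pair, fixed = TRUE)))
    panel <- panel[!drop, , drop = FALSE]
  }
  subj <- sort(unique(panel$subject_id))
  fam <- families[subj]
  if (any(is.na(fam))) stop("family labels missing for some subjects")
  fold_id <- make_family_folds(fam, k = folds, seed = seed)
  edge_ids <- sort(unique(panel$edge_id))
  wide <- function(col) {
    m <- matrix(NA_real_, length(subj), length(edge_ids),
                dimnames = list(subj, edge_ids))
    m[cbind(match(panel$subject_id, subj), match(panel$edge_id, edge_ids))] <-
      panel[[col]]
    m
  }
  q_arr <- lapply(paste0("rsfc_q", 1:4), wide)
  mean_z <- wide("mean_z")
  out <- list()
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    te <- !tr
    for (sid in scales) {
      it <- phenotypes$items[[sid]][
        match(subj, phenotypes$sum_scores$subject_id), , drop = FALSE]
      y <- phenotypes$sum_scores[[sid]][
        match(subj, phenotypes$sum_scores$subject_id)]
      op_tr <- list(); op_te <- list()
      for (e in seq_along(edge_ids)) {
        q_tr <- vapply(q_arr, function(m) m[tr, e], numeric(sum(tr)))
        jf <- joint_fit_checked(q_tr, it[tr, , drop = FALSE], thresholds,
                                mean_structure = TRUE)
        if (!jf$pass) next
        q_te <- vapply(q_arr, function(m) m[te, e], numeric(sum(te)))
        op_tr[[edge_ids[e]]] <- rowSums(operative_predict(jf$fit, q_tr))
        op_te[[edge_ids[e]]] <- rowSums(operative_predict(jf$fit, q_te))
      }
      n_used <- length(op_tr)
      add_row <- function(method, z, r2) {
        out[[length(out) + 1L]] <<- data.frame(
          method = method, scale_id = sid, fold = f, fisher_z = z,
          r_squared = r2, n_edges_used = n_used)
      }
      if (n_used > 0) {
        x_tr <- do.call(cbind, op_tr)
        x_te <- do.call(cbind, op_te)
        rg <- ridge_cv(x_tr, y[tr], alpha_grid, inner_folds,
                       seed = seed + f)
        yhat <- predict(rg, x_te)
        add_row("operative_ridge", safe_fisher_z(y[te], yhat),
                safe_r2(y[te], yhat))
      } else {
        add_row("operative_ridge", NA_real_, NA_real_)
      }
      rg0 <- ridge_cv(mean_z[tr, , drop = FALSE], y[tr], alpha_grid,
                      inner_folds, seed = seed + f)
      yhat0 <- predict(rg0, mean_z[te, , drop = FALSE])
      add_row("direct_ridge", safe_fisher_z(y[te], yhat0),
              safe_r2(y[te], yhat0))
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
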