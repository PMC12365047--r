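# Measurement-model layer: the four RSFC model families, the congeneric
# phenotype model, model selection rules, variance decomposition, and omega
# composite reliability.

#' Build an RSFC measurement model
#'
#' Convenience constructor for the four-indicator scan models: `single_trait`
#' (baseline, no state effects), `msst` (multistate single-trait: day factors
#' plus a second-order trait), `msst_method` (adds orthogonal within-day
#' order factors with one shared loading), and `bifactor` (general factor
#' plus orthogonal day factors).
#'
#' @param family model family name.
#' @return an [lst_model()].
#' @export
build_rsfc_model <- function(family = c("msst", "single_trait",
                                        "msst_method", "bifactor")) {
  lst_model(match.arg(family))
}

#' Build a congeneric phenotype measurement model
#'
#' One latent factor with `k` indicators; loadings vary freely across
#' indicators (congenericity) and residual variances are free. `k = 3` is
#' just-identified (df = 0).
#'
#' @param k number of indicators (>= 3).
#' @return an [lst_model()].
#' @export
build_phenotype_model <- function(k) {
  lst_model("congeneric", n_items = k)
}

#' Default model-selection thresholds
#'
#' Fit-index cutoffs (SRMR < 0.08, RMSEA < 0.08, CFI > 0.90) and the
#' standardized-loading windows for the multistate single-trait family:
#' first-order (state) loading within \[0.40, 0.90\] and second-order (trait)
#' loading within \[0.70, 1.00\].
#'
#' @return named list of thresholds.
#' @export
selection_thresholds <- function() {
  list(srmr = 0.08, rmsea = 0.08, cfi = 0.90,
       lambda_s_min = 0.40, lambda_s_max = 0.90,
       lambda_t_min = 0.70, lambda_t_max = 1.00)
}

# Standardized first-order loading of an msst-family fit: lambda_s scaled by
# the implied indicator standard deviations (averaged over the four scans).
# The trait loading lambda_t is already standardized (unit state and trait
# variances).
standardized_loadings <- function(fit) {
  est <- fit$estimates
  fam <- fit$spec$family
  if (!fam %in% c("msst", "msst_method")) return(NULL)
  sds <- sqrt(diag(fit$implied)[1:4])
  list(lambda_s = mean(est[["lambda_s"]] / sds),
       lambda_t = est[["lambda_t"]])
}

#' Apply the model-selection rules to a fitted measurement model
#'
#' A model passes when it converged, all global fit indices are inside their
#' cutoffs, and (for the multistate single-trait family) the standardized
#' first-order loading lies in \[0.40, 0.90\] and the second-order loading in
#' \[0.70, 1.00\]. Failures are enumerated as machine-readable reasons, so the
#' verdict doubles as an exclusion log entry.
#'
#' @param fit an [ml_fit()] result.
#' @param indices optional precomputed [fit_indices()]; computed if missing.
#' @param thresholds see [selection_thresholds()].
#' @return list with `pass` (flag) and `reasons` (character vector, empty on
#'   pass).
#' @export
select_model <- function(fit, indices = NULL, thresholds = selection_thresholds()) {
  stopifnot(inherits(fit, "lst_fit"))
  reasons <- character(0)
  if (!isTRUE(fit$converged)) {
    return(list(pass = FALSE, reasons = "non_convergence"))
  }
  indices <- indices %||% fit_indices(fit)
  if (!is.na(indices$srmr) && indices$srmr >= thresholds$srmr) {
    reasons <- c(reasons, sprintf("srmr_ge_%.2f", thresholds$srmr))
  }
  if (!is.na(indices$rmsea) && indices$rmsea >= thresholds$rmsea) {
    reasons <- c(reasons, sprintf("rmsea_ge_%.2f", thresholds$rmsea))
  }
  if (!is.na(indices$cfi) && indices$cfi <= thresholds$cfi) {
    reasons <- c(reasons, sprintf("cfi_le_%.2f", thresholds$cfi))
  }
  sl <- standardized_loadings(fit)
  if (!is.null(sl)) {
    if (sl$lambda_s > thresholds$lambda_s_max) {
      reasons <- c(reasons, "first_order_loading_gt_0.90")
    }
    if (sl$lambda_s < thresholds$lambda_s_min) {
      reasons <- c(reasons, "first_order_loading_lt_0.40")
    }
    if (sl$lambda_t > thresholds$lambda_t_max) {
      reasons <- c(reasons, "second_order_loading_gt_1")
    }
    if (sl$lambda_t < thresholds$lambda_t_min) {
      reasons <- c(reasons, "second_order_loading_lt_0.70")
    }
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Trait/state/error variance decomposition of a multistate single-trait fit
#'
#' Splits each indicator's modeled variance `sigma2_i = lambda_s^2 + theta_i`
#' (plus `m^2` with method factors) into common consistency (trait share,
#' `lambda_s^2 lambda_t^2 / sigma2_i`), occasion specificity (state share,
#' `lambda_s^2 (1 - lambda_t^2) / sigma2_i`), and random error
#' (`theta_i / sigma2_i`). Without method factors the three shares sum to 1.
#' Edge-level values are the means over the four indicators.
#'
#' @param fit a converged msst or msst_method [ml_fit()].
#' @return list with `per_indicator` (data frame: indicator,
#'   common_consistency, occasion_specificity, random_error, method_share)
#'   and `means` (named vector of the three shares averaged over indicators).
#' @examples
#' spec <- lst_model("msst")
#' truth <- c(lambda_s = 0.8, lambda_t = 0.9, theta1 = 0.36, theta2 = 0.36,
#'            theta3 = 0.36, theta4 = 0.36)
#' fit <- ml_fit(spec, implied_covariance(spec, truth), n = 400)
#' decompose_variance(fit)$means  # CC 0.5184, OS 0.1216, ER 0.36
#' @export
decompose_variance <- function(fit) {
  stopifnot(inherits(fit, "lst_fit"))
  if (!isTRUE(fit$converged)) stop("cannot decompose a non-converged fit")
  fam <- fit$spec$family
  if (!fam %in% c("msst", "msst_method")) {
    stop("variance decomposition requires an msst or msst_method fit")
  }
  est <- fit$estimates
  ls2 <- est[["lambda_s"]]^2
  lt2 <- est[["lambda_t"]]^2
  m2 <- if (fam == "msst_method") est[["m"]]^2 else 0
  theta <- est[paste0("theta", 1:4)]
  sigma2 <- ls2 + m2 + theta
  per <- data.frame(
    indicator = paste0("q", 1:4),
    common_consistency = ls2 * lt2 / sigma2,
    occasion_specificity = ls2 * (1 - lt2) / sigma2,
    random_error = theta / sigma2,
    method_share = m2 / sigma2,
    row.names = NULL)
  means <- c(common_consistency = mean(per$common_consistency),
             occasion_specificity = mean(per$occasion_specificity),
             random_error = mean(per$random_error))
  list(per_indicator = per, means = means)
}

#' Omega composite reliability of a congeneric fit
#'
#' `omega = (sum nu_j)^2 / ((sum nu_j)^2 + sum theta_j)`: the ratio of
#' true-score variance of the unit-weighted sum score to its total variance
#' under the fitted congeneric model. Values above 0.70 are conventionally
#' considered adequate.
#'
#' @param fit a converged congeneric [ml_fit()].
#' @return omega value with attribute `mixed_sign` flagging loadings of mixed
#'   sign (the unweighted sum may then understate reliability).
#' @export
omega_reliability <- function(fit) {
  stopifnot(inherits(fit, "lst_fit"))
  if (!isTRUE(fit$converged)) stop("cannot compute omega for a non-converged fit")
  if (fit$spec$family != "congeneric") {
    stop("omega is defined for congeneric fits")
  }
  k <- fit$spec$n_items
  nu <- fit$estimates[paste0("nu", seq_len(k))]
  theta <- fit$estimates[paste0("theta", seq_len(k))]
  om <- sum(nu)^2 / (sum(nu)^2 + sum(theta))
  if (any(nu > 0) && any(nu < 0)) attr(om, "mixed_sign") <- TRUE
  om
}

#' Fit a measurement model to every edge of an edge panel
#'
#' Splits the panel by edge, fits the requested family to each edge's
#' four-indicator sample covariance, applies the selection rules, and (for
#' the msst families) appends the variance decomposition. This is the
#' per-edge engine behind the measurement and report pipeline stages.
#'
#' @param panel edge panel data frame with columns `subject_id`, `edge_id`,
#'   `network_pair`, `rsfc_q1` .. `rsfc_q4`.
#' @param family model family, see [build_rsfc_model()].
#' @param thresholds selection thresholds, see [selection_thresholds()].
#' @return data frame with one row per edge: estimates, chi-square, df, fit
#'   indices, pass flag, comma-joined reasons, and (msst) CC/OS/ER means.
#' @export
fit_edge_panel <- function(panel, family = "msst",
                           thresholds = selection_thresholds()) {
  needed <- c("subject_id", "edge_id", paste0("rsfc_q", 1:4))
  if (!all(needed %in% names(panel))) {
    stop("edge panel must have columns: ", paste(needed, collapse = ", "))
  }
  spec <- build_rsfc_model(family)
  rows <- lapply(split(panel, panel$edge_id), function(ed) {
    y <- as.matrix(ed[, paste0("rsfc_q", 1:4)])
    fit <- ml_fit(spec, stats::cov(y), n = nrow(y))
    out <- data.frame(edge_id = ed$edge_id[1],
                      network_pair = if ("network_pair" %in% names(ed))
                        ed$network_pair[1] else NA_character_,
                      family = family, n = nrow(y),
                      converged = fit$converged, stringsAsFactors = FALSE)
    if (fit$converged) {
      idx <- fit_indices(fit)
      verdict <- select_model(fit, idx, thresholds)
      est <- as.list(fit$estimates)
      out <- cbind(out, as.data.frame(est),
                   data.frame(chisq = fit$chisq, df = fit$df,
                              srmr = idx$srmr, rmsea = idx$rmsea,
                              cfi = idx$cfi, boundary = fit$boundary,
                              pass = verdict$pass,
                              reasons = paste(verdict$reasons, collapse = ",")))
      if (family %in% c("msst", "msst_method")) {
        dec <- decompose_variance(fit)$means
        out$common_consistency <- dec[["common_consistency"]]
        out$occasion_specificity <- dec[["occasion_specificity"]]
        out$random_error <- dec[["random_error"]]
      }
    } else {
      out$pass <- FALSE
      out$reasons <- "non_convergence"
    }
    out
  })
  res <- rbind_fill(rows)
  res[order(res$edge_id), , drop = FALSE]
}
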