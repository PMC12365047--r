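# Seeded synthetic-data generator for the four-scan, two-day test-retest
# design: population latents with family structure, edge panels with known
# trait/state/error composition, congeneric phenotype item tables, and
# (optionally) raw parcel time series for the connectivity pipeline.
#
# Generating model per edge, mirroring the multistate single-trait structure:
#   S_d  = lambda_t * T + zeta_d,  Var(zeta_d) = 1 - lambda_t^2
#   Q_i  = lambda_s * S_{day(i)} + m * O_{order(i)} + eps_i,
#          eps_i ~ N(0, theta_i)
# with T, S_d, O standard normal. A single standard-normal driver shared by
# edge traits and phenotype factors induces corr(T_e, eta_s) = rho for every
# (edge, scale) pair while keeping all latents standard normal.

NETWORKS_8 <- c("visual", "somatomotor", "dorsal_attention",
                "ventral_attention", "limbic", "frontoparietal",
                "default", "subcortex")

#' Default generative edge parameter table
#'
#' Produces per-edge generative parameters with network-dependent regimes
#' reflecting the stylized facts of test-retest connectivity: sensorimotor
#' edges (visual, somatomotor) get relatively high state loadings and lower
#' trait loadings; higher-order cognitive networks get high trait loadings
#' and small state effects; limbic/subcortical edges get weak loadings and
#' large residuals (these are the edges measurement models tend to fail on).
#' Small deterministic jitter differentiates edges within a regime.
#'
#' @param n_edges number of edges.
#' @param seed RNG seed for network-pair assignment and jitter.
#' @param networks network label vocabulary.
#' @return data frame with columns `edge_id`, `network_pair`, `lambda_s`,
#'   `lambda_t`, `theta1..theta4`, `method_loading`.
#' @export
default_edge_params <- function(n_edges, seed = 1, networks = NETWORKS_8) {
  regime <- function(net) {
    if (net %in% c("visual", "somatomotor")) {
      c(ls = 0.75, lt = 0.82)
    } else if (net %in% c("limbic", "subcortex")) {
      c(ls = 0.45, lt = 0.75)
    } else {
      c(ls = 0.70, lt = 0.92)
    }
  }
  with_seed(seed, {
    n1 <- sample(networks, n_edges, replace = TRUE)
    n2 <- sample(networks, n_edges, replace = TRUE)
    base <- t(vapply(seq_len(n_edges), function(i) {
      (regime(n1[i]) + regime(n2[i])) / 2
    }, numeric(2)))
    ls <- pmin(pmax(base[, 1] + stats::rnorm(n_edges, 0, 0.03), 0.3), 0.9)
    lt <- pmin(pmax(base[, 2] + stats::rnorm(n_edges, 0, 0.02), 0.6), 0.99)
    # residuals: later scans in a day noisier, echoing the empirical increase
    # of error effects in second scans
    th1 <- pmax(1 - ls^2, 0.1)
    data.frame(edge_id = sprintf("e%04d", seq_len(n_edges)),
               network_pair = paste(pmin(n1, n2), pmax(n1, n2), sep = "-"),
               lambda_s = ls, lambda_t = lt,
               theta1 = th1 * 0.9, theta2 = th1 * 1.1,
               theta3 = th1 * 0.9, theta4 = th1 * 1.1,
               method_loading = 0)
  })
}

#' Default generative phenotype parameter table
#'
#' Congeneric scales with mildly varying loadings around 0.7 and residual
#' variances chosen for composite reliabilities in the 0.7-0.9 range typical
#' of questionnaire subscales.
#'
#' @param scale_ids character vector of scale names.
#' @param n_indicators indicators per scale (recycled).
#' @param seed RNG seed for loading jitter.
#' @return data frame with `scale_id`, `indicator`, `loading`, `residual`.
#' @export
default_scale_params <- function(scale_ids = c("cognition", "mental_health"),
                                 n_indicators = 7, seed = 1) {
  n_indicators <- rep_len(n_indicators, length(scale_ids))
  with_seed(seed, {
    rows <- mapply(function(sid, k) {
      nu <- pmin(pmax(stats::rnorm(k, 0.7, 0.08), 0.4), 0.95)
      data.frame(scale_id = sid, indicator = seq_len(k), loading = nu,
                 residual = pmax(1 - nu^2, 0.2) * 1.6)
    }, scale_ids, n_indicators, SIMPLIFY = FALSE)
    do.call(rbind, c(rows, make.row.names = FALSE))
  })
}

#' Generate a synthetic population with latent ground truth
#'
#' Draws subjects with family structure, covariates, per-edge trait and
#' day-state latents, and per-scale phenotype latents. All latent variables
#' are standard normal; a shared standard-normal driver induces
#' `corr(T_e, eta_s) = rho` for every edge-scale pair. States across days are
#' conditionally independent given the trait. Covariates (age, sex, and a
#' synthetic mean-motion summary) are independent of the latents unless
#' `covariate_effects` is supplied.
#'
#' @param n_subjects number of subjects.
#' @param edge_params generative edge table, see [default_edge_params()].
#' @param scale_params generative scale table, see [default_scale_params()].
#' @param rho latent structural correlation between every edge trait and
#'   every phenotype factor; `abs(rho) < 1`.
#' @param n_families number of families (default: about half the subjects,
#'   every family non-empty).
#' @param counterbalance_fraction fraction of subjects with flipped
#'   phase-encoding order.
#' @param covariate_effects optional list with numeric vectors `trait` and
#'   `phenotype`, each with elements `age` and `sex` giving standardized
#'   regression weights of the latents on the covariates (squared sum < 1);
#'   latent variances remain 1.
#' @param seed RNG seed (mandatory).
#' @return object of class `lst_population`: `subjects`, `edges`, `scales`,
#'   `trait` (n x E), `state` (n x E x 2), `eta` (n x n_scales), `rho`.
#' @export
generate_population <- function(n_subjects, edge_params, scale_params,
                                rho = 0, n_families = NULL,
                                counterbalance_fraction = 0.5,
                                covariate_effects = NULL, seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (abs(rho) >= 1) stop("invalid rho: |rho| must be < 1")
  bad <- edge_params$lambda_t < 0 | edge_params$lambda_t > 1 |
    edge_params$lambda_s <= 0 |
    apply(edge_params[paste0("theta", 1:4)] <= 0, 1, any)
  if (any(bad)) stop("invalid edge parameters for edges: ",
                     paste(edge_params$edge_id[bad], collapse = ", "))
  if (any(scale_params$residual <= 0)) stop("non-positive phenotype residual variance")
  ks <- table(scale_params$scale_id)
  if (any(ks < 3)) stop("each scale needs at least 3 indicators")
  n_families <- n_families %||% max(1L, round(n_subjects / 2))
  if (n_families > n_subjects) stop("more families than subjects")
  with_seed(seed, {
    fam <- c(seq_len(n_families),
             sample(n_families, n_subjects - n_families, replace = TRUE))
    fam <- sample(fam)  # shuffle so family id is not ordered with subject id
    subjects <- data.frame(
      subject_id = sprintf("s%05d", seq_len(n_subjects)),
      family_id = sprintf("f%04d", fam),
      age = round(stats::runif(n_subjects, 22, 36)),
      sex = stats::rbinom(n_subjects, 1, 0.5),
      mean_rmsd = stats::rlnorm(n_subjects, log(0.10), 0.25),
      pe_flipped = stats::rbinom(n_subjects, 1, counterbalance_fraction) == 1)
    E <- nrow(edge_params)
    scale_ids <- unique(scale_params$scale_id)
    a <- sqrt(abs(rho))
    b <- sign(rho) * sqrt(abs(rho))
    driver <- stats::rnorm(n_subjects)
    mix <- function(w, n_col) {
      w * driver + sqrt(1 - w^2) * matrix(stats::rnorm(n_subjects * n_col),
                                          n_subjects, n_col)
    }
    trait <- mix(a, E)
    eta <- mix(b, length(scale_ids))
    colnames(trait) <- edge_params$edge_id
    colnames(eta) <- scale_ids
    if (!is.null(covariate_effects)) {
      xs <- cbind(age = as.numeric(scale(subjects$age)),
                  sex = as.numeric(scale(subjects$sex)))
      blend <- function(latent, w) {
        w <- w[c("age", "sex")]; w[is.na(w)] <- 0
        if (sum(w^2) >= 1) stop("covariate effect weights too large")
        drop(xs %*% w) + sqrt(1 - sum(w^2)) * latent
      }
      if (!is.null(covariate_effects$trait)) {
        trait <- apply(trait, 2, blend, w = covariate_effects$trait)
      }
      if (!is.null(covariate_effects$phenotype)) {
        eta <- apply(eta, 2, blend, w = covariate_effects$phenotype)
      }
    }
    state <- array(NA_real_, c(n_subjects, E, 2),
                   dimnames = list(NULL, edge_params$edge_id, NULL))
    for (d in 1:2) {
      lt <- rep(edge_params$lambda_t, each = n_subjects)
      state[, , d] <- lt * trait +
        sqrt(1 - lt^2) * matrix(stats::rnorm(n_subjects * E), n_subjects, E)
    }
    structure(list(subjects = subjects, edges = edge_params,
                   scales = scale_params, trait = trait, state = state,
                   eta = eta, rho = rho),
              class = "lst_population")
  })
}

#' @export
print.lst_population <- function(x, ...) {
  cat("<lst_population>", nrow(x$subjects), "subjects,",
      length(unique(x$subjects$family_id)), "families,",
      nrow(x$edges), "edges,", length(unique(x$scales$scale_id)),
      "phenotype scales, rho =", x$rho, "\n")
  invisible(x)
}

#' Generate the four-indicator edge panel from a population
#'
#' Draws the observed Fisher-z indicators `Q1..Q4` for every subject and
#' edge: `Q_i = lambda_s * S_day(i) + m * O_order(i) + eps_i`. Q1, Q2 are the
#' two scans of day 1 and Q3, Q4 those of day 2; Q1, Q3 are first-in-day.
#' The 4-scan mean is included.
#'
#' @param pop an [generate_population()] result.
#' @param seed RNG seed.
#' @return data frame: `subject_id`, `edge_id`, `network_pair`,
#'   `rsfc_q1..rsfc_q4`, `mean_z`.
#' @export
generate_edge_panel <- function(pop, seed) {
  stopifnot(inherits(pop, "lst_population"))
  ep <- pop$edges
  n <- nrow(pop$subjects)
  with_seed(seed, {
    blocks <- lapply(seq_len(nrow(ep)), function(e) {
      p <- ep[e, ]
      o_fac <- matrix(stats::rnorm(n * 2), n, 2)
      q <- vapply(1:4, function(i) {
        p$lambda_s * pop$state[, e, DAY_OF_Q[i]] +
          p$method_loading * o_fac[, ORDER_OF_Q[i]] +
          stats::rnorm(n, 0, sqrt(p[[paste0("theta", i)]]))
      }, numeric(n))
      data.frame(subject_id = pop$subjects$subject_id,
                 edge_id = p$edge_id, network_pair = p$network_pair,
                 rsfc_q1 = q[, 1], rsfc_q2 = q[, 2],
                 rsfc_q3 = q[, 3], rsfc_q4 = q[, 4],
                 mean_z = rowMeans(q))
    })
    do.call(rbind, c(blocks, make.row.names = FALSE))
  })
}

#' Generate phenotype item tables from a population
#'
#' Draws congeneric indicators `item_j = nu_j * eta + e_j` for every scale
#' and appends the unit-weighted sum score.
#'
#' @param pop an [generate_population()] result.
#' @param seed RNG seed.
#' @return object of class `lst_phenotype_panel`: `items` (named list of
#'   n x k matrices), `sum_scores` (data frame, one column per scale),
#'   `params` (the generative table).
#' @export
generate_phenotype <- function(pop, seed) {
  stopifnot(inherits(pop, "lst_population"))
  n <- nrow(pop$subjects)
  with_seed(seed, {
    items <- lapply(split(pop$scales, pop$scales$scale_id), function(sp) {
      sp <- sp[order(sp$indicator), ]
      k <- nrow(sp)
      eta <- pop$eta[, sp$scale_id[1]]
      x <- vapply(seq_len(k), function(j) {
        sp$loading[j] * eta + stats::rnorm(n, 0, sqrt(sp$residual[j]))
      }, numeric(n))
      colnames(x) <- paste0("item_", seq_len(k))
      x
    })
    items <- items[unique(pop$scales$scale_id)]
    sums <- data.frame(subject_id = pop$subjects$subject_id)
    for (sid in names(items)) sums[[sid]] <- rowSums(items[[sid]])
    structure(list(items = items, sum_scores = sums, params = pop$scales),
              class = "lst_phenotype_panel")
  })
}

#' Generate raw parcel time series consistent with an edge panel
#'
#' For use with the connectivity pipeline: the edge set must be the complete
#' upper triangle over `n_parcels` parcels (ids `p<i>_p<j>`). Each scan's
#' parcel series are multivariate normal with pairwise correlations
#' `tanh(z)` of that scan's generated indicator value, plus an optional
#' shared (global) component, plus artifact noise on spike volumes. Per-
#' volume motion summaries (relative RMSD, mm) are returned alongside, with
#' spikes exceeding 0.25 mm at the configured rate.
#'
#' @param pop population (for subject ids).
#' @param panel edge panel from [generate_edge_panel()].
#' @param n_parcels parcel count; `n_edges(n_parcels)` must match the edge
#'   set.
#' @param volumes volumes per scan after the initial dummy volumes.
#' @param n_dummy initial volumes to prepend (dropped by the pipeline).
#' @param spike_rate per-volume probability of a motion spike.
#' @param global_amp standard deviation of the shared across-parcel signal.
#' @param spike_amp standard deviation of artifact noise added on spike
#'   volumes.
#' @param seed RNG seed.
#' @return object of class `lst_timeseries_panel`: list `scans` of entries
#'   with `subject_id`, `day`, `order`, `signal` (volumes x parcels), `rmsd`;
#'   plus `n_parcels` and `edge_ids`.
#' @export
generate_timeseries <- function(pop, panel, n_parcels, volumes = 120,
                                n_dummy = 4, spike_rate = 0.02,
                                global_amp = 0, spike_amp = 3, seed) {
  stopifnot(inherits(pop, "lst_population"))
  if (volumes < 24) stop("need at least 20 usable volumes after the 4-volume drop")
  eids <- parcel_edge_ids(n_parcels)
  if (!setequal(unique(panel$edge_id), eids)) {
    stop("edge panel must cover the complete upper triangle of ",
         n_parcels, " parcels (ids p<i>_p<j>)")
  }
  pidx <- do.call(rbind, strsplit(sub("^p", "", eids), "_p", fixed = TRUE))
  p_i <- as.integer(pidx[, 1])
  p_j <- as.integer(pidx[, 2])
  nv <- volumes + n_dummy
  with_seed(seed, {
    scans <- list()
    for (s in seq_len(nrow(pop$subjects))) {
      sid <- pop$subjects$subject_id[s]
      rows <- panel[panel$subject_id == sid, ]
      rows <- rows[match(eids, rows$edge_id), ]
      for (q in 1:4) {
        r_mat <- diag(n_parcels)
        rq <- tanh(rows[[paste0("rsfc_q", q)]])
        r_mat[cbind(p_i, p_j)] <- rq
        r_mat[cbind(p_j, p_i)] <- rq
        ch <- tryCatch(chol(r_mat), error = function(e) NULL)
        if (is.null(ch)) {
          worst <- order(-abs(rows[[paste0("rsfc_q", q)]]))[1:min(5, nrow(rows))]
          stop("target correlation matrix not positive definite for subject ",
               sid, " scan ", q, "; strongest edges: ",
               paste(rows$edge_id[worst], collapse = ", "))
        }
        sig <- matrix(stats::rnorm(nv * n_parcels), nv, n_parcels) %*% ch
        if (global_amp > 0) {
          sig <- sig + global_amp * stats::rnorm(nv)
        }
        spike <- stats::runif(nv) < spike_rate
        rmsd <- stats::runif(nv, 0.03, 0.15)
        if (any(spike)) {
          rmsd[spike] <- 0.25 + stats::rexp(sum(spike), rate = 20)
          sig[spike, ] <- sig[spike, , drop = FALSE] +
            spike_amp * matrix(stats::rnorm(sum(spike) * n_parcels),
                               sum(spike), n_parcels)
        }
        scans[[length(scans) + 1L]] <- list(
          subject_id = sid, day = DAY_OF_Q[q], order = ORDER_OF_Q[q],
          phase_encoding = if (xor(pop$subjects$pe_flipped[s],
                                   ORDER_OF_Q[q] == 2)) "LR" else "RL",
          signal = sig, rmsd = rmsd)
      }
    }
    structure(list(scans = scans, n_parcels = n_parcels, edge_ids = eids),
              class = "lst_timeseries_panel")
  })
}

#' Subset one subject per family
#'
#' Random family-unrelated subset, as used for split-half prediction runs.
#'
#' @param pop an [generate_population()] result.
#' @param seed RNG seed.
#' @return character vector of retained subject ids, one per family.
#' @export
subset_unrelated <- function(pop, seed) {
  stopifnot(inherits(pop, "lst_population"))
  with_seed(seed, {
    picked <- vapply(split(pop$subjects$subject_id, pop$subjects$family_id),
                     function(ids) ids[sample.int(length(ids), 1)],
                     character(1))
    unname(sort(picked))
  })
}
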