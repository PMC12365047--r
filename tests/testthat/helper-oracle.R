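# Independent oracle for the ML covariance-structure fits: the implied
# covariance is assembled through explicit factor-loading matrix algebra
# (Lambda Phi Lambda' + Theta), a deliberately different code path from the
# package's closed-form entries, and the discrepancy is minimized by
# Nelder-Mead from several fixed starts.

oracle_sigma <- function(family, par, k = NULL) {
  if (family == "single_trait") {
    lam <- matrix(par[1], 4, 1)
    lam %*% t(lam) + diag(par[2:5])
  } else if (family == "msst") {
    # day factors S1, S2 with corr(S1, S2) = lambda_t^2
    l <- matrix(0, 4, 2)
    l[1:2, 1] <- par[1]
    l[3:4, 2] <- par[1]
    phi <- matrix(c(1, par[2]^2, par[2]^2, 1), 2, 2)
    l %*% phi %*% t(l) + diag(par[3:6])
  } else if (family == "bifactor") {
    lg <- matrix(par[1], 4, 1)
    ls <- matrix(0, 4, 2)
    ls[1:2, 1] <- par[2]
    ls[3:4, 2] <- par[2]
    lg %*% t(lg) + ls %*% t(ls) + diag(par[3:6])
  } else if (family == "congeneric") {
    nu <- matrix(par[seq_len(k)], k, 1)
    nu %*% t(nu) + diag(par[k + seq_len(k)])
  } else {
    stop("unsupported family in oracle")
  }
}

oracle_fml <- function(par, family, s, k = NULL) {
  sigma <- oracle_sigma(family, par, k)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) return(1e8)
  val <- sum(log(ev)) - determinant(s, logarithm = TRUE)$modulus[1] +
    sum(diag(s %*% solve(sigma))) - nrow(s)
  if (!is.finite(val)) return(1e8)
  val
}

oracle_min_fml <- function(family, s, k = NULL) {
  n_par <- switch(family, single_trait = 5L, msst = 6L, bifactor = 6L,
                  congeneric = 2L * k)
  starts <- list(rep(0.5, n_par), rep(0.8, n_par),
                 c(rep(0.6, n_par - 4), rep(0.3, 4)),
                 rep(0.4, n_par))
  best <- Inf
  for (st in starts) {
    for (i in 1:2) {  # restart Nelder-Mead from its own optimum
      res <- stats::optim(st, oracle_fml, family = family, s = s, k = k,
                          method = "Nelder-Mead",
                          control = list(maxit = 3000, reltol = 1e-12))
      st <- res$par
    }
    best <- min(best, res$value)
  }
  best
}

# Small deterministic sample covariance from a model family.
random_problem <- function(family, seed, n = 200, k = 5) {
  spec <- switch(family,
    single_trait = lst_model("single_trait"),
    msst = lst_model("msst"),
    bifactor = lst_model("bifactor"),
    congeneric = lst_model("congeneric", n_items = k))
  set.seed(seed)
  par <- switch(family,
    single_trait = c(lambda = runif(1, 0.4, 0.9),
                     setNames(runif(4, 0.2, 1), paste0("theta", 1:4))),
    msst = c(lambda_s = runif(1, 0.4, 0.9), lambda_t = runif(1, 0.7, 0.99),
             setNames(runif(4, 0.2, 1), paste0("theta", 1:4))),
    bifactor = c(g = runif(1, 0.3, 0.8), s = runif(1, 0.2, 0.6),
                 setNames(runif(4, 0.2, 1), paste0("theta", 1:4))),
    congeneric = c(setNames(runif(k, 0.3, 0.9), paste0("nu", 1:k)),
                   setNames(runif(k, 0.2, 1), paste0("theta", 1:k))))
  sigma <- implied_covariance(spec, par)
  x <- matrix(rnorm(n * nrow(sigma)), n) %*% chol(sigma)
  list(spec = spec, truth = par, s = cov(x), n = n)
}

# Edge parameter table with every edge identical; handy for regime tests.
uniform_edge_params <- function(n_edges, lambda_s, lambda_t, theta,
                                network_pair = "default-default",
                                method_loading = 0) {
  theta <- rep_len(theta, 4)
  data.frame(edge_id = sprintf("e%04d", seq_len(n_edges)),
             network_pair = network_pair,
             lambda_s = lambda_s, lambda_t = lambda_t,
             theta1 = theta[1], theta2 = theta[2],
             theta3 = theta[3], theta4 = theta[4],
             method_loading = method_loading)
}

# Congeneric scale table with constant loading/residual.
uniform_scale_params <- function(scale_id, k, loading, residual) {
  data.frame(scale_id = scale_id, indicator = seq_len(k),
             loading = loading, residual = residual)
}
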