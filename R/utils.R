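# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so seeded generators do not clobber the
# user session.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Fisher z with clipping at |r| = 1 - 1e-7; returns attribute "clipped" count
# when any value had to be clipped.
fisher_z <- function(r, clip = 1 - 1e-7) {
  clipped <- abs(r) > clip & is.finite(r)
  r[clipped] <- sign(r[clipped]) * clip
  z <- atanh(r)
  if (any(clipped, na.rm = TRUE)) attr(z, "clipped") <- sum(clipped, na.rm = TRUE)
  z
}

#' Number of edges among P parcels
#'
#' Unordered parcel pairs: `P * (P - 1) / 2`. With the 432 cortical and
#' subcortical parcels used for whole-brain connectivity this gives 93,096
#' edges.
#'
#' @param n_parcels number of parcels (nodes).
#' @return integer edge count.
#' @examples
#' n_edges(432)
#' @export
n_edges <- function(n_parcels) {
  stopifnot(n_parcels >= 0)
  as.integer(n_parcels * (n_parcels - 1) / 2)
}

#' Canonical edge identifiers for a parcel set
#'
#' Edge ids `p<i>_p<j>` (1-based, `i < j`) in upper-triangle row-major
#' order - the order used by [compute_edges()] and expected by
#' [generate_timeseries()].
#'
#' @param n_parcels number of parcels.
#' @return character vector of length `n_edges(n_parcels)`.
#' @export
parcel_edge_ids <- function(n_parcels) {
  if (n_parcels < 2) return(character(0))
  idx <- which(upper.tri(matrix(0, n_parcels, n_parcels)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  paste0("p", idx[, 1], "_p", idx[, 2])
}

# Draw n rows from N(0, Sigma) via Cholesky (upper factor), deterministic
# given the RNG state.
rmvn <- function(n, sigma) {
  p <- nrow(sigma)
  ch <- chol(sigma)
  matrix(stats::rnorm(n * p), n, p) %*% ch
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rbind data frames that may differ in columns, filling with NA.
rbind_fill <- function(dfs) {
  dfs <- Filter(Negate(is.null), dfs)
  if (length(dfs) == 0) return(NULL)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, c(lapply(dfs, function(d) {
    for (cl in setdiff(cols, names(d))) d[[cl]] <- NA
    d[, cols, drop = FALSE]
  }), make.row.names = FALSE))
}
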