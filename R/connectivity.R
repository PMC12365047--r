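# Desk-scale connectivity pipeline: motion QC, scan cleaning (initial-volume
# drop, spike regression, optional mean-signal regression), Fisher-z edge
# computation, and assembly of the four-scan edge panel.

#' Participant-level motion quality control
#'
#' A subject is retained only if all four scans are present and no scan has
#' more than `max_fraction` of its volumes with relative RMSD above
#' `rmsd_threshold` (defaults: more than 10% of volumes above 0.25 mm
#' excludes; exactly 10% is retained).
#'
#' @param ts_panel an `lst_timeseries_panel` (see [generate_timeseries()]) or
#'   a bare list of scan entries with `subject_id` and `rmsd`.
#' @param rmsd_threshold spike threshold in mm for the QC count (volumes
#'   strictly above it count).
#' @param max_fraction maximum tolerated fraction of spike volumes per scan.
#' @return list with `retained` (subject ids) and `excluded` (data frame of
#'   subject_id, reason).
#' @export
qc_participants <- function(ts_panel, rmsd_threshold = 0.25,
                            max_fraction = 0.10) {
  scans <- if (inherits(ts_panel, "lst_timeseries_panel")) ts_panel$scans else ts_panel
  by_subj <- split(scans, vapply(scans, `[[`, character(1), "subject_id"))
  excluded <- list()
  retained <- character(0)
  for (sid in names(by_subj)) {
    sc <- by_subj[[sid]]
    if (length(sc) != 4L) {
      excluded[[sid]] <- data.frame(subject_id = sid, reason = "missing_scan")
      next
    }
    frac <- vapply(sc, function(x) mean(x$rmsd > rmsd_threshold), numeric(1))
    if (any(frac > max_fraction)) {
      excluded[[sid]] <- data.frame(
        subject_id = sid,
        reason = sprintf("spike_fraction_%.3f_gt_%.2f", max(frac), max_fraction))
    } else {
      retained <- c(retained, sid)
    }
  }
  list(retained = sort(retained), excluded = rbind_fill(excluded) %||%
         data.frame(subject_id = character(0), reason = character(0)))
}

#' Clean one scan's parcel time series
#'
#' Drops the first `n_drop` volumes, then regresses every parcel series on an
#' intercept, one indicator column per spike volume (relative RMSD at or
#' above `rmsd_threshold`), and - when `gsr` is on - the across-parcel mean
#' signal. The residual series are returned; spike volumes therefore have
#' exactly zero residuals and, under GSR, residuals are orthogonal to the
#' mean signal.
#'
#' @param signal volumes x parcels matrix.
#' @param rmsd per-volume relative RMSD (mm), same length as volumes.
#' @param rmsd_threshold spike threshold in mm (volumes at or above it are
#'   regressed out).
#' @param gsr logical; add the across-parcel mean signal as a regressor.
#' @param n_drop initial volumes to discard.
#' @return residual matrix ((volumes - n_drop) x parcels).
#' @export
clean_scan <- function(signal, rmsd, rmsd_threshold = 0.25, gsr = FALSE,
                       n_drop = 4) {
  signal <- as.matrix(signal)
  if (length(rmsd) != nrow(signal)) {
    stop("rmsd length must equal the number of volumes")
  }
  keep <- seq_len(nrow(signal)) > n_drop
  y <- signal[keep, , drop = FALSE]
  rm_ <- rmsd[keep]
  spikes <- which(rm_ >= rmsd_threshold)
  x <- matrix(1, nrow(y), 1)
  if (length(spikes) > 0) {
    ind <- matrix(0, nrow(y), length(spikes))
    ind[cbind(spikes, seq_along(spikes))] <- 1
    x <- cbind(x, ind)
  }
  if (gsr) x <- cbind(x, rowMeans(y))
  if (nrow(y) - qr(x)$rank < 10) {
    stop("fewer than 10 residual degrees of freedom after nuisance regression")
  }
  qr_x <- qr(x)
  y - x %*% qr.coef(qr_x, y)
}

#' Fisher-z connectivity edges of one cleaned scan
#'
#' Pearson correlation for every unordered parcel pair, Fisher
#' z-transformed. Edge order is the upper triangle in row-major order of the
#' (1-based) parcel indices, matching [parcel_edge_ids()]. Correlations with
#' a zero-variance parcel are returned as `NA` and logged in the
#' `undefined` attribute; `|r| = 1` is clipped to `atanh(1 - 1e-7)`.
#'
#' @param cleaned volumes x parcels matrix (at least 2 parcels).
#' @return named numeric vector of length `n_edges(P)`.
#' @export
compute_edges <- function(cleaned) {
  cleaned <- as.matrix(cleaned)
  p <- ncol(cleaned)
  if (p < 2) stop("need at least 2 parcels")
  sds <- apply(cleaned, 2, stats::sd)
  degenerate <- which(sds == 0 | !is.finite(sds))
  r <- suppressWarnings(stats::cor(cleaned))
  ut <- which(upper.tri(r), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  vals <- r[ut]
  z <- fisher_z(vals)
  names(z) <- paste0("p", ut[, 1], "_p", ut[, 2])
  if (length(degenerate) > 0) {
    bad <- ut[, 1] %in% degenerate | ut[, 2] %in% degenerate
    z[bad] <- NA_real_
    attr(z, "undefined") <- names(z)[bad]
  }
  z
}

#' Assemble the four-scan edge panel from per-scan edge vectors
#'
#' Assigns the quarterly indicators by (day, order-in-day) slot - Q1 = day 1
#' first scan, Q2 = day 1 second, Q3 = day 2 first, Q4 = day 2 second - so
#' the result is invariant to the input order of scans, and appends the
#' four-scan mean of the z values.
#'
#' @param scan_edges list of entries, each with `subject_id`, `day`, `order`,
#'   and `z` (a vector from [compute_edges()]).
#' @param network_pairs optional named character vector mapping edge id to
#'   network-pair label.
#' @return edge panel data frame (`subject_id`, `edge_id`, `network_pair`,
#'   `rsfc_q1..rsfc_q4`, `mean_z`).
#' @export
assemble_edge_panel <- function(scan_edges, network_pairs = NULL) {
  by_subj <- split(scan_edges,
                   vapply(scan_edges, `[[`, character(1), "subject_id"))
  blocks <- lapply(by_subj, function(sc) {
    slots <- vapply(sc, function(x) {
      (as.integer(x$day) - 1L) * 2L + as.integer(x$order)
    }, integer(1))
    if (length(sc) != 4L || anyDuplicated(slots) || !setequal(slots, 1:4)) {
      stop("subject ", sc[[1]]$subject_id,
           ": need exactly 4 scans with distinct (day, order) slots")
    }
    sc <- sc[order(slots)]
    eids <- names(sc[[1]]$z)
    q <- vapply(sc, function(x) unname(x$z[eids]), numeric(length(eids)))
    if (is.null(dim(q))) q <- matrix(q, nrow = 1)
    data.frame(subject_id = sc[[1]]$subject_id, edge_id = eids,
               network_pair = if (is.null(network_pairs)) NA_character_
                 else unname(network_pairs[eids]),
               rsfc_q1 = q[, 1], rsfc_q2 = q[, 2],
               rsfc_q3 = q[, 3], rsfc_q4 = q[, 4],
               mean_z = rowMeans(q))
  })
  do.call(rbind, c(blocks, make.row.names = FALSE))
}

#' Run the full connectivity pipeline on a time-series panel
#'
#' Applies participant QC, per-scan cleaning and edge computation, and panel
#' assembly in one call.
#'
#' @param ts_panel an `lst_timeseries_panel`.
#' @param gsr logical, mean-signal regression on or off.
#' @param qc_threshold,qc_max_fraction participant QC settings (strictly
#'   above threshold counts, see [qc_participants()]).
#' @param clean_threshold spike-regression threshold (at or above).
#' @param n_drop initial volumes to discard per scan.
#' @param network_pairs optional edge-id to network-pair mapping.
#' @return list with `panel` (edge panel of retained subjects) and
#'   `exclusions` (QC log).
#' @export
connectivity_pipeline <- function(ts_panel, gsr = FALSE, qc_threshold = 0.25,
                                  qc_max_fraction = 0.10,
                                  clean_threshold = 0.25, n_drop = 4,
                                  network_pairs = NULL) {
  stopifnot(inherits(ts_panel, "lst_timeseries_panel"))
  qc <- qc_participants(ts_panel, qc_threshold, qc_max_fraction)
  keep <- vapply(ts_panel$scans, `[[`, character(1), "subject_id") %in%
    qc$retained
  scan_edges <- lapply(ts_panel$scans[keep], function(sc) {
    cleaned <- clean_scan(sc$signal, sc$rmsd, clean_threshold, gsr, n_drop)
    list(subject_id = sc$subject_id, day = sc$day, order = sc$order,
         z = compute_edges(cleaned))
  })
  list(panel = assemble_edge_panel(scan_edges, network_pairs),
       exclusions = qc$excluded)
}
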