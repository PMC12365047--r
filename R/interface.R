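# Pipeline stages tying the modules together: seeded simulation, file-based
# connectivity, per-edge measurement fitting, decomposition and reliability
# summaries, association, the two prediction experiments, and report tables.
# All artifacts are delimited text with headers; every stage writes a JSON
# manifest (inputs, full config, seed, package version) and an exclusion log.

PIPELINE_STAGES <- c("simulate", "connectivity", "fit-measurement",
                     "decompose", "reliability", "associate",
                     "predict-factor-scores", "predict-operative", "report")

#' Read a pipeline run configuration
#'
#' Loads a YAML (or JSON) configuration document. `seed` is mandatory; all
#' other entries default per stage (see [run_stage()]).
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must declare a `seed`")
  cfg
}

write_tsv <- function(x, path) {
  utils::write.table(format(x, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

read_tsv <- function(path) utils::read.delim(path, check.names = FALSE)

write_manifest <- function(workdir, stage, cfg, inputs, outputs) {
  man <- list(stage = stage,
              package_version = as.character(utils::packageVersion("lstconn")),
              seed = cfg$seed, config = cfg, inputs = inputs,
              outputs = outputs)
  path <- file.path(workdir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  path
}

write_exclusions <- function(workdir, stage, exclusions) {
  path <- file.path(workdir, paste0("exclusions_", gsub("-", "_", stage), ".tsv"))
  if (is.null(exclusions) || nrow(exclusions) == 0) {
    exclusions <- data.frame(stage = character(0), unit = character(0),
                             reason = character(0))
  } else {
    exclusions <- data.frame(stage = stage, unit = exclusions$unit,
                             reason = exclusions$reason)
  }
  write_tsv(exclusions, path)
}

#' Run one pipeline stage
#'
#' Dispatches a named stage on a configuration (list or YAML path). Stages
#' read their inputs from, and write their outputs to, `config$workdir`
#' (default: current directory). Outputs are tab-separated tables plus a JSON
#' manifest and an exclusion log per stage; reruns with an identical
#' configuration yield byte-identical tables.
#'
#' Stage overview: `simulate` writes the synthetic edge panel, phenotype
#' tables, covariates, ground truth and (optionally) raw scan files;
#' `connectivity` turns scan files into an edge panel (with `gsr: true/false`);
#' `fit-measurement` fits the configured model family per edge;
#' `decompose` summarizes trait/state/error shares per network pair;
#' `reliability` computes omega per scale; `associate` estimates corrected
#' and uncorrected edge-phenotype correlations, improvement factors and
#' required-sample-size ratios; `predict-factor-scores` runs the repeated
#' split-half factor-score experiment; `predict-operative` runs the
#' family-aware operative-prediction comparison; `report` aggregates
#' association outputs into per-network summary tables.
#'
#' @param stage one of the names in `PIPELINE_STAGES`.
#' @param config list or path to a YAML config; must contain `seed`.
#' @return invisibly, a list with the written file paths and main tables.
#' @export
run_stage <- function(stage, config) {
  if (!stage %in% PIPELINE_STAGES) {
    stop("unknown stage '", stage, "'; expected one of: ",
         paste(PIPELINE_STAGES, collapse = ", "))
  }
  cfg <- if (is.character(config)) read_run_config(config) else config
  if (is.null(cfg$seed)) stop("config must declare a `seed`")
  cfg$workdir <- cfg$workdir %||% "."
  dir.create(cfg$workdir, showWarnings = FALSE, recursive = TRUE)
  switch(stage,
    "simulate" = stage_simulate(cfg),
    "connectivity" = stage_connectivity(cfg),
    "fit-measurement" = stage_fit_measurement(cfg),
    "decompose" = stage_decompose(cfg),
    "reliability" = stage_reliability(cfg),
    "associate" = stage_associate(cfg),
    "predict-factor-scores" = stage_predict_fs(cfg),
    "predict-operative" = stage_predict_operative(cfg),
    "report" = stage_report(cfg))
}

stage_simulate <- function(cfg) {
  sc <- cfg$simulate %||% list()
  n <- sc$n_subjects %||% 400
  rho <- sc$rho %||% 0.3
  ep <- if (!is.null(sc$edge_params_file)) read_tsv(file.path(cfg$workdir, sc$edge_params_file))
        else default_edge_params(sc$n_edges %||% 50, seed = cfg$seed)
  sp <- if (!is.null(sc$scale_params_file)) read_tsv(file.path(cfg$workdir, sc$scale_params_file))
        else default_scale_params(sc$scales %||% c("cognition", "mental_health"),
                                  sc$n_indicators %||% 7, seed = cfg$seed)
  pop <- generate_population(n, ep, sp, rho = rho,
                             n_families = sc$n_families,
                             covariate_effects = sc$covariate_effects,
                             seed = cfg$seed)
  panel <- generate_edge_panel(pop, seed = cfg$seed + 1)
  phen <- generate_phenotype(pop, seed = cfg$seed + 2)
  out <- c(
    edge_panel = write_tsv(panel, file.path(cfg$workdir, "edge_panel.tsv")),
    covariates = write_tsv(pop$subjects, file.path(cfg$workdir, "covariates.tsv")),
    truth_edges = write_tsv(pop$edges, file.path(cfg$workdir, "truth_edges.tsv")),
    truth_scales = write_tsv(pop$scales, file.path(cfg$workdir, "truth_scales.tsv")),
    sum_scores = write_tsv(phen$sum_scores, file.path(cfg$workdir, "sum_scores.tsv")))
  for (sid in names(phen$items)) {
    d <- data.frame(subject_id = phen$sum_scores$subject_id, phen$items[[sid]],
                    sum_score = phen$sum_scores[[sid]])
    out[paste0("phenotype_", sid)] <-
      write_tsv(d, file.path(cfg$workdir, paste0("phenotype_", sid, ".tsv")))
  }
  if (isTRUE((sc$timeseries %||% list())$enabled)) {
    tcfg <- sc$timeseries
    np <- tcfg$n_parcels %||% 6
    ep_ts <- data.frame(edge_id = parcel_edge_ids(np),
                        network_pair = "simulated-simulated",
                        lambda_s = 0.7, lambda_t = 0.9,
                        theta1 = 0.3, theta2 = 0.3, theta3 = 0.3, theta4 = 0.3,
                        method_loading = 0)
    # modest connectivity scale keeps the implied correlation matrices PD
    pop_ts <- generate_population(n, ep_ts, sp, rho = 0, seed = cfg$seed + 3)
    pan_ts <- generate_edge_panel(pop_ts, seed = cfg$seed + 4)
    for (qc in paste0("rsfc_q", 1:4)) pan_ts[[qc]] <- pan_ts[[qc]] * (tcfg$z_scale %||% 0.25)
    ts <- generate_timeseries(pop_ts, pan_ts, n_parcels = np,
                              volumes = tcfg$volumes %||% 120,
                              spike_rate = tcfg$spike_rate %||% 0.02,
                              global_amp = tcfg$global_amp %||% 0,
                              seed = cfg$seed + 5)
    man <- list()
    for (i in seq_along(ts$scans)) {
      sc_i <- ts$scans[[i]]
      sig_path <- sprintf("scan_%s_d%d_o%d.tsv", sc_i$subject_id, sc_i$day, sc_i$order)
      rmsd_path <- sprintf("rmsd_%s_d%d_o%d.tsv", sc_i$subject_id, sc_i$day, sc_i$order)
      write_tsv(as.data.frame(sc_i$signal), file.path(cfg$workdir, sig_path))
      write_tsv(data.frame(rmsd = sc_i$rmsd), file.path(cfg$workdir, rmsd_path))
      man[[i]] <- data.frame(subject_id = sc_i$subject_id, day = sc_i$day,
                             order = sc_i$order,
                             phase_encoding = sc_i$phase_encoding,
                             signal_file = sig_path, rmsd_file = rmsd_path)
    }
    out["timeseries_manifest"] <- write_tsv(
      do.call(rbind, man), file.path(cfg$workdir, "timeseries_manifest.tsv"))
  }
  write_exclusions(cfg$workdir, "simulate", NULL)
  write_manifest(cfg$workdir, "simulate", cfg, character(0), unname(out))
  invisible(list(paths = out, panel = panel, phenotypes = phen, population = pop))
}

stage_connectivity <- function(cfg) {
  cc <- cfg$connectivity %||% list()
  man <- read_tsv(file.path(cfg$workdir, cc$manifest %||% "timeseries_manifest.tsv"))
  scans <- lapply(seq_len(nrow(man)), function(i) {
    list(subject_id = man$subject_id[i], day = man$day[i], order = man$order[i],
         signal = as.matrix(read_tsv(file.path(cfg$workdir, man$signal_file[i]))),
         rmsd = read_tsv(file.path(cfg$workdir, man$rmsd_file[i]))$rmsd)
  })
  np <- ncol(scans[[1]]$signal)
  ts <- structure(list(scans = scans, n_parcels = np,
                       edge_ids = parcel_edge_ids(np)),
                  class = "lst_timeseries_panel")
  res <- connectivity_pipeline(
    ts, gsr = isTRUE(cc$gsr),
    qc_threshold = cc$qc_threshold %||% 0.25,
    qc_max_fraction = cc$qc_max_fraction %||% 0.10,
    clean_threshold = cc$clean_threshold %||% 0.25,
    n_drop = cc$n_drop %||% 4)
  tag <- if (isTRUE(cc$gsr)) "gsr" else "nogsr"
  path <- write_tsv(res$panel,
                    file.path(cfg$workdir, paste0("edge_panel_", tag, ".tsv")))
  excl <- if (nrow(res$exclusions) > 0) {
    data.frame(unit = res$exclusions$subject_id, reason = res$exclusions$reason)
  } else NULL
  write_exclusions(cfg$workdir, "connectivity", excl)
  write_manifest(cfg$workdir, "connectivity", cfg, "timeseries_manifest.tsv", path)
  invisible(list(paths = path, panel = res$panel))
}

stage_fit_measurement <- function(cfg) {
  fm <- cfg$fit_measurement %||% list()
  panel <- read_tsv(file.path(cfg$workdir, fm$edge_panel %||% "edge_panel.tsv"))
  family <- fm$family %||% "msst"
  res <- fit_edge_panel(panel, family)
  path <- write_tsv(res, file.path(cfg$workdir,
                                   paste0("measurement_", family, ".tsv")))
  failed <- res[!res$pass %in% TRUE, , drop = FALSE]
  excl <- if (nrow(failed) > 0) {
    data.frame(unit = failed$edge_id, reason = failed$reasons)
  } else NULL
  write_exclusions(cfg$workdir, "fit-measurement", excl)
  write_manifest(cfg$workdir, "fit-measurement", cfg,
                 fm$edge_panel %||% "edge_panel.tsv", path)
  invisible(list(paths = path, results = res))
}

stage_decompose <- function(cfg) {
  dc <- cfg$decompose %||% list()
  res <- read_tsv(file.path(cfg$workdir,
                            dc$measurement %||% "measurement_msst.tsv"))
  ok <- res[res$pass %in% TRUE & !is.na(res$common_consistency), , drop = FALSE]
  agg <- stats::aggregate(
    ok[, c("common_consistency", "occasion_specificity", "random_error")],
    by = list(network_pair = ok$network_pair), FUN = mean)
  overall <- data.frame(network_pair = "overall",
                        t(colMeans(ok[, c("common_consistency",
                                          "occasion_specificity",
                                          "random_error")])))
  out <- rbind(agg, overall)
  path <- write_tsv(out, file.path(cfg$workdir, "decomposition_summary.tsv"))
  write_exclusions(cfg$workdir, "decompose", NULL)
  write_manifest(cfg$workdir, "decompose", cfg,
                 dc$measurement %||% "measurement_msst.tsv", path)
  invisible(list(paths = path, summary = out))
}

stage_reliability <- function(cfg) {
  rl <- cfg$reliability %||% list()
  files <- list.files(cfg$workdir, "^phenotype_.*\\.tsv$")
  rows <- lapply(files, function(f) {
    d <- read_tsv(file.path(cfg$workdir, f))
    items <- as.matrix(d[, grep("^item_", names(d)), drop = FALSE])
    fit <- ml_fit(lst_model("congeneric", n_items = ncol(items)),
                  stats::cov(items), nrow(items))
    data.frame(scale_id = sub("^phenotype_(.*)\\.tsv$", "\\1", f),
               n_indicators = ncol(items),
               omega = if (isTRUE(fit$converged)) omega_reliability(fit) else NA_real_,
               converged = fit$converged)
  })
  out <- do.call(rbind, rows)
  path <- write_tsv(out, file.path(cfg$workdir, "reliability.tsv"))
  write_exclusions(cfg$workdir, "reliability", NULL)
  write_manifest(cfg$workdir, "reliability", cfg, files, path)
  invisible(list(paths = path, reliability = out))
}

stage_associate <- function(cfg) {
  as_ <- cfg$associate %||% list()
  panel <- read_tsv(file.path(cfg$workdir, as_$edge_panel %||% "edge_panel.tsv"))
  cov_tab <- read_tsv(file.path(cfg$workdir, as_$covariates %||% "covariates.tsv"))
  subj <- sort(unique(panel$subject_id))
  cov_tab <- cov_tab[match(subj, cov_tab$subject_id), ]
  xmat <- if (isTRUE(as_$use_covariates %||% TRUE)) {
    as.matrix(cov_tab[, c("age", "sex", "mean_rmsd")])
  } else NULL
  files <- list.files(cfg$workdir, "^phenotype_.*\\.tsv$")
  all_rows <- list()
  for (f in files) {
    sid <- sub("^phenotype_(.*)\\.tsv$", "\\1", f)
    d <- read_tsv(file.path(cfg$workdir, f))
    d <- d[match(subj, d$subject_id), ]
    items <- as.matrix(d[, grep("^item_", names(d)), drop = FALSE])
    all_rows[[sid]] <- associate_edges(panel, items, xmat, scale_id = sid)
  }
  res <- do.call(rbind, c(all_rows, make.row.names = FALSE))
  path <- write_tsv(res, file.path(cfg$workdir, "association.tsv"))
  imp <- improvement_factor(res, group = "network_pair",
                            min_edges = as_$min_edges %||% 10)
  path_imp <- write_tsv(imp, file.path(cfg$workdir, "improvement_factors.tsv"))
  ok <- res[res$pass %in% TRUE, ]
  ratio <- if (nrow(ok) >= 3) {
    data.frame(group = "overall",
               median_corrected = stats::median(ok$corrected_r),
               median_uncorrected = stats::median(ok$uncorrected_r),
               sample_size_ratio = sample_size_ratio(
                 stats::median(ok$corrected_r), stats::median(ok$uncorrected_r),
                 alpha = as_$alpha %||% 0.05, power = as_$power %||% 0.80))
  } else data.frame(group = character(0), median_corrected = numeric(0),
                    median_uncorrected = numeric(0),
                    sample_size_ratio = numeric(0))
  path_ratio <- write_tsv(ratio, file.path(cfg$workdir, "sample_size_ratios.tsv"))
  failed <- res[!res$pass %in% TRUE, ]
  excl <- if (nrow(failed) > 0) {
    data.frame(unit = paste(failed$edge_id, failed$scale_id, sep = ":"),
               reason = failed$reasons)
  } else NULL
  write_exclusions(cfg$workdir, "associate", excl)
  write_manifest(cfg$workdir, "associate", cfg,
                 c(as_$edge_panel %||% "edge_panel.tsv", files),
                 c(path, path_imp, path_ratio))
  invisible(list(paths = c(path, path_imp, path_ratio), association = res,
                 improvement = imp, ratios = ratio))
}

read_phenotype_panel <- function(workdir, subj) {
  files <- list.files(workdir, "^phenotype_.*\\.tsv$")
  items <- list()
  sums <- data.frame(subject_id = subj)
  for (f in files) {
    sid <- sub("^phenotype_(.*)\\.tsv$", "\\1", f)
    d <- read_tsv(file.path(workdir, f))
    d <- d[match(subj, d$subject_id), ]
    items[[sid]] <- as.matrix(d[, grep("^item_", names(d)), drop = FALSE])
    sums[[sid]] <- d$sum_score
  }
  structure(list(items = items, sum_scores = sums, params = NULL),
            class = "lst_phenotype_panel")
}

stage_predict_fs <- function(cfg) {
  pf <- cfg$predict_factor_scores %||% list()
  panel <- read_tsv(file.path(cfg$workdir, pf$edge_panel %||% "edge_panel.tsv"))
  cov_tab <- read_tsv(file.path(cfg$workdir, pf$covariates %||% "covariates.tsv"))
  unrel <- vapply(split(cov_tab$subject_id, cov_tab$family_id),
                  `[`, character(1), 1)
  panel <- panel[panel$subject_id %in% unrel, ]
  subj <- sort(unique(panel$subject_id))
  phen <- read_phenotype_panel(cfg$workdir, subj)
  res <- split_half_experiment(
    panel, phen, repeats = pf$repeats %||% 10, seed = cfg$seed,
    exclude_networks = pf$exclude_networks %||% c("limbic", "subcortex"),
    min_n = pf$min_n %||% 100)
  path <- write_tsv(res, file.path(cfg$workdir, "predictions_factor_scores.tsv"))
  write_exclusions(cfg$workdir, "predict-factor-scores", NULL)
  write_manifest(cfg$workdir, "predict-factor-scores", cfg,
                 pf$edge_panel %||% "edge_panel.tsv", path)
  invisible(list(paths = path, report = res))
}

stage_predict_operative <- function(cfg) {
  po <- cfg$predict_operative %||% list()
  panel <- read_tsv(file.path(cfg$workdir, po$edge_panel %||% "edge_panel.tsv"))
  cov_tab <- read_tsv(file.path(cfg$workdir, po$covariates %||% "covariates.tsv"))
  subj <- sort(unique(panel$subject_id))
  phen <- read_phenotype_panel(cfg$workdir, subj)
  fams <- stats::setNames(cov_tab$family_id, cov_tab$subject_id)
  res <- operative_pipeline(
    panel, phen, fams, folds = po$folds %||% 10, seed = cfg$seed,
    exclude_networks = po$exclude_networks %||% c("limbic", "subcortex"))
  path <- write_tsv(res, file.path(cfg$workdir, "predictions_operative.tsv"))
  write_exclusions(cfg$workdir, "predict-operative", NULL)
  write_manifest(cfg$workdir, "predict-operative", cfg,
                 po$edge_panel %||% "edge_panel.tsv", path)
  invisible(list(paths = path, report = res))
}

stage_report <- function(cfg) {
  res <- read_tsv(file.path(cfg$workdir, "association.tsv"))
  imp <- improvement_factor(res, group = "network_pair")
  ok <- res[res$pass %in% TRUE, ]
  summary_tab <- data.frame(
    n_edge_scale_pairs = nrow(res),
    n_passing = nrow(ok),
    median_corrected_r = stats::median(ok$corrected_r),
    median_uncorrected_r = stats::median(ok$uncorrected_r),
    median_improvement_factor = stats::median(imp$improvement_factor,
                                              na.rm = TRUE),
    mean_improvement_factor = mean(imp$improvement_factor, na.rm = TRUE))
  p1 <- write_tsv(imp, file.path(cfg$workdir, "report_improvement.tsv"))
  p2 <- write_tsv(summary_tab, file.path(cfg$workdir, "report_summary.tsv"))
  write_exclusions(cfg$workdir, "report", NULL)
  write_manifest(cfg$workdir, "report", cfg, "association.tsv", c(p1, p2))
  invisible(list(paths = c(p1, p2), improvement = imp, summary = summary_tab))
}
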