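#' End-to-end cohort workflow: calibrate, predict, score, compare
#'
#' For every patient: manufacture (or accept) the observed follow-up NC
#' growth, calibrate the unobservable inflammation/microvessel levels
#' against it, predict to the 36-month horizon, and collect the eight
#' severity factors. The cohort is then scored and the stable-like vs
#' unstable-like groups are compared by Welch t-tests on the pooled monthly
#' factor trajectories and by within-group Spearman correlations of each
#' factor with NC expansion.
#'
#' @param cohort A [generate_cohort()] result.
#' @param p A [default_parameters()] set.
#' @param cfg A [solver_config()].
#' @param noise Relative noise on the manufactured follow-up observation.
#' @param observed Optional numeric vector of observed growths (one per
#'   patient) overriding the manufactured ones.
#' @param horizon_months Prediction horizon (default 36).
#' @param seed Seed for the observation noise.
#' @return A list of class `cohort_result`: `calibrations`, `trajectories`,
#'   `observed`, `score_table`, `group_label` (truth-derived stable-like /
#'   unstable-like split), `ttests`, `correlations` (per group and factor),
#'   `nc_growth_t3`.
#' @export
run_cohort_pipeline <- function(cohort, p = default_parameters(),
                                cfg = solver_config(), noise = 0,
                                observed = NULL, horizon_months = 36,
                                seed = NULL) {
  np <- length(cohort$patients)
  calibs <- vector("list", np)
  trajs <- vector("list", np)
  obs <- numeric(np)
  factors <- vector("list", np)
  for (i in seq_len(np)) {
    pt <- cohort$patients[[i]]
    g <- cohort$geometries[[i]]
    obs[i] <- if (!is.null(observed)) observed[i] else
      generate_observed_followup(pt, cohort$truths[i, ], g, p, cfg,
                                 noise = noise,
                                 seed = if (is.null(seed)) NULL else seed + i)
    calibs[[i]] <- calibrate_t2(pt, obs[i], g, p = p, cfg = cfg)
    trajs[[i]] <- predict_t3(pt, calibs[[i]], g, p, cfg,
                             horizon_months = horizon_months)
    final <- trajs[[i]]$means[nrow(trajs[[i]]$means), ]
    factors[[i]] <- data.frame(
      id = pt$id, PB = plaque_burden(g), EI = eccentricity_index(g),
      LDL = pt$LDL, HDL = pt$HDL, WSS = pt$WSS,
      MPhi = final[["Ma"]], SMC = final[["S"]], oxLDL = final[["Lox"]])
  }
  factors <- do.call(rbind, factors)
  scores <- if (np >= 2) score_cohort(factors) else NULL

  group_label <- ifelse(cohort$truths$inflammation == "mild",
                        "stable-like", "unstable-like")
  stat_factors <- c("L", "Lox", "Mo", "Ma", "P", "S", "CECM", "F")
  pool <- function(idx) {
    stats::setNames(lapply(stat_factors, function(f)
      unlist(lapply(trajs[idx], function(tr) tr$means[, f]))), stat_factors)
  }
  idx_s <- which(group_label == "stable-like")
  idx_u <- which(group_label == "unstable-like")
  both_groups <- length(idx_s) > 0 && length(idx_u) > 0
  tt <- if (both_groups) group_ttest(pool(idx_s), pool(idx_u)) else NULL

  cors <- if (!both_groups) NULL else
    do.call(rbind, lapply(c("stable-like", "unstable-like"), function(gl) {
    idx <- which(group_label == gl)
    do.call(rbind, lapply(stat_factors, function(f) {
      fac <- unlist(lapply(trajs[idx], function(tr) tr$means[, f]))
      nc <- unlist(lapply(trajs[idx], function(tr) tr$nc_area))
      res <- spearman_nc_correlation(fac, nc)
      data.frame(group = gl, factor = f, r = res$r, p_value = res$p_value,
                 flag = res$flag)
    }))
  }))

  structure(list(
    calibrations = calibs, trajectories = trajs, observed = obs,
    factors = factors, score_table = scores, group_label = group_label,
    ttests = tt, correlations = cors,
    nc_growth_t3 = vapply(trajs, nc_growth_rate, numeric(1))
  ), class = "cohort_result")
}

#' Run the patient workflow from a config file
#'
#' Thin orchestration entry for the command-line tool. The YAML config
#' names either a synthetic cohort (`cohort: synthetic: ...`) or a list of
#' patients with geometry masks, plus optional solver settings, parameter
#' overrides or parameter file, observation noise and output directory.
#' Executes calibrate, predict and analyze for every patient and writes
#' per-patient trajectory CSVs, a calibration summary, the cohort score
#' table, group statistics and a log with version, seed and parameters.
#'
#' @param config_path Path to the YAML config.
#' @return The output directory, invisibly.
#' @export
run_patient_cli <- function(config_path) {
  if (!file.exists(config_path))
    stop("usage error: config file not found: ", config_path, call. = FALSE)
  conf <- yaml::read_yaml(config_path)
  out_dir <- conf$output_dir %||% "plaquesim-output"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  p <- if (!is.null(conf$params_file)) read_parameters(conf$params_file)
       else do.call(default_parameters, as.list(conf$params %||% list()))
  sc <- conf$solver %||% list()
  cfg <- solver_config(
    dt = sc$dt %||% NA,
    safety_factor = sc$safety_factor %||% 0.8,
    t_end = sc$t_end %||% 36,
    snapshot_interval = sc$snapshot_interval %||% 1)

  cohort <- .config_cohort(conf)
  res <- run_cohort_pipeline(cohort, p, cfg, noise = conf$noise %||% 0,
                             observed = conf$observed_growth,
                             horizon_months = sc$t_end %||% 36,
                             seed = conf$seed %||% NULL)

  for (i in seq_along(res$trajectories))
    write_trajectory_csv(res$trajectories[[i]],
      file.path(out_dir, paste0("trajectory_", cohort$patients[[i]]$id, ".csv")))
  calib_df <- do.call(rbind, lapply(seq_along(res$calibrations), function(i)
    data.frame(id = cohort$patients[[i]]$id,
               observed_growth = res$observed[i],
               inflammation = res$calibrations[[i]]$inflammation,
               microvessel = res$calibrations[[i]]$microvessel)))
  utils::write.csv(calib_df, file.path(out_dir, "calibration.csv"),
                   row.names = FALSE)
  if (!is.null(res$score_table))
    utils::write.csv(res$score_table, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
  if (!is.null(res$ttests))
    utils::write.csv(res$ttests, file.path(out_dir, "group_ttests.csv"),
                     row.names = FALSE)
  if (!is.null(res$correlations))
    utils::write.csv(res$correlations, file.path(out_dir, "nc_correlations.csv"),
                     row.names = FALSE)
  writeLines(c(
    paste0("plaquesim version: ",
           as.character(utils::packageVersion("plaquesim"))),
    paste0("config: ", normalizePath(config_path)),
    paste0("seed: ", conf$seed %||% "none"),
    paste0("grid: ", cohort$geometries[[1]]$n_rows, "x",
           cohort$geometries[[1]]$n_cols, " cells, h = ",
           signif(cohort$geometries[[1]]$h, 4), " um"),
    paste0("dt: ", signif(res$trajectories[[1]]$dt, 4), " months"),
    paste0("parameters: ", paste(names(p), unlist(p), sep = "=",
                                 collapse = "; "))
  ), file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

## build the cohort described by a parsed config
.config_cohort <- function(conf) {
  if (!is.null(conf$cohort$synthetic)) {
    syn <- conf$cohort$synthetic
    ## YAML 1.1 parses a bare `n` key as a boolean; accept both spellings
    names(syn)[names(syn) %in% c("FALSE", "grid_n")] <- "n"
    spec <- do.call(cohort_spec, syn)
    return(generate_cohort(spec))
  }
  if (is.null(conf$patients))
    stop("usage error: config needs either `cohort: synthetic:` or `patients:`",
         call. = FALSE)
  patients <- list(); geometries <- list()
  for (i in seq_along(conf$patients)) {
    pc <- conf$patients[[i]]
    g <- if (!is.null(pc$geometry$mask))
      load_label_mask(pc$geometry$mask, pc$geometry$pixel_size_um %||% 20)
    else if (!is.null(pc$geometry$synthetic))
      do.call(generate_synthetic_geometry, pc$geometry$synthetic)
    else stop("usage error: patient ", i, " has no geometry", call. = FALSE)
    n0 <- pc$N0 %||% (0.12 * sum(g$intima) * g$h^2)
    patients[[i]] <- patient_record(
      id = pc$id %||% paste0("P", i), LDL = pc$LDL, HDL = pc$HDL,
      WSS = pc$WSS, interval_months = pc$interval_months, N0 = n0)
    geometries[[i]] <- g
  }
  truths <- if (!is.null(conf$truths)) as.data.frame(conf$truths)
            else .cohort_truths(length(patients))
  structure(list(patients = patients, geometries = geometries,
                 truths = truths, spec = NULL), class = "plaque_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
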