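#' Patient record
#'
#' Baseline (T1) clinical inputs of one patient: plasma LDL and HDL, local
#' wall shear stress (held at its baseline value throughout the simulation),
#' and the T1 to T2 follow-up interval. `N0` is the image-derived baseline
#' necrotic-core area.
#'
#' @param id Patient identifier.
#' @param LDL,HDL Plasma lipids (mg/dL).
#' @param WSS Wall shear stress (dyn/cm^2).
#' @param interval_months Follow-up interval T1 to T2 (months).
#' @param N0 Baseline NC area (um^2).
#' @param monocyte_label Optional plasma monocyte grade label.
#' @param demographics Optional named list (age, gender, vessel, ...).
#' @return A list of class `patient_record`.
#' @export
patient_record <- function(id, LDL, HDL, WSS, interval_months, N0 = NA,
                           monocyte_label = NA_character_,
                           demographics = list()) {
  if (any(c(LDL, HDL, WSS) <= 0)) stop("LDL, HDL, WSS must be > 0", call. = FALSE)
  if (interval_months <= 0) stop("follow-up interval must be > 0", call. = FALSE)
  structure(list(id = id, LDL = LDL, HDL = HDL, WSS = WSS,
                 interval_months = interval_months, N0 = N0,
                 monocyte_label = monocyte_label,
                 demographics = demographics),
            class = "patient_record")
}

#' Candidate level grid for calibration
#'
#' The full cross of the three inflammation levels with the three
#' microvessel levels, ordered from milder to severer (so that residual
#' ties resolve towards the milder pair).
#'
#' @return Data frame with columns `inflammation`, `microvessel`.
#' @export
default_levels <- function() {
  grid <- expand.grid(inflammation = c("mild", "moderate", "severe"),
                      microvessel = c("low", "mid", "high"),
                      stringsAsFactors = FALSE)
  sev <- as.integer(factor(grid$inflammation,
                           c("mild", "moderate", "severe"))) +
    as.integer(factor(grid$microvessel, c("low", "mid", "high")))
  ord <- order(sev,
               as.integer(factor(grid$inflammation, c("mild", "moderate", "severe"))),
               as.integer(factor(grid$microvessel, c("low", "mid", "high"))))
  grid[ord, , drop = FALSE]
}

## patient-specific parameter set: WSS and plasma LDL ride on the record
.patient_params <- function(patient, p) {
  p$WSS <- patient$WSS
  p$C_LDL <- patient$LDL
  p
}

#' Simulated NC growth of every candidate level pair
#'
#' Runs one simulation per candidate (inflammation, microvessel) pair to
#' the patient's follow-up interval and returns the NC growth rate of each.
#'
#' @param patient A [patient_record()].
#' @param g A [plaque_geometry()].
#' @param levels Candidate grid as from [default_levels()].
#' @param p A [default_parameters()] set.
#' @param cfg A [solver_config()]; its horizon is overridden by the
#'   patient's interval.
#' @return `levels` with a `growth` column appended.
#' @export
candidate_growths <- function(patient, g, levels = default_levels(),
                              p = default_parameters(),
                              cfg = solver_config()) {
  p <- .patient_params(patient, p)
  cfg$t_end <- patient$interval_months
  levels$growth <- vapply(seq_len(nrow(levels)), function(i) {
    init <- initial_conditions(levels$inflammation[i], levels$microvessel[i])
    traj <- run_simulation(g, p, init, cfg, N0 = patient$N0)
    nc_growth_rate(traj)
  }, numeric(1))
  levels
}

## residual-minimizing row; `levels` ordered milder-first so the first
## strict minimum realizes the tie rule
.select_level_pair <- function(growths, observed) {
  residuals <- abs(growths$growth - observed)
  best <- which(residuals == min(residuals))[1L]
  list(row = best, residuals = residuals)
}

#' Calibrate initial inflammation and microvessel levels at follow-up
#'
#' The two microenvironmental unknowns that imaging cannot measure are
#' identified by simulation: each candidate (inflammation, microvessel)
#' pair is simulated to the follow-up time T2 and the pair whose simulated
#' NC growth is closest (smallest absolute residual) to the observed growth
#' is selected; exact ties resolve to the milder pair.
#'
#' @inheritParams candidate_growths
#' @param observed_growth Observed NC growth ratio at T2 (>= 0).
#' @param precomputed Optional output of [candidate_growths()] to reuse.
#' @return A list of class `calibration_result`: chosen `inflammation` and
#'   `microvessel`, the per-candidate `table` (levels, growth, residual)
#'   and `observed`.
#' @export
calibrate_t2 <- function(patient, observed_growth, g,
                         levels = default_levels(),
                         p = default_parameters(), cfg = solver_config(),
                         precomputed = NULL) {
  if (!is.finite(observed_growth) || observed_growth < 0)
    stop("observed growth must be a nonnegative number", call. = FALSE)
  if (nrow(levels) == 0L) stop("calibration error: empty candidate grid",
                               call. = FALSE)
  growths <- if (is.null(precomputed))
    tryCatch(candidate_growths(patient, g, levels, p, cfg),
             error = function(e)
               stop("calibration error: all candidates failed to simulate (",
                    conditionMessage(e), ")", call. = FALSE))
  else precomputed
  sel <- .select_level_pair(growths, observed_growth)
  growths$residual <- sel$residuals
  structure(list(
    inflammation = growths$inflammation[sel$row],
    microvessel = growths$microvessel[sel$row],
    table = growths, observed = observed_growth
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> inflammation = %s, microvessel = %s (observed growth %.3f)\n",
              x$inflammation, x$microvessel, x$observed))
  invisible(x)
}

#' Predict plaque development to three years (T3)
#'
#' Re-runs the simulation from baseline with the calibrated levels to the
#' 36-month horizon, returning the full trajectory with NC and plaque
#' burden series.
#'
#' @inheritParams candidate_growths
#' @param calib A `calibration_result`.
#' @param horizon_months Prediction horizon (default 36).
#' @return A `plaque_trajectory`.
#' @export
predict_t3 <- function(patient, calib, g, p = default_parameters(),
                       cfg = solver_config(), horizon_months = 36) {
  stopifnot(inherits(calib, "calibration_result"))
  p <- .patient_params(patient, p)
  cfg$t_end <- horizon_months
  init <- initial_conditions(calib$inflammation, calib$microvessel)
  run_simulation(g, p, init, cfg, N0 = patient$N0)
}
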