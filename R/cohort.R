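#' Specification of a synthetic four-patient cohort
#'
#' Declares the ranges from which a fully synthetic cohort is drawn:
#' eccentric annular plaque geometries plus patient records with plasma
#' LDL/HDL, WSS and follow-up intervals bracketing the values typical of a
#' coronary follow-up study (LDL 70--160 mg/dL, HDL 19--38 mg/dL, WSS
#' 77--141 dyn/cm^2, intervals 5--13 months). The default cohort has two
#' low-inflammation ("stable-like") and two high-inflammation
#' ("unstable-like") patients. The intima-thickness bracket is kept narrow:
#' relative NC growth scales inversely with wall thickness, and a cohort
#' designed to contrast inflammation groups should not let geometric spread
#' dominate that contrast.
#'
#' @param n_patients Number of patients (default 4).
#' @param seed Master seed; the same seed reproduces the cohort exactly.
#' @param n Grid size of the generated geometries (default 200, i.e. the
#'   20 um discretization of a 4 mm domain).
#' @param ldl_range,hdl_range,wss_range,interval_range Per-record sampling
#'   brackets.
#' @param lumen_radius_range,intima_base_range,ecc_amplitude_range Geometry
#'   brackets in micrometres.
#' @param media_thickness Media ring thickness (um).
#' @param n0_fraction Baseline NC area as a fraction of the intima area.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 4, seed = 1, n = 200,
                        ldl_range = c(70, 160), hdl_range = c(19, 38),
                        wss_range = c(77, 141), interval_range = c(5, 13),
                        lumen_radius_range = c(800, 1000),
                        intima_base_range = c(340, 390),
                        ecc_amplitude_range = c(50, 120),
                        media_thickness = 250, n0_fraction = 0.12) {
  ## worst-case outer radius (1000 + 550 + 250 = 1800 um) stays inside the
  ## 4 mm domain at any resolution n >= 36
  stopifnot(n_patients >= 2, n >= 36)
  structure(as.list(environment()), class = "cohort_spec")
}

## true (unobservable) levels: first half stable-like, second unstable-like
.cohort_truths <- function(n_patients) {
  half <- ceiling(n_patients / 2)
  data.frame(
    inflammation = rep(c("mild", "severe"), c(half, n_patients - half)),
    microvessel = c(rep(c("low", "mid"), length.out = half),
                    rep(c("mid", "high"), length.out = n_patients - half)),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic cohort
#'
#' Draws `n_patients` patient records and eccentric plaque geometries from
#' the brackets of a [cohort_spec()], together with the true (unobservable)
#' inflammation and microvessel levels used to manufacture follow-up
#' observations. Deterministic for a fixed seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `plaque_cohort` with elements `patients` (list
#'   of [patient_record()]), `geometries` (list of [plaque_geometry()]),
#'   `truths` (data frame of true levels) and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  np <- spec$n_patients
  draws <- .with_seed(spec$seed, list(
    LDL = stats::runif(np, spec$ldl_range[1], spec$ldl_range[2]),
    HDL = stats::runif(np, spec$hdl_range[1], spec$hdl_range[2]),
    WSS = stats::runif(np, spec$wss_range[1], spec$wss_range[2]),
    interval = round(stats::runif(np, spec$interval_range[1],
                                  spec$interval_range[2])),
    lumen_r = stats::runif(np, spec$lumen_radius_range[1],
                           spec$lumen_radius_range[2]),
    ti_base = stats::runif(np, spec$intima_base_range[1],
                           spec$intima_base_range[2]),
    ecc_amp = stats::runif(np, spec$ecc_amplitude_range[1],
                           spec$ecc_amplitude_range[2]),
    phase = stats::runif(np, 0, 2 * pi)
  ))
  truths <- .cohort_truths(np)

  geometries <- vector("list", np)
  patients <- vector("list", np)
  for (i in seq_len(np)) {
    a <- draws$ti_base[i]; b <- draws$ecc_amp[i]; ph <- draws$phase[i]
    geometries[[i]] <- generate_synthetic_geometry(
      n = spec$n, lumen_radius = draws$lumen_r[i],
      intima_thickness_fn = local({
        a0 <- a; b0 <- b; ph0 <- ph
        function(angle) a0 + b0 * cos(angle - ph0)
      }),
      media_thickness = spec$media_thickness,
      seed = spec$seed + i)
    n0 <- spec$n0_fraction * sum(geometries[[i]]$intima) * geometries[[i]]$h^2
    patients[[i]] <- patient_record(
      id = paste0("SP", i), LDL = draws$LDL[i], HDL = draws$HDL[i],
      WSS = draws$WSS[i], interval_months = draws$interval[i], N0 = n0)
  }
  structure(list(patients = patients, geometries = geometries,
                 truths = truths, spec = spec), class = "plaque_cohort")
}

#' @export
print.plaque_cohort <- function(x, ...) {
  cat(sprintf("<plaque_cohort> %d synthetic patients (%s)\n",
              length(x$patients),
              paste(x$truths$inflammation, x$truths$microvessel,
                    sep = "/", collapse = ", ")))
  invisible(x)
}

#' Manufacture an observed follow-up NC growth
#'
#' Plays the role of the T2 image measurement: simulates the patient with
#' the true levels to the follow-up interval and perturbs the resulting NC
#' growth with multiplicative Gaussian noise of relative standard deviation
#' `noise`. With `noise = 0` calibration against this observation recovers
#' the truth exactly.
#'
#' @param patient A [patient_record()].
#' @param truth List or one-row data frame with `inflammation` and
#'   `microvessel`.
#' @param g The patient's [plaque_geometry()].
#' @param p A [default_parameters()] set.
#' @param cfg A [solver_config()].
#' @param noise Relative standard deviation of the measurement noise.
#' @param seed Seed for the noise draw.
#' @return Observed NC growth ratio (nonnegative).
#' @export
generate_observed_followup <- function(patient, truth, g,
                                       p = default_parameters(),
                                       cfg = solver_config(),
                                       noise = 0, seed = NULL) {
  p <- .patient_params(patient, p)
  cfg$t_end <- patient$interval_months
  init <- initial_conditions(truth$inflammation, truth$microvessel)
  traj <- run_simulation(g, p, init, cfg, N0 = patient$N0)
  growth <- nc_growth_rate(traj)
  if (noise > 0)
    growth <- growth * (1 + .with_seed(seed, stats::rnorm(1, 0, noise)))
  max(growth, 0)
}

#' Write a cohort to a directory
#'
#' Masks as PNG images, records as a CSV, and the true levels as a
#' separate (test-only) CSV.
#'
#' @param cohort A `plaque_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$patients)) {
    save_label_mask(cohort$geometries[[i]],
                    file.path(dir, paste0(cohort$patients[[i]]$id, "_mask.png")))
  }
  recs <- do.call(rbind, lapply(cohort$patients, function(pt)
    data.frame(id = pt$id, LDL = pt$LDL, HDL = pt$HDL, WSS = pt$WSS,
               interval_months = pt$interval_months, N0_um2 = pt$N0)))
  utils::write.csv(recs, file.path(dir, "records.csv"), row.names = FALSE)
  utils::write.csv(cbind(id = recs$id, cohort$truths),
                   file.path(dir, "truths.csv"), row.names = FALSE)
  invisible(dir)
}
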