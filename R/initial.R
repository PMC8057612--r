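#' Per-species reference scales for nondimensionalization
#'
#' Each species is scaled by a reference concentration so that the simulated
#' fields are dimensionless and comparable between patients. For species
#' initialized at a physiological working level the reference is that
#' initial magnitude (SMC 6e-3 g/cm^3, LDL 1e-3 mg/mm^2, MMP 3e-8 g/cm^3,
#' ECM 4e-2 g/cm^3); species initialized at trace level (ox-LDL, MCP-1,
#' VEGF) are scaled by a plausible maximum instead, so their nondimensional
#' values stay within order one as they grow. Cell densities
#' (monocyte/macrophage/foam cell/EC) and extravascular plasma start at zero
#' and carry working-level references. The global scales map one
#' nondimensional time unit to one month (`t_ref`) and one length unit to
#' one grid cell (`x_ref = h`).
#'
#' @param h Cell edge length in micrometres (sets `x_ref`).
#' @return A list of class `reference_scales`: `conc` (named per-species
#'   reference, physical units per species), `conc_unit`, `t_ref_months`,
#'   `x_ref_um`.
#' @export
reference_scales <- function(h = 20) {
  conc <- c(
    L = 1.0e-3,   # mg/mm^2 (initial LDL)
    Lox = 1.0e-3, # mg/mm^2 (plausible maximum; initial is 1e-7)
    P = 3.0e-7,   # g/cm^3 (plausible maximum; initial is 3e-10)
    Mo = 1.0e6,   # cells/cm^3
    Ma = 1.0e6,   # cells/cm^3
    F = 1.0e6,    # cells/cm^3
    S = 6.0e-3,   # g/cm^3 (initial media SMC)
    CECM = 4.0e-2,# g/cm^3 (initial ECM)
    CM = 3.0e-8,  # g/cm^3 (initial MMP)
    E = 1.0e6,    # cells/cm^3
    Cv = 8.0e-10, # g/cm^3 (plausible maximum; initial mean is 4e-10)
    Pl = 1.0      # dimensionless proxy for extravasated plasma
  )
  unit <- c(L = "mg/mm^2", Lox = "mg/mm^2", P = "g/cm^3", Mo = "cells/cm^3",
            Ma = "cells/cm^3", F = "cells/cm^3", S = "g/cm^3",
            CECM = "g/cm^3", CM = "g/cm^3", E = "cells/cm^3",
            Cv = "g/cm^3", Pl = "1")
  structure(list(conc = conc, conc_unit = unit,
                 t_ref_months = 1, x_ref_um = h),
            class = "reference_scales")
}

#' Nondimensionalize or redimensionalize state fields
#'
#' Divides (multiplies) each species field by its reference concentration.
#' The round trip is the identity.
#'
#' @param state Named list of per-species matrices (a `plaque_state`), or a
#'   single named numeric vector of per-species values.
#' @param scales A [reference_scales()] object.
#' @return The scaled state, same shape as the input.
#' @export
nondimensionalize <- function(state, scales) {
  .scale_state(state, scales, inverse = FALSE)
}

#' @rdname nondimensionalize
#' @export
redimensionalize <- function(state, scales) {
  .scale_state(state, scales, inverse = TRUE)
}

.scale_state <- function(state, scales, inverse) {
  stopifnot(inherits(scales, "reference_scales"))
  if (any(scales$conc <= 0)) stop("config error: zero or negative reference scale",
                                  call. = FALSE)
  f <- if (inverse) function(v, ref) v * ref else function(v, ref) v / ref
  if (is.list(state)) {
    out <- state
    for (sp in intersect(names(state), species_names()))
      out[[sp]] <- f(state[[sp]], scales$conc[[sp]])
    out
  } else {
    refs <- scales$conc[names(state)]
    f(state, refs)
  }
}

#' Initial-condition specification
#'
#' Encodes the baseline (T1) plaque microenvironment: SMC 6e-3 g/cm^3 in
#' media and 3e-3 g/cm^3 in intima; LDL 1.0e-3 mg/mm^2 and ox-LDL
#' 1e-7 mg/mm^2 distributed evenly in the intima; MMP 3e-8, MCP-1 3e-10 and
#' ECM 4e-2 g/cm^3; VEGF with mean 4e-10 g/cm^3 and a gradient rising from
#' the media towards the intima (stimulating inward neovascularization);
#' monocytes, macrophages, foam cells and extravascular plasma absent at
#' baseline. The unobservable initial inflammation is encoded as a plasma
#' monocyte level (mild/moderate/severe = 4, 8, 16 x 1e5 cells/cm^3 feeding
#' the endothelial influx) and the unobservable microvessel status as a
#' low/mid/high scaling of the initial EC density on the media rim adjacent
#' to the external elastic membrane, where vasa-vasorum-derived microvessels
#' enter.
#'
#' @param inflammation One of `"mild"`, `"moderate"`, `"severe"`.
#' @param microvessel One of `"low"`, `"mid"`, `"high"`.
#' @param ec_rim_density Baseline nondimensional EC density at the EEM rim
#'   (scaled by the microvessel level).
#' @param ec_decay_um Decay length (um) of the EC density into the wall:
#'   microvessels sprout from the vasa vasorum at the EEM and penetrate the
#'   media and, more sparsely, the deep intima.
#' @return A list of class `plaque_init`.
#' @export
initial_conditions <- function(inflammation = c("mild", "moderate", "severe"),
                               microvessel = c("low", "mid", "high"),
                               ec_rim_density = 0.5, ec_decay_um = 150) {
  inflammation <- match.arg(inflammation)
  microvessel <- match.arg(microvessel)
  structure(list(
    inflammation = inflammation,
    microvessel = microvessel,
    C_Mo = c(mild = 4e5, moderate = 8e5, severe = 16e5)[[inflammation]],
    microvessel_scale = c(low = 0.4, mid = 1, high = 2.2)[[microvessel]],
    ec_rim_density = ec_rim_density,
    ec_decay_um = ec_decay_um,
    ## physical initial magnitudes (units as in reference_scales)
    phys = c(S_media = 6e-3, S_intima = 3e-3, L = 1.0e-3, Lox = 1e-7,
             CM = 3e-8, P = 3e-10, CECM = 4e-2, Cv_mean = 4e-10)
  ), class = "plaque_init")
}

#' Build the nondimensional initial state on a geometry
#'
#' Realizes [initial_conditions()] as the twelve nondimensional fields on
#' the active (intima + media) cells of a geometry. The VEGF gradient is
#' constructed from the normalized wall depth `u` (0 at the endothelium, 1
#' at the EEM) as `Cv = Cv_mean * (1.5 - u)`, i.e. highest near the hypoxic
#' thickened intima; its wall average equals the stated mean. The EC density
#' decays exponentially from the EEM rim into the wall. Values on lumen and
#' exterior cells are identically zero.
#'
#' @param g A [plaque_geometry()].
#' @param init A `plaque_init`.
#' @param scales A [reference_scales()]; defaults to `reference_scales(g$h)`.
#' @return Named list of class `plaque_state`: twelve matrices, plus no
#'   values outside the active region.
#' @export
build_initial_state <- function(g, init = initial_conditions(),
                                scales = reference_scales(g$h)) {
  stopifnot(inherits(g, "plaque_geometry"), inherits(init, "plaque_init"))
  zero <- matrix(0, g$n_rows, g$n_cols)
  st <- stats::setNames(rep(list(zero), length(species_names())), species_names())

  ref <- scales$conc
  ph <- init$phys
  st$S[g$media] <- ph[["S_media"]] / ref[["S"]]
  st$S[g$intima] <- ph[["S_intima"]] / ref[["S"]]
  st$L[g$intima] <- ph[["L"]] / ref[["L"]]
  st$Lox[g$intima] <- ph[["Lox"]] / ref[["Lox"]]
  st$CM[g$active] <- ph[["CM"]] / ref[["CM"]]
  st$P[g$active] <- ph[["P"]] / ref[["P"]]
  st$CECM[g$active] <- ph[["CECM"]] / ref[["CECM"]]

  ## normalized wall depth: 0 at endothelium, 1 at EEM rim
  d_lum <- .grid_distance(g$active, g$endothelium)
  d_eem <- .grid_distance(g$active, g$eem)
  u <- d_lum / pmax(d_lum + d_eem, 1e-12)
  cv <- (ph[["Cv_mean"]] / ref[["Cv"]]) * (1.5 - u)
  st$Cv[g$active] <- cv[g$active]

  ## microvessel seed: EC density decaying from the EEM rim into the wall
  ec <- init$ec_rim_density * init$microvessel_scale *
    exp(-d_eem * g$h / init$ec_decay_um)
  st$E[g$active] <- ec[g$active]

  structure(st, class = "plaque_state")
}
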