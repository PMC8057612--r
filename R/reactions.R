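#' Endothelial solute influx of LDL
#'
#' Transluminal LDL flux per unit endothelium length, modulated by the local
#' wall shear stress: `J_LDL = L_cr * C_LDL / (1 + WSS / WSS0)`. Low shear
#' promotes lipoprotein infiltration through the injured endothelium; at
#' `WSS = WSS0` the flux is half its no-shear value.
#'
#' @param C_LDL Plasma LDL concentration (mg/dL).
#' @param WSS Wall shear stress (dyn/cm^2).
#' @param p A [default_parameters()] set supplying `L_cr` (m/s, default
#'   2e-5) and `WSS0` (default 100 dyn/cm^2).
#' @return The flux `J_LDL` (conductive-rate units times concentration).
#' @export
#' @examples
#' p <- default_parameters()
#' endothelial_influx_ldl(70.4, 85.8, p)
endothelial_influx_ldl <- function(C_LDL, WSS, p = default_parameters()) {
  if (any(C_LDL < 0) || any(WSS < 0))
    stop("domain error: C_LDL and WSS must be >= 0", call. = FALSE)
  p$L_cr * C_LDL / (1 + WSS / p$WSS0)
}

#' Endothelial influx of monocytes
#'
#' Transluminal monocyte flux per unit endothelium length:
#' `J_Mo = Mo_cr * C_Mo / (1 + WSS / WSS0)`, with the plasma monocyte level
#' `C_Mo` set by the inflammation grade (4, 8, 16 x 1e5 cells/cm^3 for
#' mild/moderate/severe).
#'
#' @param C_Mo Plasma monocyte density (cells/cm^3).
#' @inheritParams endothelial_influx_ldl
#' @return The flux `J_Mo`.
#' @export
endothelial_influx_monocyte <- function(C_Mo, WSS, p = default_parameters()) {
  if (any(C_Mo < 0) || any(WSS < 0))
    stop("domain error: C_Mo and WSS must be >= 0", call. = FALSE)
  p$Mo_cr * C_Mo / (1 + WSS / p$WSS0)
}

.check_state <- function(state, g) {
  if (!is.list(state) || !all(species_names() %in% names(state)))
    stop("state must contain all twelve species fields", call. = FALSE)
  invisible(TRUE)
}

#' Local reaction rates of the twelve-field model
#'
#' Assembles the per-cell reaction terms (no transport, no boundary influx)
#' of the coupled model: LDL oxidation and its leaky-microvessel source;
#' ox-LDL formation and macrophage phagocytosis; MCP-1 production by ECs
#' (Michaelis-saturated in ox-LDL) and SMCs with first-order decay;
#' monocyte extravasation, differentiation into macrophages and decay;
#' macrophage gain from differentiation and apoptosis; VEGF uptake by ECs,
#' production by SMCs and macrophages, and decay; ox-LDL-induced SMC
#' apoptosis; ECM degradation by MMP and production by SMCs; MMP production
#' by ECs and SMCs with decay; foam-cell production proportional to the
#' phagocytosis term with slow decay; and plasma extravasation proportional
#' to the local EC density, saturating as the tissue plasma level
#' approaches its capacity `Pl_max`. ECs have no local reaction (transport
#' only).
#'
#' @param state A `plaque_state` (named list of twelve matrices).
#' @param p A [default_parameters()] set.
#' @param g A [plaque_geometry()].
#' @return Named list of twelve rate matrices (d/dt of each species).
#' @export
reaction_rhs <- function(state, p, g) {
  .check_state(state, g)
  L <- state$L; Lox <- state$Lox; P <- state$P; Mo <- state$Mo
  Ma <- state$Ma; F <- state$F; S <- state$S; CECM <- state$CECM
  CM <- state$CM; E <- state$E; Cv <- state$Cv; Pl <- state$Pl

  phago <- p$lambda_LoxMa * Lox * Ma
  rates <- list(
    L    = -p$lambda_L * L + p$lambda_Plextra * Pl,
    Lox  = p$lambda_LoxL * L - phago,
    P    = p$lambda_PE * E * Lox / (p$K_P + Lox) + p$lambda_PS * S - p$d_P * P,
    Mo   = p$lambda_Plextra * Pl - p$lambda_MaMo * Mo - p$d_Mo * Mo,
    Ma   = p$lambda_MaMo * Mo - p$d_Ma * Ma,
    F    = p$lambda_F * Lox * Ma - p$d_F * F,
    S    = -p$d_S * S * Lox,
    CECM = -p$lambda_CMCECM * CECM * CM + p$lambda_SCECM_prod * S,
    CM   = p$lambda_CME * E + p$lambda_CMS * S - p$d_CM * CM,
    E    = state$E * 0,
    Cv   = -p$lambda_CvE * E + p$lambda_CvS * S + p$lambda_CvMa * Ma - p$d_Cv * Cv,
    Pl   = p$gamma * p$q_t * E *
      (if (p$Pl_max > 0) pmax(1 - Pl / p$Pl_max, 0) else 0)
  )
  for (sp in species_names()) {
    bad <- !is.finite(rates[[sp]]) & g$active
    if (any(bad)) {
      idx <- which(bad)[1L]
      stop(sprintf("numerical error: non-finite reaction rate for %s at cell %d",
                   sp, idx), call. = FALSE)
    }
    rates[[sp]][!g$active] <- 0
  }
  rates[species_names()]
}

#' Taxis specifications of the motile species
#'
#' Returns, for each motile species, the attractant field(s) and the
#' sensitivity coefficient defining its advective flux. All terms are
#' attractive: cells move up the attractant gradient, with flux
#' `J = lambda * C * grad(attractant)` entering the balance as `-div(J)`.
#' Macrophages and SMCs chemotax towards MCP-1, SMCs additionally towards
#' macrophage-secreted PDGF (proxied by the macrophage field) and along the
#' ECM (haptotaxis); monocytes are recruited towards ox-LDL; ECs chemotax
#' towards VEGF with saturated sensitivity `lambda_ECv / (K_E + Cv)` and
#' haptotax along the ECM.
#'
#' @inheritParams reaction_rhs
#' @return Named list (by motile species) of lists with elements
#'   `attractant` (species name) and `coeff` (scalar or per-cell matrix).
#' @export
taxis_velocity_fields <- function(state, p, g) {
  .check_state(state, g)
  list(
    Ma = list(list(attractant = "P", coeff = p$lambda_MaP)),
    Mo = list(list(attractant = "Lox", coeff = p$lambda_MoLox)),
    E = list(
      list(attractant = "Cv", coeff = p$lambda_ECv / (p$K_E + state$Cv)),
      list(attractant = "CECM", coeff = p$lambda_ECECM)
    ),
    S = list(
      list(attractant = "P", coeff = p$lambda_SP),
      list(attractant = "Ma", coeff = p$lambda_SMa),
      list(attractant = "CECM", coeff = p$lambda_SCECM_taxis)
    )
  )
}

#' Add endothelial boundary influx to reaction rates
#'
#' Converts the per-unit-length transluminal fluxes of
#' [endothelial_influx_ldl()] and [endothelial_influx_monocyte()] into
#' per-cell volumetric sources at the endothelium cells only. Each
#' endothelium cell receives flux through one face of length `h` into a
#' cell of area `h^2`, so the concentration source rate scales inversely
#' with the cell size (`scale = x_ref / h`); the nondimensional flux is the physical flux
#' scaled by the gap-filled gains `k_influx_L / (L_cr * C_ref_LDL)` and
#' `k_influx_Mo / (Mo_cr * C_ref_Mo)`.
#'
#' @param rates Output of [reaction_rhs()].
#' @param state A `plaque_state` (unused; kept for a uniform signature).
#' @param scale Cell-size rescaling `x_ref / h` (1 at the reference 20 um).
#' @inheritParams reaction_rhs
#' @return `rates` with the LDL and monocyte sources added at endothelium
#'   cells.
#' @export
apply_boundary_influx <- function(rates, state, g, p, scale = 1) {
  if (length(g$endothelium) == 0L) return(rates)
  j_ldl <- if (p$k_influx_L > 0 && p$L_cr > 0)
    endothelial_influx_ldl(p$C_LDL, p$WSS, p) *
      p$k_influx_L / (p$L_cr * p$C_ref_LDL) else 0
  j_mo <- if (p$k_influx_Mo > 0 && p$Mo_cr > 0)
    endothelial_influx_monocyte(p$C_Mo, p$WSS, p) *
      p$k_influx_Mo / (p$Mo_cr * p$C_ref_Mo) else 0
  ## `scale` = x_ref / h: the source band is one cell wide, so the
  ## per-cell concentration rate scales inversely with the cell size
  rates$L[g$endothelium] <- rates$L[g$endothelium] + j_ldl * scale
  rates$Mo[g$endothelium] <- rates$Mo[g$endothelium] + j_mo * scale
  rates
}
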