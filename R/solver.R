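#' Solver configuration
#'
#' Controls the explicit Euler integration. `dt = NA` derives the step from
#' the stability bound via [stable_timestep()]; an explicit `dt` is used as
#' given. Time is measured in months (one nondimensional time unit), space
#' in grid cells (`x_ref = h`).
#'
#' @param dt Time step in months, or `NA` to derive it from the stability
#'   bound.
#' @param safety_factor Fraction (0--1] of the stability-limited step used.
#' @param t_end Simulated horizon in months (default 36, three years).
#' @param snapshot_interval Output cadence in months.
#' @param scales A [reference_scales()] object.
#' @param dirichlet_outer If `TRUE`, clamp the EEM rim cells to their
#'   initial values after every step (literal fixed-value outer boundary)
#'   instead of the default zero-flux closure.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(dt = NA, safety_factor = 0.8, t_end = 36,
                          snapshot_interval = 1, scales = reference_scales(),
                          dirichlet_outer = FALSE) {
  stopifnot(safety_factor > 0, safety_factor <= 1, t_end >= 0,
            snapshot_interval > 0)
  structure(list(dt = dt, safety_factor = safety_factor, t_end = t_end,
                 snapshot_interval = snapshot_interval, scales = scales,
                 dirichlet_outer = dirichlet_outer),
            class = "solver_config")
}

#' Masked 5-point Laplacian with zero-flux closure
#'
#' Discrete Laplacian on the active (intima + media) cells. At every
#' interface to an inactive cell (lumen, exterior) and at the grid edge the
#' mirror (zero normal flux) closure is used, which is the "no mass
#' transport at the outer boundary" condition at the EEM.
#'
#' @param field Matrix defined on the active cells (zero elsewhere).
#' @param g A [plaque_geometry()].
#' @param h Grid spacing used in the stencil; `g$h` (micrometres) for
#'   physical fields, 1 for the solver's nondimensional cell units.
#' @return Matrix of the same shape; units `field / h^2`.
#' @export
laplacian <- function(field, g, h = g$h) {
  lap <- (g$a_n * (.nbr_n(field) - field) +
          g$a_s * (.nbr_s(field) - field) +
          g$a_w * (.nbr_w(field) - field) +
          g$a_e * (.nbr_e(field) - field)) / h^2
  lap[!g$active] <- 0
  lap
}

#' Conservative taxis divergence
#'
#' Flux-form discretization of a chemotaxis/haptotaxis term. The advective
#' face velocity up the attractant gradient is
#' `v_face = coeff_face * (attr_nb - attr) / h` (spatially varying
#' sensitivities averaged onto the face); the transported density is taken
#' from the donor (upwind) cell, optionally damped by a volume-filling
#' factor `(1 - C/c_max)+` that switches migration off in crowded tissue.
#' Fluxes exist only on faces joining two active cells, so the normal flux
#' at the domain boundary is zero and the scheme is exactly conservative:
#' the returned contribution `-div(J)` sums to zero over the closed domain.
#' Donor-cell upwinding makes the scheme positivity-preserving under the
#' advective CFL bound of [stable_timestep()].
#'
#' @param C Motile species field.
#' @param attractant Attractant field.
#' @param coeff Taxis sensitivity: scalar or per-cell matrix.
#' @param c_max Volume-filling capacity (default `Inf`, plain linear flux).
#' @inheritParams laplacian
#' @return Matrix: the rate contribution `-div(coeff * C * grad attr)`
#'   with sign convention such that `C` accumulates up the attractant
#'   gradient.
#' @export
taxis_divergence <- function(C, attractant, coeff, g, h = 1, c_max = Inf) {
  if (is.matrix(coeff)) {
    coef_e <- (coeff + .nbr_e(coeff)) / 2
    coef_s <- (coeff + .nbr_s(coeff)) / 2
  } else {
    coef_e <- coeff
    coef_s <- coeff
  }
  q <- if (is.finite(c_max)) C * pmax(1 - C / c_max, 0) else C
  v_e <- coef_e * (.nbr_e(attractant) - attractant) / h
  v_s <- coef_s * (.nbr_s(attractant) - attractant) / h
  flux_e <- g$f_e * v_e * ifelse(v_e > 0, q, .nbr_e(q))
  flux_s <- g$f_s * v_s * ifelse(v_s > 0, q, .nbr_s(q))
  div <- (flux_e - .nbr_w(flux_e) + flux_s - .nbr_n(flux_s)) / h
  -div
}

## rescaling from the reference cell size to this geometry's cells
.cell_scale <- function(g, cfg) {
  x_ref <- if (!is.null(cfg$scales) && !is.null(cfg$scales$x_ref_um))
    cfg$scales$x_ref_um else 20
  x_ref / g$h
}

## largest face-normal taxis speed |coeff * grad(attr)| over the domain
.max_taxis_speed <- function(state, p, g, h = 1) {
  specs <- taxis_velocity_fields(state, p, g)
  vmax <- 0
  for (sp in names(specs)) {
    for (term in specs[[sp]]) {
      a <- state[[term$attractant]]
      cf <- term$coeff
      ce <- if (is.matrix(cf)) (cf + .nbr_e(cf)) / 2 else cf
      cs <- if (is.matrix(cf)) (cf + .nbr_s(cf)) / 2 else cf
      ve <- abs(ce * (.nbr_e(a) - a) / h) * g$f_e
      vs <- abs(cs * (.nbr_s(a) - a) / h) * g$f_s
      vmax <- max(vmax, ve, vs)
    }
  }
  vmax
}

#' Stability-bounded time step
#'
#' Explicit-scheme bound `dt = safety * h^2 / (4 * D_max)` (two space
#' dimensions), further reduced to `safety * h / (4 * v_max)` when the
#' current maximum taxis speed `v_max` would otherwise violate the
#' advective CFL condition (the factor 4 keeps the donor-cell upwind flux
#' positivity-preserving when a cell drains through all four faces), and by
#' `safety / r_max` where `r_max` is the largest first-order sink rate, so
#' fast reactions cannot drain a cell below zero in one step. With no
#' diffusion, no taxis and no sinks the configured `dt` is returned
#' unchanged.
#'
#' @param p A [default_parameters()] set (nondimensional diffusivities).
#' @param cfg A [solver_config()].
#' @param g A [plaque_geometry()].
#' @param state Optional `plaque_state` used to evaluate the taxis bound.
#' @param h Grid spacing (1 in the solver's cell units).
#' @return Time step in months.
#' @export
stable_timestep <- function(p, cfg, g, state = NULL, h = 1) {
  sc <- .cell_scale(g, cfg)
  d_max <- max(unlist(p[grep("^D_", names(p))])) * sc^2
  v_max <- if (is.null(state)) 0 else sc^2 * .max_taxis_speed(state, p, g, h)
  r_max <- .max_sink_rate(p, state)
  if (d_max <= 0 && v_max <= 0 && r_max <= 0) return(cfg$dt)
  dt <- if (d_max > 0) cfg$safety_factor * h^2 / (4 * d_max) else Inf
  ## h/(4 v): a cell can lose mass through all four faces at once
  if (v_max > 0) dt <- min(dt, cfg$safety_factor * h / (4 * v_max))
  ## first-order sinks must not drain more than a cell holds in one step
  if (r_max > 0) dt <- min(dt, cfg$safety_factor / r_max)
  dt
}

## largest per-species linear sink rate (1/month); state-dependent sinks
## are bounded with the current field maxima when a state is supplied
.max_sink_rate <- function(p, state = NULL) {
  r <- c(p$lambda_L, p$d_P, p$lambda_MaMo + p$d_Mo, p$d_Ma, p$d_Cv,
         p$d_CM, p$d_F)
  if (!is.null(state)) {
    r <- c(r,
           p$d_S * max(state$Lox),
           p$lambda_LoxMa * max(state$Ma),
           p$lambda_CMCECM * max(state$CM))
  }
  max(r, 0)
}

#' One explicit Euler step of the coupled system
#'
#' Advances all twelve species simultaneously by
#' `state + dt * (diffusion + taxis + reaction + boundary influx)`.
#' Negative values produced by the explicit update are clipped to zero and
#' counted; the minimum pre-clip value is reported so positivity can be
#' monitored against the stability bound.
#'
#' @param state A `plaque_state`.
#' @param p A [default_parameters()] set.
#' @param g A [plaque_geometry()].
#' @param dt Time step (months); must satisfy the stability bound.
#' @param cfg A [solver_config()] (Dirichlet-outer flag, reference state).
#' @param initial_state State used for the Dirichlet-outer clamp.
#' @return List with elements `state`, `clip_count`, `min_preclip` and
#'   `min_preclip_by_species` (named vector of per-species pre-clip minima).
#' @export
euler_step <- function(state, p, g, dt, cfg = solver_config(),
                       initial_state = NULL) {
  ## transport constants are defined at the reference cell size (x_ref,
  ## 20 um); other resolutions rescale so the physical model is unchanged
  sc <- .cell_scale(g, cfg)
  rates <- reaction_rhs(state, p, g)
  rates <- apply_boundary_influx(rates, state, g, p, scale = sc)
  specs <- taxis_velocity_fields(state, p, g)
  h_nd <- 1
  for (sp in species_names()) {
    total <- rates[[sp]]
    D <- p[[paste0("D_", sp)]] * sc^2
    if (D > 0) total <- total + D * laplacian(state[[sp]], g, h = h_nd)
    if (!is.null(specs[[sp]])) {
      for (term in specs[[sp]])
        total <- total + taxis_divergence(state[[sp]], state[[term$attractant]],
                                          term$coeff * sc^2, g, h = h_nd,
                                          c_max = p$taxis_cmax)
    }
    rates[[sp]] <- total
  }
  clip_count <- 0L
  preclip <- stats::setNames(numeric(length(species_names())), species_names())
  new <- state
  for (sp in species_names()) {
    f <- state[[sp]] + dt * rates[[sp]]
    if (anyNA(f) || any(!is.finite(f[g$active]))) {
      idx <- which(!is.finite(f) & g$active)[1L]
      stop(sprintf("numerical error: non-finite %s at cell %s after step",
                   sp, idx), call. = FALSE)
    }
    preclip[[sp]] <- min(f, 0)
    neg <- f < 0
    if (any(neg)) {
      clip_count <- clip_count + sum(neg)
      f[neg] <- 0
    }
    f[!g$active] <- 0
    new[[sp]] <- f
  }
  min_preclip <- min(preclip)
  if (isTRUE(cfg$dirichlet_outer) && !is.null(initial_state)) {
    for (sp in species_names()) new[[sp]][g$eem] <- initial_state[[sp]][g$eem]
  }
  list(state = new, clip_count = clip_count, min_preclip = min_preclip,
       min_preclip_by_species = preclip)
}

#' Run a full simulation
#'
#' Advances the system from baseline (T1) to `cfg$t_end` months, emitting
#' snapshots of per-species spatial means, necrotic-core area and plaque
#' burden at the configured cadence. The necrotic core is the intima area
#' where the SMC density fell below half its initial value, added to the
#' baseline core area `N0` (an image-derived input in the clinical
#' workflow). The run is fully deterministic.
#'
#' @param g A [plaque_geometry()].
#' @param p A [default_parameters()] set.
#' @param init An [initial_conditions()] object, or a prebuilt
#'   `plaque_state`.
#' @param cfg A [solver_config()].
#' @param N0 Baseline necrotic-core area (um^2) entering the NC series.
#' @return An object of class `plaque_trajectory`: `time` (months),
#'   `means` (time x species matrix of spatial means over the wall),
#'   `nc_area` (um^2, `N0` + newly apoptotic area), `N0`, `pb`,
#'   `clip_count`, `min_preclip`, `dt`, `final_state`, `initial_smc`.
#' @export
run_simulation <- function(g, p = default_parameters(),
                           init = initial_conditions(),
                           cfg = solver_config(), N0 = 0) {
  state <- if (inherits(init, "plaque_state")) init else
    build_initial_state(g, init, cfg$scales)
  ## per-patient plasma monocyte level rides on the inflammation grade
  if (inherits(init, "plaque_init")) p$C_Mo <- init$C_Mo
  initial_state <- state
  initial_smc <- state$S

  adaptive <- is.na(cfg$dt)
  dt <- if (adaptive) stable_timestep(p, cfg, g, state) else cfg$dt
  if (!is.finite(dt) || dt <= 0) dt <- cfg$snapshot_interval

  n_active <- sum(g$active)
  pb <- plaque_burden(g)
  record <- function(t, state) {
    rec_time <<- c(rec_time, t)
    rec_means <<- rbind(rec_means, vapply(species_names(),
      function(sp) sum(state[[sp]]) / n_active, numeric(1)))
    rec_nc <<- c(rec_nc, N0 + nc_area(state, initial_smc, g))
  }
  rec_time <- numeric(0)
  rec_means <- matrix(numeric(0), 0L, length(species_names()))
  rec_nc <- numeric(0)
  record(0, state)
  clip_total <- 0L
  min_preclip <- 0

  t <- 0
  k <- 0L
  next_snap <- cfg$snapshot_interval
  eps <- 1e-9
  while (t < cfg$t_end - eps) {
    ## re-derive the stability bound as taxis gradients steepen
    if (adaptive && k %% 10L == 0L)
      dt <- min(dt, stable_timestep(p, cfg, g, state))
    dt_step <- min(dt, cfg$t_end - t, next_snap - t)
    res <- euler_step(state, p, g, dt_step, cfg, initial_state)
    state <- res$state
    clip_total <- clip_total + res$clip_count
    min_preclip <- min(min_preclip, res$min_preclip)
    t <- t + dt_step
    k <- k + 1L
    if (t >= next_snap - eps || t >= cfg$t_end - eps) {
      record(t, state)
      next_snap <- next_snap + cfg$snapshot_interval
    }
  }
  colnames(rec_means) <- species_names()
  structure(list(
    time = rec_time, means = rec_means, nc_area = rec_nc, N0 = N0,
    pb = pb, clip_count = clip_total, min_preclip = min_preclip, dt = dt,
    final_state = state, initial_smc = initial_smc, geometry_h = g$h
  ), class = "plaque_trajectory")
}

#' @export
print.plaque_trajectory <- function(x, ...) {
  cat(sprintf(
    "<plaque_trajectory> %d snapshots over %.1f months (dt = %.4g), PB = %.3f\n",
    length(x$time), max(x$time), x$dt, x$pb))
  cat(sprintf("  NC area %.3g -> %.3g um^2, %d clipped values (min preclip %.2g)\n",
              x$nc_area[1], x$nc_area[length(x$nc_area)], x$clip_count,
              x$min_preclip))
  invisible(x)
}

#' Write trajectory snapshots to CSV
#'
#' One row per snapshot: time (months), per-species spatial means, NC area
#' (um^2), NC growth rate and plaque burden.
#'
#' @param traj A `plaque_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(time_months = traj$time, traj$means,
                   nc_area_um2 = traj$nc_area,
                   nc_growth = if (traj$N0 > 0) traj$nc_area / traj$N0 else NA,
                   pb = traj$pb, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
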