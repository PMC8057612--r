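test_that("masked laplacian reproduces analytic second derivatives", {
  g <- strip_geometry(n_rows = 5, n_cols = 9, h = 20)
  ## constant field -> 0 everywhere
  f <- matrix(0, 5, 9); f[g$active] <- 3.7
  expect_true(all(laplacian(f, g) == 0))
  ## linear ramp -> 0 at interior cells (both lateral neighbours active)
  f2 <- matrix(0, 5, 9)
  f2[g$active] <- col(f2)[g$active] * 2.5
  lap2 <- laplacian(f2, g)
  interior <- g$active & col(f2) %in% 3:7
  expect_true(all(abs(lap2[interior]) < 1e-12))
  ## f = x^2 -> second derivative 2, any spacing
  f3 <- matrix(0, 5, 9)
  f3[g$active] <- (col(f3)[g$active] * g$h)^2
  lap3 <- laplacian(f3, g)
  expect_equal(lap3[interior], rep(2, sum(interior)))
})

test_that("taxis divergence is conservative and matches a hand stencil", {
  g <- strip_geometry(n_rows = 6, n_cols = 10)
  set.seed(5)
  C <- matrix(0, 6, 10); C[g$active] <- stats::runif(sum(g$active))
  ## uniform attractant -> no flux
  attr_u <- matrix(0, 6, 10); attr_u[g$active] <- 1.4
  expect_true(all(taxis_divergence(C, attr_u, 2, g) == 0))
  ## arbitrary attractant: total mass change is exactly zero
  attr_r <- matrix(0, 6, 10); attr_r[g$active] <- stats::runif(sum(g$active))
  expect_equal(sum(taxis_divergence(C, attr_r, 1.5, g)), 0)
  ## 1D 5-cell instance against hand-evaluated upwind face fluxes
  g1 <- strip_geometry(n_rows = 1, n_cols = 7)   # active cols 2..6
  Cv <- c(1.0, 0.5, 0.2, 0.8, 0.3)
  Av <- c(0.1, 0.4, 0.2, 0.9, 0.5)
  C1 <- matrix(0, 1, 7); C1[1, 2:6] <- Cv
  A1 <- matrix(0, 1, 7); A1[1, 2:6] <- Av
  lam <- 2
  v <- lam * diff(Av)                       # face velocities, positive right
  donor <- ifelse(v > 0, Cv[-5], Cv[-1])    # upwind donor density
  fluxes <- c(0, v * donor, 0)              # closed ends
  expected <- -(fluxes[-1] - fluxes[-6])
  got <- taxis_divergence(C1, A1, lam, g1)
  expect_equal(got[1, 2:6], expected)
})

test_that("stable timestep obeys diffusive and advective bounds", {
  g <- strip_geometry()
  cfg1 <- solver_config(safety_factor = 1)
  p <- zero_params(D_L = 1)
  expect_equal(stable_timestep(p, cfg1, g, h = 1), 0.25)
  expect_equal(stable_timestep(p, cfg1, g, h = 0.5), 0.25 / 4)  # halving h quarters dt
  ## no diffusion, no taxis: configured dt passes through
  cfg2 <- solver_config(dt = 0.123)
  expect_equal(stable_timestep(zero_params(), cfg2, g), 0.123)
  ## advective bound: dt never exceeds h / (2 v_max)
  p2 <- zero_params(lambda_MaP = 1)
  st <- zero_state(g)
  st$Ma[, 6] <- 1                                   # density spike
  st$P[g$active] <- 2^(col(st$P)[g$active]) * 0.1   # steep gradient
  vmax <- 0.1 * (2^7 - 2^6)                         # largest open-face jump
  dt <- stable_timestep(p2, cfg1, g, st)
  expect_lte(dt, 1 / (2 * vmax))
  ## a step at several times the bound drives densities negative (pre-clip),
  ## the bounded step does not
  res_bad <- euler_step(st, p2, g, dt * 8)
  res_ok <- euler_step(st, p2, g, dt)
  expect_lt(res_bad$min_preclip, -1e-12)
  expect_gte(res_ok$min_preclip, -1e-12)
})

test_that("explicit Euler reproduces closed-form exponential decay", {
  g <- strip_geometry()
  k <- 0.4
  p <- zero_params(d_Ma = k)
  st <- zero_state(g)
  st$Ma[g$active] <- 1
  dt <- 0.01; n <- 200
  for (i in seq_len(n)) st <- euler_step(st, p, g, dt)$state
  ## exact discrete solution
  expect_equal(st$Ma[g$active][1], (1 - k * dt)^n, tolerance = 1e-12)
  ## continuous solution within O(dt)
  expect_lt(abs(st$Ma[g$active][1] - exp(-k * dt * n)), 5 * k^2 * dt)
})

test_that("diffusion alone conserves mass to relative 1e-10 over 1000 steps", {
  g <- small_annulus(n = 32)
  p <- zero_params(D_L = 1)
  st <- zero_state(g)
  set.seed(11)
  st$L[g$active] <- stats::runif(sum(g$active), 0.5, 1.5)
  m0 <- sum(st$L)
  dt <- stable_timestep(p, solver_config(), g)
  for (i in 1:1000) st <- euler_step(st, p, g, dt)$state
  expect_lt(abs(sum(st$L) - m0) / m0, 1e-10)
})

test_that("zero dt leaves the state unchanged", {
  g <- strip_geometry()
  st <- zero_state(g)
  st$L[g$active] <- 0.8; st$S[g$active] <- 1
  res <- euler_step(st, default_parameters(), g, 0)
  for (sp in species_names()) expect_equal(res$state[[sp]], st[[sp]])
})

test_that("nondimensionalization divides by reference scales and inverts", {
  sc <- reference_scales()
  v <- c(S = 6e-3, L = 1e-3, Lox = 1e-7)
  nd <- nondimensionalize(v, sc)
  expect_equal(unname(nd[["S"]]), 1)      # media SMC reference
  expect_equal(unname(nd[["L"]]), 1)
  expect_equal(redimensionalize(nd, sc), v)
  ## state round trip
  g <- strip_geometry()
  st <- build_initial_state(g, initial_conditions())
  expect_equal(nondimensionalize(redimensionalize(st, sc), sc), st)
  ## zero reference is a config error
  sc_bad <- sc; sc_bad$conc[["L"]] <- 0
  expect_error(nondimensionalize(v, sc_bad), "config error")
})

test_that("scaled and unscaled decay trajectories agree after inverse scaling", {
  ## dC/dt = -k C in physical units vs the nondimensional system
  k <- 0.3; C0 <- 5e-3; ref <- 5e-3; dt <- 0.02; n <- 100
  phys <- C0
  for (i in seq_len(n)) phys <- phys - dt * k * phys
  nd <- C0 / ref
  for (i in seq_len(n)) nd <- nd - dt * k * nd
  expect_equal(nd * ref, phys, tolerance = 1e-14)
})

test_that("run_simulation contracts: zero horizon, determinism, refinement", {
  g <- small_annulus(n = 40)
  p <- default_parameters()
  init <- initial_conditions("moderate", "mid")
  ## t_end = 0: single snapshot equal to the initial state
  tr0 <- run_simulation(g, p, init, solver_config(t_end = 0))
  expect_equal(length(tr0$time), 1L)
  expect_equal(tr0$final_state$S, build_initial_state(g, init)$S)
  ## identical config twice: bitwise identical summaries
  cfg <- solver_config(t_end = 3)
  tr1 <- run_simulation(g, p, init, cfg, N0 = 1e5)
  tr2 <- run_simulation(g, p, init, cfg, N0 = 1e5)
  expect_identical(tr1$means, tr2$means)
  expect_identical(tr1$nc_area, tr2$nc_area)
  ## halving dt changes final mean ox-LDL by < 1%
  tra <- run_simulation(g, p, init, solver_config(dt = 0.02, t_end = 6))
  trb <- run_simulation(g, p, init, solver_config(dt = 0.01, t_end = 6))
  la <- tra$means[nrow(tra$means), "Lox"]
  lb <- trb$means[nrow(trb$means), "Lox"]
  expect_lt(abs(la - lb) / lb, 0.01)
})

test_that("positivity holds before clipping for self-limited species", {
  ## every sink except the VEGF uptake by ECs (a zeroth-order drain in the
  ## model equations) is proportional to its own species; under the
  ## stability-bounded dt those fields never need clipping
  g <- small_annulus(n = 40)
  p <- default_parameters()
  cfg <- solver_config()
  st <- build_initial_state(g, initial_conditions("severe", "high"))
  watched <- setdiff(species_names(), "Cv")
  worst <- 0
  for (i in 1:200) {
    dt <- stable_timestep(p, cfg, g, st)
    res <- euler_step(st, p, g, dt, cfg)
    worst <- min(worst, res$min_preclip_by_species[watched])
    st <- res$state
  }
  expect_gte(worst, -1e-12)
})

test_that("trajectory CSV export carries times, means and NC series", {
  g <- small_annulus(n = 32)
  tr <- run_simulation(g, default_parameters(), initial_conditions(),
                       solver_config(t_end = 2), N0 = 2e5)
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), length(tr$time))
  expect_equal(df$nc_area_um2, tr$nc_area)
  expect_equal(df$nc_growth, tr$nc_area / tr$N0)
})
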