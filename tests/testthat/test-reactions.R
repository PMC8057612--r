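test_that("endothelial influx follows the shear-modulated formula", {
  p <- default_parameters()
  ## no-shear limit and half-saturation at WSS0
  expect_equal(endothelial_influx_ldl(100, 0, p), p$L_cr * 100)
  expect_equal(endothelial_influx_ldl(100, p$WSS0, p), p$L_cr * 100 / 2)
  ## patient P3-like inputs against independent hand evaluation
  expect_equal(endothelial_influx_ldl(70.4, 85.8, p),
               2e-5 * 70.4 / (1 + 85.8 / 100))
  ## monocytes: linearity in the plasma level, quarter flux at WSS = 300
  expect_equal(endothelial_influx_monocyte(16e5, 50, p) /
                 endothelial_influx_monocyte(4e5, 50, p), 4)
  expect_equal(endothelial_influx_monocyte(4e5, 300, p),
               p$Mo_cr * 4e5 / 4)
  expect_error(endothelial_influx_ldl(-1, 10, p), "domain error")
  expect_error(endothelial_influx_monocyte(1e5, -2, p), "domain error")
})

test_that("reaction rates vanish without substrate or without constants", {
  g <- strip_geometry()
  st <- zero_state(g)
  rates <- reaction_rhs(st, default_parameters(), g)
  for (sp in species_names()) expect_true(all(rates[[sp]] == 0), label = sp)
  ## all rate constants zero -> exactly zero everywhere even with mass present
  st$L[g$active] <- 1; st$Ma[g$active] <- 2; st$S[g$active] <- 1
  rates0 <- reaction_rhs(st, zero_params(), g)
  for (sp in species_names()) expect_true(all(rates0[[sp]] == 0), label = sp)
})

test_that("LDL alone feeds only the oxidation pathway", {
  g <- strip_geometry()
  st <- zero_state(g)
  st$L[g$active] <- 0.7
  p <- default_parameters()
  rates <- reaction_rhs(st, p, g)
  expect_equal(rates$L[g$active], rep(-p$lambda_L * 0.7, sum(g$active)))
  expect_equal(rates$Lox[g$active], rep(p$lambda_LoxL * 0.7, sum(g$active)))
  for (sp in setdiff(species_names(), c("L", "Lox")))
    expect_true(all(rates[[sp]] == 0), label = sp)
})

test_that("single-cell rates match a term-by-term hand evaluation", {
  ## one active cell, every rate constant set to 1
  m <- matrix(lbl[["EXTERIOR"]], 3, 3)
  m[2, 1] <- lbl[["LUMEN"]]; m[2, 2] <- lbl[["INTIMA"]]
  g <- plaque_geometry(m)
  p <- default_parameters()
  for (nm in setdiff(names(p), c("WSS", "C_LDL", "C_Mo"))) p[[nm]] <- 1
  st <- zero_state(g)
  vals <- c(L = 2, Lox = 1, Ma = 3, P = 0.5, Mo = 0.25, S = 0.4, E = 0.6,
            Cv = 0.3, CECM = 0.8, CM = 0.2, F = 0.1, Pl = 0.05)
  for (sp in names(vals)) st[[sp]][2, 2] <- vals[[sp]]
  rates <- reaction_rhs(st, p, g)
  at <- function(sp) rates[[sp]][2, 2]
  expect_equal(at("L"), -2 + 0.05)                       # -L + Pl
  expect_equal(at("Lox"), 2 - 1 * 3)                     # +L - Lox*Ma
  expect_equal(at("P"), 0.6 * 1 / (1 + 1) + 0.4 - 0.5)   # E*Lox/(K+Lox) + S - P
  expect_equal(at("Mo"), 0.05 - 0.25 - 0.25)             # +Pl - diff - decay
  expect_equal(at("Ma"), 0.25 - 3)                       # +Mo - Ma
  expect_equal(at("F"), 1 * 3 - 0.1)                     # +Lox*Ma - F
  expect_equal(at("S"), -0.4 * 1)                        # -S*Lox
  expect_equal(at("CECM"), -0.8 * 0.2 + 0.4)             # -CECM*CM + S
  expect_equal(at("CM"), 0.6 + 0.4 - 0.2)                # +E + S - CM
  expect_equal(at("E"), 0)
  expect_equal(at("Cv"), -0.6 + 0.4 + 3 - 0.3)           # -E + S + Ma - Cv
  expect_equal(at("Pl"), 1 * 1 * 0.6 * (1 - 0.05))       # gamma*q_t*E*(1-Pl/Pl_max)
})

test_that("each reaction constant switches exactly its own pathway", {
  g <- strip_geometry()
  st <- zero_state(g)
  for (sp in species_names()) st[[sp]][g$active] <- 0.5
  p <- default_parameters()
  affected <- list(
    lambda_L = "L", lambda_Plextra = c("L", "Mo"), lambda_LoxL = "Lox",
    lambda_LoxMa = "Lox", lambda_PE = "P", lambda_PS = "P", d_P = "P",
    lambda_MaMo = c("Mo", "Ma"), d_Mo = "Mo", d_Ma = "Ma",
    lambda_CvE = "Cv", lambda_CvS = "Cv", lambda_CvMa = "Cv", d_Cv = "Cv",
    d_S = "S", lambda_CMCECM = "CECM", lambda_SCECM_prod = "CECM",
    lambda_CME = "CM", lambda_CMS = "CM", d_CM = "CM",
    lambda_F = "F", d_F = "F", gamma = "Pl")
  base <- reaction_rhs(st, p, g)
  for (nm in names(affected)) {
    p0 <- p; p0[[nm]] <- 0
    alt <- reaction_rhs(st, p0, g)
    changed <- Filter(function(sp) !isTRUE(all.equal(alt[[sp]], base[[sp]])),
                      species_names())
    expect_setequal(changed, affected[[nm]])
  }
})

test_that("foam-cell production is nonnegative for nonnegative states", {
  g <- strip_geometry()
  p <- default_parameters()
  set.seed(42)
  for (i in 1:20) {
    st <- zero_state(g)
    for (sp in species_names())
      st[[sp]][g$active] <- stats::runif(sum(g$active), 0, 3)
    rates <- reaction_rhs(st, p, g)
    production <- rates$F + p$d_F * st$F
    expect_true(all(production[g$active] >= 0))
  }
})

test_that("taxis specifications cover the motile species with attraction", {
  g <- strip_geometry()
  st <- zero_state(g)
  st$Cv[g$active] <- 0.5
  p <- default_parameters()
  specs <- taxis_velocity_fields(st, p, g)
  expect_setequal(names(specs), c("Ma", "Mo", "E", "S"))
  expect_equal(specs$Ma[[1]]$attractant, "P")
  expect_equal(specs$Mo[[1]]$attractant, "Lox")
  expect_setequal(vapply(specs$S, `[[`, "", "attractant"), c("P", "Ma", "CECM"))
  ## EC sensitivity is saturated in VEGF
  expect_equal(specs$E[[1]]$coeff[g$active][1],
               p$lambda_ECv / (p$K_E + 0.5))
  ## macrophages drift up an MCP-1 gradient
  st$Ma[, 2] <- 1
  st$P[g$active] <- col(st$P)[g$active] * 0.1
  contrib <- taxis_divergence(st$Ma, st$P, p$lambda_MaP, g)
  expect_lt(sum(contrib[, 2]), 0)      # donor column loses
  expect_gt(sum(contrib[, 3]), 0)      # up-gradient neighbour gains
})

test_that("boundary influx adds mass only at the endothelium, linearly", {
  g <- strip_geometry(n_rows = 6, n_cols = 9)
  st <- zero_state(g)
  p <- default_parameters(WSS = 80, C_LDL = 120)
  rates <- apply_boundary_influx(reaction_rhs(st, p, g), st, g, p)
  expect_true(all(rates$L[-g$endothelium] == 0))
  expect_true(all(rates$Mo[-g$endothelium] == 0))
  ## independent bookkeeping: source = k * (C/C_ref) / (1 + WSS/WSS0) per cell
  j_expect <- p$k_influx_L * (120 / p$C_ref_LDL) / (1 + 80 / p$WSS0)
  expect_equal(sum(rates$L), j_expect * length(g$endothelium))
  ## doubling plasma LDL doubles every endothelial source
  p2 <- p; p2$C_LDL <- 240
  rates2 <- apply_boundary_influx(reaction_rhs(st, p2, g), st, g, p2)
  expect_equal(rates2$L[g$endothelium], 2 * rates$L[g$endothelium])
  ## zero plasma concentrations leave rates unchanged
  p0 <- p; p0$C_LDL <- 0; p0$C_Mo <- 0
  rates0 <- apply_boundary_influx(reaction_rhs(st, p0, g), st, g, p0)
  expect_true(all(rates0$L == 0) && all(rates0$Mo == 0))
})
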