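# Shared fixtures: tiny geometries and parameter helpers built in code.

lbl <- label_codes()

# horizontal strip: first column lumen, last column exterior, intima between;
# gives a quasi-1D active region for stencil tests
strip_geometry <- function(n_rows = 5, n_cols = 8, h = 20) {
  labels <- matrix(lbl[["INTIMA"]], n_rows, n_cols)
  labels[, 1] <- lbl[["LUMEN"]]
  labels[, n_cols] <- lbl[["EXTERIOR"]]
  plaque_geometry(labels, h = h)
}

# standard small annulus reused by solver/pipeline tests
small_annulus <- function(n = 48, ecc = 150) {
  generate_synthetic_geometry(
    n = n, lumen_radius = 900,
    intima_thickness_fn = function(a) 400 + ecc * cos(a),
    media_thickness = 300)
}

# parameter set with every rate and diffusion constant zeroed (units blocks
# kept so the influx formulas stay evaluable); build selective dynamics by
# assigning individual constants afterwards
zero_params <- function(...) {
  p <- default_parameters()
  keep <- c("WSS0", "C_ref_LDL", "C_ref_Mo", "K_P", "K_E", "taxis_cmax",
            "Pl_max", "WSS", "C_LDL", "C_Mo")
  for (nm in setdiff(names(p), keep)) p[[nm]] <- 0
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  p
}

# zero state on a geometry
zero_state <- function(g) {
  z <- matrix(0, g$n_rows, g$n_cols)
  structure(stats::setNames(rep(list(z), length(species_names())),
                            species_names()),
            class = "plaque_state")
}

# independent Spearman oracle: Pearson correlation of average ranks
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
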