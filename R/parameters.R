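#' Model species
#'
#' The twelve fields of the plaque-microenvironment model, in fixed order:
#' LDL (`L`), oxidized LDL (`Lox`), MCP-1 (`P`), monocytes (`Mo`),
#' macrophages (`Ma`), foam cells (`F`), smooth muscle cells (`S`),
#' extracellular matrix (`CECM`), matrix metalloproteinase (`CM`),
#' endothelial cells of the intraplaque microvasculature (`E`), VEGF (`Cv`)
#' and extravascular plasma, the intraplaque-haemorrhage proxy (`Pl`).
#'
#' @return Character vector of the twelve species names.
#' @export
species_names <- function() {
  c("L", "Lox", "P", "Mo", "Ma", "F", "S", "CECM", "CM", "E", "Cv", "Pl")
}

## provenance classes allowed for model constants
.provenance_levels <- c("paper", "prior-model-literature", "gap-filled")

.default_param_table <- function() {
  ## name, value, provenance. Values are nondimensional (concentrations
  ## relative to per-species reference scales, lengths in cells, time in
  ## months) except for the endothelial-flux block, which keeps the
  ## published physical units (m/s, dyn/cm^2, mg/dL, cells/cm^3).
  rbind.data.frame(
    ## -- diffusion coefficients (cell^2 / month) --
    list("D_L",    2,     "prior-model-literature"),
    list("D_Lox",  0.08,  "prior-model-literature"),
    list("D_P",    6,     "prior-model-literature"),
    list("D_Mo",   0.5,   "prior-model-literature"),
    list("D_Ma",   0.5,   "prior-model-literature"),
    list("D_F",    0,     "gap-filled"),
    list("D_S",    0.2,   "prior-model-literature"),
    list("D_CECM", 0,     "prior-model-literature"),
    list("D_CM",   6,     "prior-model-literature"),
    list("D_E",    0.2,   "prior-model-literature"),
    list("D_Cv",   6,     "prior-model-literature"),
    list("D_Pl",   6,     "gap-filled"),
    ## -- LDL / ox-LDL (per month) --
    list("lambda_L",       3,    "prior-model-literature"), # LDL clearance from the wall
    list("lambda_Plextra", 0.3,  "gap-filled"),             # leaky-microvessel source (L and Mo)
    list("lambda_LoxL",    0.05, "prior-model-literature"), # ox-LDL formed from LDL
    list("lambda_LoxMa",   0.05, "prior-model-literature"), # macrophage phagocytosis
    ## -- MCP-1 --
    list("lambda_PE", 0.5,  "prior-model-literature"),      # EC production, saturated in Lox
    list("K_P",       1,    "gap-filled"),
    list("lambda_PS", 0.3,  "prior-model-literature"),      # SMC production
    list("d_P",       1.0,  "prior-model-literature"),      # decay
    ## -- monocytes / macrophages --
    list("lambda_MaMo", 0.8, "prior-model-literature"),     # differentiation Mo -> Ma
    list("d_Mo",        0.5, "prior-model-literature"),
    list("d_Ma",        0.3, "prior-model-literature"),
    list("lambda_MaP",  1.0, "prior-model-literature"),     # Ma chemotaxis to MCP-1
    list("lambda_MoLox", 0.5, "prior-model-literature"),    # Mo chemotaxis to ox-LDL
    ## -- endothelial cells (microvasculature) --
    list("lambda_ECv",   1.0, "prior-model-literature"),    # EC chemotaxis to VEGF
    list("K_E",          1,   "gap-filled"),
    list("lambda_ECECM", 0.3, "prior-model-literature"),    # EC haptotaxis on ECM
    ## -- VEGF --
    list("lambda_CvE",  0.4,  "prior-model-literature"),    # uptake by ECs
    list("lambda_CvS",  0.05, "prior-model-literature"),    # early production by SMCs
    list("lambda_CvMa", 0.2,  "prior-model-literature"),    # late production by macrophages
    list("d_Cv",        0.6,  "prior-model-literature"),
    ## -- SMCs --
    list("lambda_SP",          0.5, "prior-model-literature"), # chemotaxis to MCP-1
    list("lambda_SMa",         1.5, "prior-model-literature"), # chemotaxis to macrophage PDGF
    list("lambda_SCECM_taxis", 0.3, "prior-model-literature"), # haptotaxis on ECM
    list("d_S",                0.6,  "prior-model-literature"),# ox-LDL-induced apoptosis
    ## -- ECM / MMP --
    list("lambda_CMCECM",    0.3,  "prior-model-literature"), # ECM degraded by MMP
    list("lambda_SCECM_prod", 0.05, "prior-model-literature"),# ECM produced by SMCs
    list("lambda_CME", 0.05, "prior-model-literature"),       # MMP from ECs
    list("lambda_CMS", 0.05, "prior-model-literature"),       # MMP from SMCs
    list("d_CM",       0.8,  "prior-model-literature"),
    ## -- taxis volume-filling capacity (suppresses chemotactic collapse) --
    list("taxis_cmax", 6, "gap-filled"),
    ## -- foam cells (no printed row; production follows phagocytosis) --
    list("lambda_F", 0.4,  "gap-filled"),
    list("d_F",      0.05, "gap-filled"),
    ## -- extravascular plasma (IPH proxy) --
    list("psi",   0, "gap-filled"),   # plasma convection, disabled by default
    list("U_i",   0, "gap-filled"),   # interstitial velocity scale
    list("gamma", 0.4,  "gap-filled"),# fluid-flux gain
    list("q_t",   1.0, "gap-filled"), # Q_t = q_t * E (continuum microvessel proxy)
    list("Pl_max", 1.0, "gap-filled"),# tissue plasma capacity (extravasation saturates)
    ## -- endothelial influx (physical units) --
    list("L_cr",  2e-5, "paper"),     # LDL conductive rate, m/s
    list("Mo_cr", 4e-5, "paper"),     # monocyte conductive rate, m/s
    list("WSS0",  100,  "paper"),     # shear reference, dyn/cm^2
    list("C_ref_LDL", 100,  "gap-filled"), # plasma LDL nondimensionalization, mg/dL
    list("C_ref_Mo",  4e5,  "paper"),      # mild plasma monocyte level, cells/cm^3
    list("k_influx_L",  12,  "gap-filled"),# nondim endothelial source gain, per month
    list("k_influx_Mo", 0.4, "gap-filled"),
    ## -- patient inputs (overridden per patient) --
    list("WSS",   100, "paper"),      # dyn/cm^2, held at its baseline value
    list("C_LDL", 100, "paper"),      # plasma LDL, mg/dL
    list("C_Mo",  4e5, "paper")       # plasma monocytes, cells/cm^3
  ) -> df
  names(df) <- c("name", "value", "provenance")
  df
}

#' Default model parameter set
#'
#' Every rate, diffusion and boundary constant of the twelve-field model,
#' with a provenance tag per constant (`paper` for values printed in the
#' source study, `prior-model-literature` for values of the kind used in
#' earlier continuum plaque/angiogenesis models, `gap-filled` for constants
#' the model needs but no publication prints). All constants are
#' overridable.
#'
#' Except for the endothelial-influx block (`L_cr`, `Mo_cr`, `WSS0` and the
#' patient inputs, which keep their published physical units), constants are
#' nondimensional: concentrations are relative to the per-species reference
#' scales of [reference_scales()], lengths are in grid cells and time is in
#' months.
#'
#' @param ... Named overrides, e.g. `default_parameters(d_S = 0.2)`.
#' @return A named list of class `plaque_params` with a `provenance`
#'   attribute.
#' @export
#' @examples
#' p <- default_parameters(WSS = 85.8, C_LDL = 70.4)
#' p$WSS
default_parameters <- function(...) {
  tab <- .default_param_table()
  p <- as.list(stats::setNames(tab$value, tab$name))
  prov <- stats::setNames(tab$provenance, tab$name)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    p[names(over)] <- over
    prov[names(over)] <- "gap-filled"
  }
  .validate_params(structure(p, provenance = prov, class = "plaque_params"))
}

.validate_params <- function(p) {
  vals <- unlist(p)
  if (!all(is.finite(vals))) stop("non-finite parameter value", call. = FALSE)
  dnames <- grep("^D_", names(p), value = TRUE)
  if (any(unlist(p[dnames]) < 0))
    stop("diffusion coefficients must be >= 0", call. = FALSE)
  decay <- c("lambda_L", "d_P", "d_Mo", "d_Ma", "d_Cv", "d_S", "d_CM", "d_F")
  if (any(unlist(p[decay]) < 0))
    stop("decay constants must be >= 0", call. = FALSE)
  prov <- attr(p, "provenance")
  if (!all(prov %in% .provenance_levels))
    stop("invalid provenance tag", call. = FALSE)
  p
}

#' @export
print.plaque_params <- function(x, ...) {
  cat(sprintf("<plaque_params> %d constants (paper %d, prior-model %d, gap-filled %d)\n",
              length(x),
              sum(attr(x, "provenance") == "paper"),
              sum(attr(x, "provenance") == "prior-model-literature"),
              sum(attr(x, "provenance") == "gap-filled")))
  invisible(x)
}

#' Write / read a parameter set as a YAML config
#'
#' Round-trips a [default_parameters()] object through a structured YAML
#' file with one `{value, provenance}` entry per constant.
#'
#' @param p A `plaque_params` object.
#' @param path Output (input) file path.
#' @return `write_parameters` returns `path` invisibly; `read_parameters`
#'   returns a `plaque_params`.
#' @export
write_parameters <- function(p, path) {
  stopifnot(inherits(p, "plaque_params"))
  prov <- attr(p, "provenance")
  out <- lapply(names(p), function(nm)
    list(value = unname(p[[nm]]), provenance = unname(prov[[nm]])))
  names(out) <- names(p)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  raw <- yaml::read_yaml(path)
  vals <- lapply(raw, function(e) e$value)
  prov <- vapply(raw, function(e) e$provenance, character(1))
  .validate_params(structure(vals, provenance = prov, class = "plaque_params"))
}
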