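#' Region label codes for cross-section masks
#'
#' The simulation arena is a labeled grid standing in for a segmented
#' VH-IVUS cross-section. Cells are coded `0 = exterior` (outside the
#' external elastic membrane, EEM), `1 = lumen`, `2 = thickening intima`
#' and `3 = media`. Grids are row-major with the origin at the top-left.
#'
#' @return Named integer vector of the four label codes.
#' @export
#' @examples
#' label_codes()
label_codes <- function() {
  c(EXTERIOR = 0L, LUMEN = 1L, INTIMA = 2L, MEDIA = 3L)
}

## ---- neighbour shift helpers (shared by geometry and solver) ----
## .nbr_n(M)[r, c] == M[r - 1, c]; out-of-grid neighbours filled with `fill`.

.nbr_n <- function(M, fill = 0) rbind(matrix(fill, 1L, ncol(M)), M[-nrow(M), , drop = FALSE])
.nbr_s <- function(M, fill = 0) rbind(M[-1L, , drop = FALSE], matrix(fill, 1L, ncol(M)))
.nbr_w <- function(M, fill = 0) cbind(matrix(fill, nrow(M), 1L), M[, -ncol(M), drop = FALSE])
.nbr_e <- function(M, fill = 0) cbind(M[, -1L, drop = FALSE], matrix(fill, nrow(M), 1L))

## 4-connected flood fill inside a logical mask, vectorised over the grid
.flood_fill <- function(mask, seed_index) {
  reached <- mask & FALSE
  reached[seed_index] <- TRUE
  repeat {
    grown <- mask & (reached |
      .nbr_n(reached, FALSE) | .nbr_s(reached, FALSE) |
      .nbr_w(reached, FALSE) | .nbr_e(reached, FALSE))
    if (identical(grown, reached)) break
    reached <- grown
  }
  reached
}

## chamfer (4-neighbour) distance, in cells, from `sources` within `mask`
.grid_distance <- function(mask, sources) {
  src <- matrix(FALSE, nrow(mask), ncol(mask))
  src[sources] <- TRUE
  d <- matrix(Inf, nrow(mask), ncol(mask))
  d[src] <- 0
  repeat {
    dn <- pmin(
      d,
      .nbr_n(d, Inf) + 1, .nbr_s(d, Inf) + 1,
      .nbr_w(d, Inf) + 1, .nbr_e(d, Inf) + 1
    )
    dn[!mask & !src] <- Inf
    if (identical(dn, d)) break
    d <- dn
  }
  d
}

#' Construct a cross-section domain from a label matrix
#'
#' Validates a labeled grid and derives everything the solver and the
#' morphology metrics need: the active (intima + media) mask, the
#' endothelium (intima cells 4-adjacent to lumen), the EEM rim (media cells
#' 4-adjacent to exterior; off-grid counts as exterior), the lumen centroid,
#' and neighbour/face-openness masks for the finite-difference stencils.
#'
#' @param labels Integer matrix with values in `label_codes()`.
#' @param h Cell edge length in micrometres (default 20, the 4 mm / 200 cell
#'   discretization).
#' @return An object of class `plaque_geometry`.
#' @export
plaque_geometry <- function(labels, h = 20) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (!all(labels %in% label_codes()))
    stop("format error: unknown label code(s): ",
         paste(setdiff(unique(as.vector(labels)), label_codes()), collapse = ", "),
         call. = FALSE)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("`h` must be a single positive length (micrometres)", call. = FALSE)

  lbl <- label_codes()
  lumen  <- labels == lbl[["LUMEN"]]
  intima <- labels == lbl[["INTIMA"]]
  media  <- labels == lbl[["MEDIA"]]
  exterior <- labels == lbl[["EXTERIOR"]]

  if (!any(lumen))
    stop("geometry error: mask contains no lumen", call. = FALSE)
  reached <- .flood_fill(lumen, which(lumen)[1L])
  if (!all(reached[lumen]))
    stop("geometry error: lumen is not a single 4-connected region", call. = FALSE)

  active <- intima | media

  ## endothelium: intima cells with a lumen 4-neighbour
  has_lumen_nb <- .nbr_n(lumen, FALSE) | .nbr_s(lumen, FALSE) |
    .nbr_w(lumen, FALSE) | .nbr_e(lumen, FALSE)
  endothelium <- which(intima & has_lumen_nb)

  ## EEM rim: media cells with an exterior 4-neighbour (off-grid = exterior)
  has_ext_nb <- .nbr_n(exterior, TRUE) | .nbr_s(exterior, TRUE) |
    .nbr_w(exterior, TRUE) | .nbr_e(exterior, TRUE)
  eem <- which(media & has_ext_nb)

  lum_idx <- which(lumen, arr.ind = TRUE)
  lumen_centroid <- c(row = mean(lum_idx[, 1L]), col = mean(lum_idx[, 2L]))

  act_num <- active * 1
  g <- structure(list(
    labels = labels,
    h = h,
    n_rows = nrow(labels),
    n_cols = ncol(labels),
    active = active,
    lumen = lumen,
    intima = intima,
    media = media,
    endothelium = endothelium,
    eem = eem,
    lumen_centroid = lumen_centroid,
    ## neighbour-active masks (0/1) for mirror-closure stencils
    a_n = .nbr_n(act_num), a_s = .nbr_s(act_num),
    a_w = .nbr_w(act_num), a_e = .nbr_e(act_num),
    ## face openness: both cells active (for conservative taxis fluxes)
    f_e = act_num * .nbr_e(act_num),
    f_s = act_num * .nbr_s(act_num)
  ), class = "plaque_geometry")
  g
}

#' @export
print.plaque_geometry <- function(x, ...) {
  cat(sprintf(
    "<plaque_geometry> %d x %d cells, h = %g um\n", x$n_rows, x$n_cols, x$h))
  cat(sprintf("  lumen %d, intima %d, media %d cells; endothelium %d, EEM rim %d\n",
              sum(x$lumen), sum(x$intima), sum(x$media),
              length(x$endothelium), length(x$eem)))
  invisible(x)
}

#' Load a labeled cross-section mask
#'
#' Reads an 8-bit single-channel PNG or TIFF image, or a whitespace-delimited
#' integer text grid, holding the region codes of [label_codes()], and builds
#' a validated [plaque_geometry()]. Image pixel intensities are interpreted
#' as raw 8-bit label codes (0--3).
#'
#' @param path Path to the mask file; format chosen by extension
#'   (`.png`, `.tif`/`.tiff`, anything else is read as a text grid).
#' @param pixel_size_um Physical edge length of one pixel in micrometres.
#' @return A `plaque_geometry`.
#' @export
load_label_mask <- function(path, pixel_size_um = 20) {
  if (!file.exists(path))
    stop("mask file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    labels <- round(img * 255)
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    labels <- round(img * 255)
  } else {
    labels <- as.matrix(utils::read.table(path, header = FALSE))
    dimnames(labels) <- NULL
  }
  plaque_geometry(labels, h = pixel_size_um)
}

#' Save a labeled cross-section mask
#'
#' Inverse of [load_label_mask()]: writes the label matrix as an 8-bit
#' grayscale PNG/TIFF (raw codes 0--3) or a whitespace-delimited text grid.
#'
#' @param g A `plaque_geometry` (or a bare label matrix).
#' @param path Output path; format chosen by extension as in
#'   [load_label_mask()].
#' @return `path`, invisibly.
#' @export
save_label_mask <- function(g, path) {
  labels <- if (inherits(g, "plaque_geometry")) g$labels else g
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(labels / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(labels / 255, path, bits.per.sample = 8L)
  } else {
    utils::write.table(labels, path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Generate a synthetic vessel cross-section
#'
#' Builds an annular single-vessel geometry emulating a segmented VH-IVUS
#' slice: a circular lumen surrounded by a (possibly eccentric) thickening
#' intima and a media ring, embedded in an exterior background. Eccentric
#' plaques are produced by an angle-dependent intima thickness; an optional
#' seeded harmonic roughness perturbs the intima contour deterministically.
#'
#' @param n Grid size (the domain is `n x n` cells).
#' @param h Cell edge length in micrometres. The default `4000 / n` keeps the
#'   physical domain at 4 mm regardless of resolution (200 cells give
#'   h = 20 um).
#' @param lumen_radius Lumen radius in micrometres.
#' @param intima_thickness_fn Function mapping angle (radians) to intima
#'   thickness in micrometres; a constant function gives a concentric plaque.
#' @param media_thickness Media ring thickness in micrometres.
#' @param roughness Amplitude (um) of a smooth random perturbation of the
#'   intima contour; 0 disables it.
#' @param seed Integer seed making the roughness reproducible.
#' @return A `plaque_geometry`.
#' @export
#' @examples
#' g <- generate_synthetic_geometry(n = 80, lumen_radius = 800,
#'   intima_thickness_fn = function(a) 400 + 200 * cos(a))
#' plaque_burden(g)
generate_synthetic_geometry <- function(n = 200, h = 4000 / n,
                                        lumen_radius = 1000,
                                        intima_thickness_fn = function(angle) 400,
                                        media_thickness = 300,
                                        roughness = 0, seed = NULL) {
  stopifnot(n >= 8, h > 0, lumen_radius > 0, media_thickness >= 0)
  ctr <- (n + 1) / 2
  row <- matrix(seq_len(n), n, n)
  col <- matrix(seq_len(n), n, n, byrow = TRUE)
  x <- (col - ctr) * h
  y <- (row - ctr) * h
  r <- sqrt(x^2 + y^2)
  theta <- atan2(y, x)

  ti <- matrix(vapply(theta, intima_thickness_fn, numeric(1)), n, n)
  if (any(ti < 0)) stop("parameter error: negative intima thickness", call. = FALSE)
  if (roughness > 0) {
    coefs <- .with_seed(seed, stats::runif(6, -1, 1))
    bump <- coefs[1] * cos(theta) + coefs[2] * sin(theta) +
      coefs[3] * cos(2 * theta) + coefs[4] * sin(2 * theta) +
      coefs[5] * cos(3 * theta) + coefs[6] * sin(3 * theta)
    ti <- pmax(ti + roughness * bump, 0)
  }

  outer_r <- lumen_radius + ti + media_thickness
  if (max(outer_r) > (n / 2 - 1.5) * h)
    stop("parameter error: geometry exceeds grid (outer radius ",
         round(max(outer_r)), " um)", call. = FALSE)

  lbl <- label_codes()
  labels <- matrix(lbl[["EXTERIOR"]], n, n)
  labels[r <= outer_r] <- lbl[["MEDIA"]]
  labels[r <= lumen_radius + ti] <- lbl[["INTIMA"]]
  labels[r <= lumen_radius] <- lbl[["LUMEN"]]
  plaque_geometry(labels, h = h)
}

#' Plaque burden of a cross-section
#'
#' Plaque burden is the plaque area divided by the plaque-plus-lumen area,
#' with areas measured as cell counts times the cell area `h^2`. The plaque
#' area is by default the whole wall between lumen and outer boundary
#' (intima + media); set `include_media = FALSE` for the intima-only variant.
#'
#' @param g A `plaque_geometry`.
#' @param include_media Include the media ring in the plaque area (default).
#' @return Plaque burden, a dimensionless fraction in `[0, 1)`.
#' @export
plaque_burden <- function(g, include_media = TRUE) {
  stopifnot(inherits(g, "plaque_geometry"))
  plaque_cells <- sum(g$intima) + if (include_media) sum(g$media) else 0L
  lumen_cells <- sum(g$lumen)
  if (plaque_cells + lumen_cells == 0L) return(0)
  plaque_cells / (plaque_cells + lumen_cells)
}

## wall thickness along equiangular rays from the lumen centroid:
## from the first non-lumen sample to the last non-exterior sample
.wall_thickness_rays <- function(g, n_rays = 360, step = 0.25) {
  ctr <- g$lumen_centroid
  angles <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  max_steps <- ceiling(sqrt(g$n_rows^2 + g$n_cols^2) / step) + 2L
  lbl <- label_codes()
  wt <- numeric(n_rays)
  for (k in seq_len(n_rays)) {
    dr <- sin(angles[k]) * step
    dc <- cos(angles[k]) * step
    r_in <- NA_real_
    r_out <- NA_real_
    for (s in seq_len(max_steps)) {
      rr <- round(ctr[["row"]] + s * dr)
      cc <- round(ctr[["col"]] + s * dc)
      if (rr < 1 || rr > g$n_rows || cc < 1 || cc > g$n_cols) break
      lab <- g$labels[rr, cc]
      ## midpoint of the bracketing samples: subpixel crossing estimate
      if (is.na(r_in) && lab != lbl[["LUMEN"]]) r_in <- (s - 0.5) * step
      if (lab == lbl[["EXTERIOR"]]) { r_out <- (s - 0.5) * step; break }
    }
    if (is.na(r_in) || is.na(r_out))
      stop("geometry error: ray ", k, " never exits the wall", call. = FALSE)
    wt[k] <- (r_out - r_in) * g$h
  }
  ## circular moving average over ~20 degrees: wall thickness is a
  ## tissue-scale quantity, and raw per-ray values carry +-1 cell of
  ## pixelation jitter that min/max would otherwise amplify
  w <- max(1L, round(n_rays / 18))
  if (w %% 2L == 0L) w <- w + 1L
  if (w > 1L) {
    half <- (w - 1L) %/% 2L
    padded <- c(wt[(n_rays - half + 1L):n_rays], wt, wt[1:half])
    wt <- stats::filter(padded, rep(1 / w, w), sides = 2)[(half + 1L):(half + n_rays)]
    wt <- as.numeric(wt)
  }
  wt
}

#' Eccentricity index of a cross-section
#'
#' Wall thickness is measured along `n_rays` equiangular rays cast from the
#' lumen centroid, from the first non-lumen cell to the last non-exterior
#' cell. The eccentricity index is `EI = 1 - WT_min / WT_max`; a concentric
#' annulus has EI = 0.
#'
#' @param g A `plaque_geometry`.
#' @param n_rays Number of rays (default 360).
#' @return EI, a dimensionless value in `[0, 1]`.
#' @export
eccentricity_index <- function(g, n_rays = 360) {
  wt <- .wall_thickness_rays(g, n_rays)
  ex <- .wt_extremes(wt)
  1 - ex[["min"]] / ex[["max"]]
}

## robust thickness extremes: 1st/99th percentiles of the smoothed profile,
## so a handful of pixelation outliers cannot masquerade as eccentricity
.wt_extremes <- function(wt) {
  q <- stats::quantile(wt, c(0.01, 0.99), names = FALSE, type = 7)
  c(min = q[1], max = q[2])
}

#' Morphology metrics of a cross-section
#'
#' Computes the plaque area, lumen area, plaque burden, minimum and maximum
#' wall thickness, and eccentricity index of a labeled cross-section.
#'
#' @inheritParams eccentricity_index
#' @inheritParams plaque_burden
#' @return A list of class `morphology_metrics` with elements `plaque_area`
#'   and `lumen_area` (um^2), `PB`, `wt_min`, `wt_max` (um) and `EI`.
#' @export
morphology_metrics <- function(g, n_rays = 360, include_media = TRUE) {
  wt <- .wall_thickness_rays(g, n_rays)
  ex <- .wt_extremes(wt)
  plaque_cells <- sum(g$intima) + if (include_media) sum(g$media) else 0L
  structure(list(
    plaque_area = plaque_cells * g$h^2,
    lumen_area = sum(g$lumen) * g$h^2,
    PB = plaque_burden(g, include_media = include_media),
    wt_min = ex[["min"]],
    wt_max = ex[["max"]],
    EI = 1 - ex[["min"]] / ex[["max"]]
  ), class = "morphology_metrics")
}

#' @export
print.morphology_metrics <- function(x, ...) {
  cat(sprintf(
    "<morphology_metrics> PB = %.3f, EI = %.3f, wall %.0f-%.0f um, plaque %.3g mm^2\n",
    x$PB, x$EI, x$wt_min, x$wt_max, x$plaque_area / 1e6))
  invisible(x)
}

## evaluate `code` under a temporary RNG seed, restoring global state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
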