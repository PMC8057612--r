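#' Necrotic-core area from apoptotic SMCs
#'
#' The necrotic core (NC) is operationalized as the intima area where the
#' SMC density decreased by more than 50% compared with its initial value:
#' `h^2` times the number of intima cells with `S < 0.5 * S_initial`
#' (strict inequality; a cell at exactly half its initial value is not
#' counted). Contiguity is not required.
#'
#' @param state A `plaque_state`, or a bare SMC matrix.
#' @param initial_smc Matrix of initial SMC densities.
#' @param g A [plaque_geometry()].
#' @return NC area in um^2.
#' @export
nc_area <- function(state, initial_smc, g) {
  S <- if (is.list(state)) state$S else state
  core <- g$intima & (initial_smc > 0) & (S < 0.5 * initial_smc)
  sum(core) * g$h^2
}

#' Necrotic-core growth rate
#'
#' `growth(t) = N(t) / N0`, the NC area at time `t` relative to the
#' baseline core area. Times between snapshots are linearly interpolated.
#'
#' @param traj A `plaque_trajectory` with `N0 > 0`.
#' @param t Time in months (default: end of the trajectory).
#' @return The growth ratio, dimensionless.
#' @export
nc_growth_rate <- function(traj, t = max(traj$time)) {
  if (is.null(traj$N0) || !is.finite(traj$N0) || traj$N0 <= 0)
    stop("undefined-growth error: baseline NC area N0 must be > 0", call. = FALSE)
  n_t <- stats::approx(traj$time, traj$nc_area, xout = t, rule = 2)$y
  n_t / traj$N0
}

#' Grade patients on one factor by min-max thirds
#'
#' The comparative three-grade scale: the min-max range of the cohort's
#' values is split into equal thirds; the worst third (per `direction`)
#' receives grade 3 (severe), the best grade 1 (mild), the middle grade 2
#' (moderate). Values falling exactly on a cut go to the milder grade. If
#' all values are equal every patient receives grade 2.
#'
#' @param values Numeric vector, one value per patient (>= 2 patients).
#' @param direction `"higher_worse"` (e.g. LDL, plaque burden) or
#'   `"lower_worse"` (e.g. HDL, WSS).
#' @return Integer vector of grades in `{1, 2, 3}`.
#' @export
#' @examples
#' score_factor(c(138.4, 157.8, 70.4, 144.4), "higher_worse")
#' score_factor(c(140.07, 129.9, 85.8, 77.11), "lower_worse")
score_factor <- function(values, direction = c("higher_worse", "lower_worse")) {
  direction <- match.arg(direction)
  if (length(values) < 2L) stop("grading needs at least 2 patients", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite factor value", call. = FALSE)
  lo <- min(values); hi <- max(values)
  if (lo == hi) return(rep(2L, length(values)))
  c1 <- lo + (hi - lo) / 3
  c2 <- lo + 2 * (hi - lo) / 3
  if (direction == "higher_worse") {
    ifelse(values <= c1, 1L, ifelse(values <= c2, 2L, 3L))
  } else {
    ifelse(values >= c2, 1L, ifelse(values >= c1, 2L, 3L))
  }
}

#' Total severity score
#'
#' Sum of the eight per-factor grades (plaque burden, eccentricity index,
#' LDL, HDL, WSS, macrophage, SMC, ox-LDL); ranges from 8 to 24.
#'
#' @param grades Vector of eight grades, each in `{1, 2, 3}`.
#' @return Integer total.
#' @export
#' @examples
#' total_score(c(3, 2, 3, 1, 1, 1, 2, 2)) # 15
total_score <- function(grades) {
  grades <- unlist(grades)
  if (length(grades) != 8L || anyNA(grades))
    stop("input error: eight grades required", call. = FALSE)
  if (!all(grades %in% 1:3))
    stop("input error: grades must be in {1, 2, 3}", call. = FALSE)
  as.integer(sum(grades))
}

#' Classify plaque fate from the total score
#'
#' Totals of 18 or more are labelled `"vulnerable"`, lower totals
#' `"stable"`. Stable plaques can be annotated with composition flags
#' (e.g. macrocalcification) observed on imaging.
#'
#' @param total Total score from [total_score()].
#' @param composition Optional character flags appended to a stable label.
#' @return Character fate label.
#' @export
classify_plaque <- function(total, composition = NULL) {
  stopifnot(is.numeric(total), length(total) == 1L, total >= 8, total <= 24)
  if (total >= 18) return("vulnerable")
  if (length(composition))
    paste0("stable (", paste(composition, collapse = ", "), ")")
  else "stable"
}

#' Score a cohort and classify plaque fates
#'
#' Applies the comparative min-max-thirds grading to the eight factors of
#' the severity scale. Morphology (PB, EI) and blood/hemodynamic factors
#' (LDL, HDL, WSS) are baseline values; macrophage, SMC and ox-LDL severity
#' are the simulated levels at the end of prediction (T3). Higher PB, EI,
#' LDL, macrophage and ox-LDL are worse; higher HDL, WSS and SMC (less
#' apoptosis) are better.
#'
#' @param factors Data frame with one row per patient and columns `PB`,
#'   `EI`, `LDL`, `HDL`, `WSS`, `MPhi`, `SMC`, `oxLDL`; an optional `id`
#'   column is carried through.
#' @return Data frame of class `score_table`: grades per factor, `total`
#'   and `fate`.
#' @export
score_cohort <- function(factors) {
  need <- c("PB", "EI", "LDL", "HDL", "WSS", "MPhi", "SMC", "oxLDL")
  if (!all(need %in% names(factors)))
    stop("input error: missing factor column(s): ",
         paste(setdiff(need, names(factors)), collapse = ", "), call. = FALSE)
  dirs <- c(PB = "higher_worse", EI = "higher_worse", LDL = "higher_worse",
            HDL = "lower_worse", WSS = "lower_worse", MPhi = "higher_worse",
            SMC = "lower_worse", oxLDL = "higher_worse")
  grades <- as.data.frame(lapply(need, function(f)
    score_factor(factors[[f]], dirs[[f]])))
  names(grades) <- need
  total <- apply(grades, 1L, function(gr) total_score(gr))
  fate <- vapply(total, classify_plaque, character(1))
  out <- cbind(
    if ("id" %in% names(factors)) factors["id"] else NULL,
    grades, total = total, fate = fate)
  class(out) <- c("score_table", class(out))
  out
}

#' Stable-vs-unstable group comparison per factor
#'
#' Welch two-sample t-tests of the pooled trajectory samples of each
#' microenvironmental factor between two patient groups. Observations are
#' the per-patient spatial-mean values at the trajectory snapshot times,
#' pooled within each group. Significance is reported at the 0.01 level.
#'
#' @param group_a,group_b Named lists of numeric vectors (one element per
#'   factor; each vector pools the group's sampled values).
#' @param alpha Significance threshold (default 0.01).
#' @return Data frame with columns `factor`, `statistic`, `p_value`,
#'   `significant`, `degenerate`.
#' @export
group_ttest <- function(group_a, group_b, alpha = 0.01) {
  factors <- intersect(names(group_a), names(group_b))
  if (!length(factors)) stop("no shared factors between groups", call. = FALSE)
  rows <- lapply(factors, function(f) {
    a <- group_a[[f]]; b <- group_b[[f]]
    if (length(a) < 2L || length(b) < 2L)
      stop("each group needs >= 2 observations per factor", call. = FALSE)
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      return(data.frame(factor = f, statistic = NA_real_, p_value = NA_real_,
                        significant = NA, degenerate = TRUE))
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    data.frame(factor = f, statistic = unname(tt$statistic),
               p_value = tt$p.value, significant = tt$p.value < alpha,
               degenerate = FALSE)
  })
  do.call(rbind, rows)
}

#' Spearman correlation of a factor with NC expansion
#'
#' Rank correlation (average ranks for ties) between a microenvironmental
#' factor's trajectory and the NC area across time points.
#'
#' @param factor_series Numeric vector of factor values over time.
#' @param nc_series Numeric vector of NC areas at the same time points.
#' @return List with `r`, `p_value` and `flag` (`"ok"` or
#'   `"undefined-r"` when a series is constant).
#' @export
spearman_nc_correlation <- function(factor_series, nc_series) {
  if (length(factor_series) != length(nc_series))
    stop("series must be paired", call. = FALSE)
  if (length(nc_series) < 3L)
    stop("need at least 3 paired time points", call. = FALSE)
  if (stats::sd(factor_series) == 0 || stats::sd(nc_series) == 0)
    return(list(r = NA_real_, p_value = NA_real_, flag = "undefined-r"))
  ct <- suppressWarnings(
    stats::cor.test(factor_series, nc_series, method = "spearman",
                    exact = FALSE))
  list(r = unname(ct$estimate), p_value = ct$p.value, flag = "ok")
}
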