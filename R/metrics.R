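#' Mass-weighted mean damage of a density
#'
#' \eqn{\langle x\rangle = \sum_i x_i u_i \Delta x / \sum_i u_i \Delta x},
#' the principal summary of compartmental aging.
#'
#' @param u Density vector with positive total mass.
#' @param grid A [make_grid()] grid.
#' @return The mean damage.
#' @export
mean_damage <- function(u, grid) {
  check_density(u, grid)
  m <- sum(u)
  if (m <= 0) stop("mean damage undefined for zero total mass", call. = FALSE)
  sum(grid$x * u) / m
}

#' Distribution maximum and rightmost support
#'
#' The mode \eqn{x^m} is the node of maximal density (smallest x on
#' ties); the rightmost support \eqn{x^r} is the largest node whose
#' density exceeds `rel_floor` times the maximum. Strict positivity is
#' meaningless in floating point, so the support uses a relative
#' numerical floor (default `1e-8`).
#'
#' @param u Density vector with `max(u) > 0`.
#' @param grid A [make_grid()] grid.
#' @param rel_floor Relative threshold defining "positive" density.
#' @return A list with `mode` and `support` (damage units).
#' @export
mode_and_support <- function(u, grid, rel_floor = 1e-8) {
  check_density(u, grid)
  mx <- max(u)
  if (mx <= 0) stop("mode undefined for an all-zero density", call. = FALSE)
  list(mode = grid$x[which.max(u)],
       support = grid$x[max(which(u > rel_floor * mx))])
}

#' Overshoot fraction of the TD-to-stem ratio
#'
#' \eqn{R = \max\{0, \max_t(\bar W/\bar P) - r^*\} / r^*}: the maximal
#' relative excess of the transient ratio above the anchor steady
#' ratio `steady_ratio` (default 7, the calibration target); zero if
#' the ratio never exceeds it.
#'
#' @param ratio_series Time series of \eqn{\bar W/\bar P} (NAs from
#'   empty states are ignored).
#' @param steady_ratio Anchor steady-state ratio (> 0).
#' @return The overshoot fraction `R >= 0`.
#' @export
overshoot_fraction <- function(ratio_series, steady_ratio = 7) {
  if (steady_ratio <= 0) stop("'steady_ratio' must be > 0", call. = FALSE)
  r <- ratio_series[is.finite(ratio_series)]
  if (length(r) == 0L) stop("'ratio_series' must be nonempty", call. = FALSE)
  max(0, max(r) - steady_ratio) / steady_ratio
}

#' Least-squares line through a mean-damage (or totals) time series
#'
#' Ordinary least squares of `values ~ times` over an optional window,
#' used to quantify the linear growth of compartment averages in the
#' no-partition regime.
#'
#' @param times,values Numeric vectors of equal length.
#' @param window Optional `c(t0, t1)` restricting the fit.
#' @return A list with `slope`, `intercept`, `r_squared`.
#' @export
linear_fit_mean <- function(times, values, window = NULL) {
  stopifnot(length(times) == length(values))
  keep <- is.finite(times) & is.finite(values)
  if (!is.null(window))
    keep <- keep & times >= window[1] - 1e-12 & times <= window[2] + 1e-12
  t <- times[keep]; y <- values[keep]
  if (length(t) < 3L) stop("need at least 3 points in the window",
                           call. = FALSE)
  if (max(t) - min(t) <= 0)
    stop("degenerate fit: times are constant in the window", call. = FALSE)
  fit <- stats::lm(y ~ t)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1)
}

#' Damage-distribution summary for a stem/TD state
#'
#' Collects the per-compartment mean, mode and rightmost support, plus
#' the overshoot fraction when a ratio series is supplied.
#'
#' @param P,W Density vectors.
#' @param grid A [make_grid()] grid.
#' @param ratio_series Optional \eqn{\bar W/\bar P} time series for the
#'   overshoot fraction.
#' @param steady_ratio Anchor ratio for the overshoot (default 7).
#' @param rel_floor Support floor, see [mode_and_support()].
#' @return A one-row `data.frame` with columns `mean_P`, `mode_P`,
#'   `support_P`, `mean_W`, `mode_W`, `support_W`, `overshoot`.
#' @export
damage_metrics <- function(P, W, grid, ratio_series = NULL,
                           steady_ratio = 7, rel_floor = 1e-8) {
  msP <- mode_and_support(P, grid, rel_floor)
  msW <- mode_and_support(W, grid, rel_floor)
  data.frame(
    mean_P = mean_damage(P, grid), mode_P = msP$mode,
    support_P = msP$support,
    mean_W = mean_damage(W, grid), mode_W = msW$mode,
    support_W = msW$support,
    overshoot = if (is.null(ratio_series)) NA_real_
                else overshoot_fraction(ratio_series, steady_ratio)
  )
}
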