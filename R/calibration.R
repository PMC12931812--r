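#' Rescale all feedback constants by a common factor
#'
#' The Hill identities give an exact scaling law for the steady state:
#' replacing every regulation constant `k_i` by `A k_i` maps a steady
#' state \eqn{(\bar P^*, \bar W^*)} to \eqn{(\bar P^*/A, \bar W^*/A)}
#' while leaving the TD-to-stem ratio (and, for the structured model,
#' the normalized damage profiles) unchanged. This is the size-control
#' step of the two-step calibration.
#'
#' @param feedback A [feedback_params()] object.
#' @param A Positive scale factor.
#' @return The feedback object with `k <- A * k`.
#' @export
rescale_feedback <- function(feedback, A) {
  stopifnot(inherits(feedback, "feedback_params"))
  if (!is.finite(A) || A <= 0)
    stop("scale factor 'A' must be positive", call. = FALSE)
  feedback$k <- A * feedback$k
  feedback
}

# One steady-state evaluation for calibration. A run whose final totals
# fall below 2% of the initial mass has collapsed to the trivial
# equilibrium: its ratio is the decaying eigenmode's ratio, not a
# steady-state property, and must not be accepted by a ratio bisection.
steady_eval <- function(params, grid, P0, W0, steady_tol, t_max, dt) {
  dx <- grid$dx
  tot0 <- dx * (sum(P0) + sum(W0))
  traj <- pde_engine(params, grid, P0, W0, t_end = t_max, dt = dt,
                     steady_tol = steady_tol, mass_floor = 0.02 * tot0)
  Pb <- dx * sum(traj$final$P); Wb <- dx * sum(traj$final$W)
  list(Pbar = Pb, Wbar = Wb,
       ratio = if (Pb > 0) Wb / Pb else NA_real_,
       collapsed = isTRUE(traj$collapsed) || (Pb + Wb) < 0.02 * tot0,
       converged = traj$converged,
       run = list(state = traj$final, converged = traj$converged,
                  trajectory = traj))
}

#' Calibrate the replication rate to a target steady ratio
#'
#' The steady TD-to-stem ratio increases monotonically with the
#' baseline replication rate, so bisection on `lambdaP_hat` inside a
#' bracket whose endpoint ratios straddle the target converges to the
#' calibrated rate. Each evaluation is a full [run_to_steady()].
#' Evaluations that collapse to the trivial equilibrium (final totals
#' below 2% of the initial mass) are treated as "ratio below target":
#' a collapsed population needs a larger replication rate, and its
#' decaying-mode ratio is not a steady-state property.
#'
#' @param params A [model_params()] object (its `lambdaP_hat` is the
#'   quantity being calibrated; everything else is held fixed).
#' @param grid,P0,W0 Grid and initial densities for the steady runs.
#' @param target_ratio Target \eqn{\bar W^*/\bar P^*} (default 7).
#' @param bracket `c(lo, hi)` bracket for `lambdaP_hat` (default the
#'   published calibration range `c(0.6785, 1.1377)`).
#' @param tol Relative tolerance on the achieved ratio (default 1e-2).
#' @param maxit Maximum bisection iterations.
#' @param steady_tol,t_max,dt Steady-state run controls.
#' @return A list with `lambdaP_hat`, `ratio`, `iterations`, `history`
#'   (a data.frame of evaluated rates and ratios) and the final steady
#'   `run`.
#' @export
calibrate_replication <- function(params, grid, P0, W0, target_ratio = 7,
                                  bracket = c(0.6785, 1.1377), tol = 1e-2,
                                  maxit = 40, steady_tol = 1e-7,
                                  t_max = 400, dt = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (length(bracket) != 2L || bracket[2] <= bracket[1])
    stop("'bracket' must be an increasing pair (lo, hi)", call. = FALSE)
  ev <- function(lam) {
    params$feedback$lambdaP_hat <- lam
    steady_eval(params, grid, P0, W0, steady_tol, t_max, dt)
  }
  # effective ratio for the bisection: the ratio is increasing in
  # lambdaP_hat, and a collapsed run means lambdaP is too small
  eff <- function(e) if (e$collapsed) -Inf else e$ratio
  lo <- bracket[1]; hi <- bracket[2]
  e_lo <- ev(lo); e_hi <- ev(hi)
  if ((eff(e_lo) - target_ratio) * (eff(e_hi) - target_ratio) > 0)
    stop(sprintf(
      "bracket does not straddle the target ratio %.4g: ratio(%.4g) = %.4g%s, ratio(%.4g) = %.4g%s",
      target_ratio,
      lo, e_lo$ratio, if (e_lo$collapsed) " (collapsed)" else "",
      hi, e_hi$ratio, if (e_hi$collapsed) " (collapsed)" else ""),
      call. = FALSE)
  hist <- data.frame(lambdaP_hat = c(lo, hi),
                     ratio = c(e_lo$ratio, e_hi$ratio),
                     collapsed = c(e_lo$collapsed, e_hi$collapsed))
  mid_e <- NULL; mid <- NA_real_
  for (it in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    mid_e <- ev(mid)
    hist <- rbind(hist, data.frame(lambdaP_hat = mid, ratio = mid_e$ratio,
                                   collapsed = mid_e$collapsed))
    if (!mid_e$collapsed &&
        abs(mid_e$ratio - target_ratio) / target_ratio < tol) break
    if (eff(mid_e) > target_ratio) hi <- mid else lo <- mid
  }
  list(lambdaP_hat = mid, ratio = mid_e$ratio, iterations = it,
       history = hist, run = mid_e)
}

#' Two-step steady-state control: ratio first, size second
#'
#' Step 1 calibrates the baseline replication rate by bisection so the
#' steady TD-to-stem ratio hits `target_ratio` ([calibrate_replication()]).
#' Step 2 rescales all feedback constants by
#' `A = Wbar_achieved / target_W` ([rescale_feedback()]), which by the
#' scaling law divides the steady totals by `A` without moving the
#' ratio, and re-verifies with one final steady run.
#'
#' @inheritParams calibrate_replication
#' @param target_W Target steady total TD mass (default 10).
#' @return An object of class `calibration_result`: `lambdaP_hat`,
#'   `scale_A`, achieved `ratio` and `Wbar`, `converged`, the calibrated
#'   `params`, and step-1 `history`.
#' @export
two_step_control <- function(params, grid, P0, W0, target_ratio = 7,
                             target_W = 10, bracket = c(0.6785, 1.1377),
                             tol = 1e-2, steady_tol = 1e-7, t_max = 400,
                             dt = NULL) {
  if (all(params$feedback$k == 0))
    stop("size control is infeasible with all feedback constants zero",
         call. = FALSE)
  s1 <- calibrate_replication(params, grid, P0, W0, target_ratio, bracket,
                              tol, steady_tol = steady_tol, t_max = t_max,
                              dt = dt)
  params$feedback$lambdaP_hat <- s1$lambdaP_hat
  A <- s1$run$Wbar / target_W
  params$feedback <- rescale_feedback(params$feedback, A)
  final <- steady_eval(params, grid, P0, W0, steady_tol, t_max, dt)
  ok <- abs(final$ratio - target_ratio) / target_ratio < 2 * tol &&
    abs(final$Wbar - target_W) / target_W < 2 * tol
  structure(
    list(lambdaP_hat = s1$lambdaP_hat, scale_A = A,
         ratio = final$ratio, Wbar = final$Wbar, Pbar = final$Pbar,
         converged = final$converged, achieved = ok,
         params = params, history = s1$history),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  cat(sprintf("  lambdaP_hat = %.6g, k-scale A = %.6g\n",
              x$lambdaP_hat, x$scale_A))
  cat(sprintf("  steady: ratio = %.5g, Wbar = %.5g, Pbar = %.5g [%s]\n",
              x$ratio, x$Wbar, x$Pbar,
              if (isTRUE(x$achieved)) "targets met" else "targets NOT met"))
  invisible(x)
}
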