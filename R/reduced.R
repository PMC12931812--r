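#' Parameters of the reduced total-count ODE models
#'
#' The totals of the structured system obey a linear two-compartment
#' ODE when the death rate is constant:
#' \deqn{d\bar P/dt = (2f - 1)\lambda_P \bar P - \delta_P \bar P +
#'   \lambda_R \bar W, \qquad
#'   d\bar W/dt = (2 - 2f)\lambda_P \bar P - (\lambda_R + \delta_W)\bar W,}
#' with renewal fraction `f`. Two equivalent conventions produce `f`:
#' `f = (1 + p1 - p2)/2` (renewal-balance form) and `f = (2 p1 + p3)/2`
#' (division-outcome form); with `p3 = 1 - p1 - p2` they coincide, and
#' the object records which one was used.
#'
#' @param f Renewal fraction in \[0, 1\].
#' @param lambdaP,lambdaR Replication and dedifferentiation rates
#'   (1/time, >= 0).
#' @param deltaW Constant TD death rate (>= 0).
#' @param deltaP Constant stem attrition rate (>= 0, default 0).
#' @param sP,rQ,deltaQ Quiescence entry, reactivation, and quiescent
#'   death rates (>= 0, defaults 0; used by the quiescence reduction).
#' @param f_convention `"renewal_balance"` or `"division_outcome"`,
#'   recorded for traceability.
#' @return An object of class `totals_params`.
#' @export
totals_params <- function(f, lambdaP, lambdaR = 0, deltaW = 0, deltaP = 0,
                          sP = 0, rQ = 0, deltaQ = 0,
                          f_convention = c("renewal_balance",
                                           "division_outcome")) {
  f_convention <- match.arg(f_convention)
  vals <- c(lambdaP, lambdaR, deltaW, deltaP, sP, rQ, deltaQ)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all rates must be finite and nonnegative", call. = FALSE)
  if (!is.finite(f) || f < 0 || f > 1)
    stop("renewal fraction 'f' must lie in [0, 1]", call. = FALSE)
  structure(list(f = f, lambdaP = lambdaP, lambdaR = lambdaR,
                 deltaW = deltaW, deltaP = deltaP,
                 sP = sP, rQ = rQ, deltaQ = deltaQ,
                 f_convention = f_convention),
            class = "totals_params")
}

#' Renewal fraction from division probabilities
#'
#' `f = (1 + p1 - p2)/2`, equivalently `(2 p1 + p3)/2` under
#' `p1 + p2 + p3 = 1`.
#'
#' @param p1,p2 Self-renewal and differentiation probabilities.
#' @return The renewal fraction.
#' @export
renewal_fraction <- function(p1, p2) (1 + p1 - p2) / 2

#' Right-hand side of the total-count ODEs
#'
#' @param Pbar,Wbar Current totals (>= 0).
#' @param params A [totals_params()] object.
#' @param death_integral Optional value of \eqn{\int \delta(x) W\,dx}
#'   replacing the constant-death term \eqn{\delta_W \bar W} (used when
#'   matching a structured run with damage-dependent death).
#' @return `c(dPbar, dWbar)`.
#' @export
totals_rhs <- function(Pbar, Wbar, params, death_integral = NULL) {
  stopifnot(inherits(params, "totals_params"))
  f <- params$f
  dW_death <- if (is.null(death_integral)) params$deltaW * Wbar
              else death_integral
  c((2 * f - 1) * params$lambdaP * Pbar - params$deltaP * Pbar +
      params$lambdaR * Wbar,
    (2 - 2 * f) * params$lambdaP * Pbar - params$lambdaR * Wbar - dW_death)
}

#' Forward-Euler integration of the total-count ODEs
#'
#' Uses the same explicit stepping as the PDE solver so that
#' trajectory comparisons between the structured and reduced models are
#' apples-to-apples discrete statements.
#'
#' @inheritParams totals_rhs
#' @param P0,W0 Initial totals.
#' @param t_end Final time.
#' @param dt Timestep.
#' @return A list with `times`, `Pbar`, `Wbar`, `ratio`.
#' @export
simulate_totals <- function(params, P0, W0, t_end, dt) {
  stopifnot(inherits(params, "totals_params"), t_end > 0, dt > 0)
  n <- ceiling(t_end / dt - 1e-9)
  times <- numeric(n + 1L); Pb <- numeric(n + 1L); Wb <- numeric(n + 1L)
  Pb[1L] <- P0; Wb[1L] <- W0
  t <- 0
  for (k in seq_len(n)) {
    dt_k <- min(dt, t_end - t)
    d <- totals_rhs(Pb[k], Wb[k], params)
    Pb[k + 1L] <- Pb[k] + dt_k * d[1L]
    Wb[k + 1L] <- Wb[k] + dt_k * d[2L]
    t <- t + dt_k
    times[k + 1L] <- t
  }
  list(times = times, Pbar = Pb, Wbar = Wb,
       ratio = ifelse(Pb > 0, Wb / Pb, NA_real_))
}

#' Integrate the no-partition comparator transport model
#'
#' The advection-reaction system with purely local reactions
#' \eqn{(2f - 1)\lambda_P P + \lambda_R W} and
#' \eqn{(2 - 2f)\lambda_P P - (\delta(x) + \lambda_R) W}: it shares the
#' total-count dynamics of the partitioned model exactly, but division
#' does not redistribute damage, so the damage distribution drifts
#' rightward without bound (mean damage grows linearly at the drift
#' speed).
#'
#' @inheritParams simulate_pde
#' @return A `pde_trajectory` (see [simulate_pde()]).
#' @export
simulate_no_partition <- function(params, grid, P0, W0, t_end, dt = NULL,
                                  snapshot_times = numeric(0),
                                  record_means = FALSE) {
  pde_engine(params, grid, P0, W0, t_end, dt, snapshot_times, record_means,
             forcing = NULL, partition = FALSE)
}

#' Linear stability of the reduced attrition model
#'
#' Jacobian of the constant-rate totals ODE:
#' `a = (2f - 1) lambdaP - deltaP`, `b = lambdaR`,
#' `c = 2 (1 - f) lambdaP`, `d = -(lambdaR + deltaW)`.
#' The trivial equilibrium is asymptotically stable iff the
#' Routh-Hurwitz conditions hold: trace < 0 and determinant > 0. When
#' defined, the report also carries the critical renewal fraction
#' `f_crit` (where the determinant changes sign) and the quiescence
#' surcharge `delta_f`.
#'
#' @param params A [totals_params()] object.
#' @return An object of class `stability_report` with entries `a`, `b`,
#'   `c`, `d`, `trace`, `determinant`, `stable`, `f_crit`, `delta_f`.
#' @export
linear_stability <- function(params) {
  stopifnot(inherits(params, "totals_params"))
  a <- (2 * params$f - 1) * params$lambdaP - params$deltaP
  b <- params$lambdaR
  cc <- 2 * (1 - params$f) * params$lambdaP
  d <- -(params$lambdaR + params$deltaW)
  tr <- a + d
  det <- a * d - b * cc
  f_crit <- if (params$deltaW > 0 && params$lambdaP > 0)
    critical_renewal_attrition(params$deltaP, params$deltaW,
                               params$lambdaP, params$lambdaR)
  else NA_real_
  delta_f <- if (params$sP > 0 && params$deltaW > 0 && params$lambdaP > 0 &&
                 params$rQ + params$deltaQ > 0)
    quiescence_delta_f(params$sP, params$rQ, params$deltaQ,
                       params$lambdaP, params$deltaW, params$lambdaR)
  else 0
  structure(list(a = a, b = b, c = cc, d = d, trace = tr,
                 determinant = det, stable = (tr < 0 && det > 0),
                 f_crit = f_crit, delta_f = delta_f),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>\n")
  cat(sprintf("  J = [% .4g % .4g; % .4g % .4g]\n", x$a, x$b, x$c, x$d))
  cat(sprintf("  trace = %.6g, det = %.6g -> %s\n", x$trace, x$determinant,
              if (x$stable) "stable" else "not stable"))
  if (is.finite(x$f_crit))
    cat(sprintf("  f_crit = %.6g (delta_f = %.6g)\n", x$f_crit, x$delta_f))
  invisible(x)
}

#' Critical renewal fraction under stem attrition
#'
#' The renewal fraction at which the reduced system's determinant
#' vanishes (zero-eigenvalue stability change):
#' \deqn{f_{crit} = \frac{\delta_P\delta_W + \delta_P\lambda_R +
#'   \delta_W\lambda_P - \lambda_P\lambda_R}{2\delta_W\lambda_P}
#'   = \frac{\delta_W - \lambda_R}{2\delta_W} +
#'     \frac{\delta_P(\delta_W + \lambda_R)}{2\delta_W\lambda_P}.}
#' At `deltaP = 0` it reduces to the attrition-free threshold
#' \eqn{(\delta_W - \lambda_R)/(2\delta_W)}.
#'
#' @param deltaP Stem attrition rate (>= 0).
#' @param deltaW TD death rate (> 0).
#' @param lambdaP Replication rate (> 0).
#' @param lambdaR Dedifferentiation rate (>= 0).
#' @return The critical renewal fraction.
#' @examples
#' critical_renewal_attrition(0, 0.5, 1, 0.1)  # 0.4
#' @export
critical_renewal_attrition <- function(deltaP, deltaW, lambdaP, lambdaR) {
  if (deltaW <= 0 || lambdaP <= 0)
    stop("'deltaW' and 'lambdaP' must be positive", call. = FALSE)
  if (deltaP < 0 || lambdaR < 0)
    stop("'deltaP' and 'lambdaR' must be nonnegative", call. = FALSE)
  (deltaP * deltaW + deltaP * lambdaR + deltaW * lambdaP -
     lambdaP * lambdaR) / (2 * deltaW * lambdaP)
}

#' Steady stem-to-TD ratio under attrition
#'
#' \eqn{\bar P^*/\bar W^* = \delta_W / (\lambda_P - \delta_P)}, the
#' replication-death balance of the reduced model; with `deltaP = 0`
#' this is the classical `delta / lambdaP` balance.
#'
#' @inheritParams critical_renewal_attrition
#' @return The steady ratio \eqn{\bar P^*/\bar W^*}.
#' @export
attrition_steady_ratio <- function(deltaP, deltaW, lambdaP) {
  if (lambdaP <= deltaP)
    stop("no positive steady ratio: requires lambdaP > deltaP",
         call. = FALSE)
  if (deltaW < 0 || deltaP < 0)
    stop("death rates must be nonnegative", call. = FALSE)
  deltaW / (lambdaP - deltaP)
}

#' Renewal surcharge required by a leaky quiescent pool
#'
#' Under the quasi-steady quiescence reduction
#' (\eqn{\bar Q^* = s_P/(r_Q + \delta_Q)\,\bar P^*}), the critical
#' renewal fraction shifts upward by
#' \deqn{\Delta f = \frac{s_P\,\delta_Q}{r_Q + \delta_Q}\,
#'   \frac{\lambda_R + \delta_W}{2\lambda_P\delta_W}.}
#' It vanishes when quiescent cells never die (`deltaQ = 0`), grows
#' with the entry rate `sP` and quiescent death `deltaQ`, and shrinks
#' as reactivation `rQ` speeds up.
#'
#' @param sP Quiescence entry rate (>= 0).
#' @param rQ Reactivation rate (>= 0).
#' @param deltaQ Quiescent death rate (>= 0); `rQ + deltaQ` must be > 0.
#' @param lambdaP Replication rate (> 0).
#' @param deltaW TD death rate (> 0).
#' @param lambdaR Dedifferentiation rate (>= 0).
#' @return The surcharge \eqn{\Delta f \ge 0}.
#' @export
quiescence_delta_f <- function(sP, rQ, deltaQ, lambdaP, deltaW, lambdaR) {
  if (rQ + deltaQ <= 0)
    stop("'rQ + deltaQ' must be positive", call. = FALSE)
  if (lambdaP <= 0 || deltaW <= 0)
    stop("'lambdaP' and 'deltaW' must be positive", call. = FALSE)
  if (sP < 0 || lambdaR < 0 || deltaQ < 0 || rQ < 0)
    stop("rates must be nonnegative", call. = FALSE)
  sP * deltaQ / (rQ + deltaQ) * (lambdaR + deltaW) / (2 * lambdaP * deltaW)
}
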