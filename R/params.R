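#' Damage partition fractions for the three division modes
#'
#' Each stem division splits the mother's damage `x'` between the two
#' daughters through delta-function transition kernels. Symmetric
#' self-renewal (P -> P + P) uses fractions `(alpha1, alpha2)`, symmetric
#' differentiation (P -> W + W) uses `(beta1, beta2)`, and asymmetric
#' division (P -> P + W) gives the stem daughter `gamma1` and the TD
#' daughter `gamma2`. Each pair sums to 1 exactly, so every division
#' conserves total damage. Baselines: `alpha = beta = (0.5, 0.5)`,
#' `gamma = (1/3, 2/3)` (the stem daughter inherits less damage).
#'
#' @param alpha1,beta1,gamma1 First fraction of each pair, in (0, 1);
#'   the complements are computed as `1 - alpha1` etc.
#' @return An object of class `partition_fractions`.
#' @export
partition_fractions <- function(alpha1 = 0.5, beta1 = 0.5, gamma1 = 1 / 3) {
  for (v in c(alpha1 = alpha1, beta1 = beta1, gamma1 = gamma1)) {
    if (!is.finite(v) || v <= 0 || v >= 1)
      stop("partition fractions must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(
    list(alpha1 = alpha1, alpha2 = 1 - alpha1,
         beta1 = beta1, beta2 = 1 - beta1,
         gamma1 = gamma1, gamma2 = 1 - gamma1),
    class = "partition_fractions"
  )
}

#' Baseline rates and Hill feedback constants
#'
#' Division probabilities and rates are regulated by total population
#' sizes through decreasing Hill functions ([hill_regulation()]):
#' `p1`, `p2` and `lambdaP` by the total TD mass, `lambdaR` by the total
#' stem mass. `p3 = 1 - p1 - p2` inherits feedback through normalization;
#' requiring `p1_hat + p2_hat <= 1` at construction guarantees `p3 >= 0`
#' at runtime because Hill regulation only decreases `p1` and `p2`.
#'
#' @param p1_hat,p2_hat Baseline self-renewal / differentiation
#'   probabilities (each in \[0, 1\], sum <= 1).
#' @param lambdaP_hat Baseline stem replication rate (1/time, >= 0).
#' @param lambdaR_hat Baseline dedifferentiation rate (1/time, >= 0).
#' @param k Regulation constants `c(k1, k2, k3, k4)` (1/cell-number,
#'   each >= 0; 0 disables the corresponding feedback).
#' @param m Hill exponents `c(m1, m2, m3, m4)` (> 0, default 2).
#' @return An object of class `feedback_params`.
#' @seealso [feedback_preset()] for the k-constraint presets used in the
#'   sensitivity sweeps.
#' @export
feedback_params <- function(p1_hat, p2_hat, lambdaP_hat, lambdaR_hat,
                            k = c(0, 0, 0, 0), m = c(2, 2, 2, 2)) {
  if (length(k) != 4L || any(!is.finite(k)) || any(k < 0))
    stop("'k' must be four nonnegative regulation constants", call. = FALSE)
  if (length(m) != 4L || any(!is.finite(m)) || any(m <= 0))
    stop("'m' must be four positive Hill exponents", call. = FALSE)
  if (p1_hat < 0 || p1_hat > 1 || p2_hat < 0 || p2_hat > 1)
    stop("baseline probabilities must lie in [0, 1]", call. = FALSE)
  if (p1_hat + p2_hat > 1 + 1e-12)
    stop("p1_hat + p2_hat must not exceed 1 (ensures p3 >= 0)", call. = FALSE)
  if (lambdaP_hat < 0 || lambdaR_hat < 0)
    stop("baseline rates must be nonnegative", call. = FALSE)
  structure(
    list(p1_hat = p1_hat, p2_hat = p2_hat,
         lambdaP_hat = lambdaP_hat, lambdaR_hat = lambdaR_hat,
         k = as.numeric(k), m = as.numeric(m)),
    class = "feedback_params"
  )
}

#' Named feedback k-constraint presets
#'
#' Two published reduced parameterizations of the four regulation
#' constants in terms of `k1`:
#' \describe{
#'   \item{`"sweeps_default"`}{`k2 = 0.1 k1`, `k3 = k4 = 0` — the setting
#'     used by the sensitivity sweeps, isolating feedback on the division
#'     probabilities.}
#'   \item{`"calibration_text"`}{`k2 = k3 = 0.1 k1`, `k4 = 10 k1` — the
#'     alternative constraint with feedback on replication and
#'     dedifferentiation as well.}
#' }
#'
#' @param name Preset name.
#' @param k1 The free regulation constant.
#' @return A numeric vector `c(k1, k2, k3, k4)`.
#' @export
feedback_preset <- function(name = c("sweeps_default", "calibration_text"),
                            k1 = 0.1) {
  name <- match.arg(name)
  if (k1 < 0) stop("'k1' must be nonnegative", call. = FALSE)
  switch(name,
    sweeps_default   = c(k1, 0.1 * k1, 0, 0),
    calibration_text = c(k1, 0.1 * k1, 0.1 * k1, 10 * k1)
  )
}

#' Hill-type negative regulation
#'
#' `baseline / (1 + (k * signal)^m)`: decreasing in the signal and in
#' `k`, equal to the baseline at zero signal, always in (0, baseline].
#'
#' @param baseline Unregulated value (>= 0).
#' @param k Regulation constant (>= 0; 0 disables feedback).
#' @param m Hill exponent (> 0).
#' @param signal Regulating total population mass (>= 0). May be a
#'   vector.
#' @return The regulated value(s).
#' @examples
#' hill_regulation(0.5, 1, 2, 1)    # 0.25
#' hill_regulation(0.5, 0, 2, 10)   # 0.5 (feedback off)
#' @export
hill_regulation <- function(baseline, k, m, signal) {
  if (!all(is.finite(c(baseline, k, m))) || any(!is.finite(signal)))
    stop("all arguments must be finite", call. = FALSE)
  if (baseline < 0 || k < 0 || any(signal < 0))
    stop("'baseline', 'k' and 'signal' must be nonnegative", call. = FALSE)
  if (m <= 0) stop("Hill exponent 'm' must be positive", call. = FALSE)
  baseline / (1 + (k * signal)^m)
}

#' Feedback-regulated division probabilities and rates
#'
#' Evaluates the runtime rates at the current totals:
#' `p1 = hill(p1_hat, k1, m1, Wbar)`, `p2 = hill(p2_hat, k2, m2, Wbar)`,
#' `lambdaP = hill(lambdaP_hat, k3, m3, Wbar)`,
#' `lambdaR = hill(lambdaR_hat, k4, m4, Pbar)`, and
#' `p3 = 1 - p1 - p2` by normalization.
#'
#' @param Pbar,Wbar Total stem and TD masses (>= 0).
#' @param feedback A [feedback_params()] object.
#' @return A list with elements `p1`, `p2`, `p3`, `lambdaP`, `lambdaR`.
#' @export
effective_rates <- function(Pbar, Wbar, feedback) {
  stopifnot(inherits(feedback, "feedback_params"))
  if (Pbar < 0 || Wbar < 0)
    stop("total masses must be nonnegative", call. = FALSE)
  k <- feedback$k; m <- feedback$m
  p1 <- hill_regulation(feedback$p1_hat, k[1], m[1], Wbar)
  p2 <- hill_regulation(feedback$p2_hat, k[2], m[2], Wbar)
  lamP <- hill_regulation(feedback$lambdaP_hat, k[3], m[3], Wbar)
  lamR <- hill_regulation(feedback$lambdaR_hat, k[4], m[4], Pbar)
  list(p1 = p1, p2 = p2, p3 = 1 - p1 - p2, lambdaP = lamP, lambdaR = lamR)
}

#' TD death model
#'
#' Either a constant death rate `delta` or the linear damage-dependent
#' form `delta(x) = coef * x` (default coefficient 0.6, which makes
#' lethality appreciable as damage approaches the normalized bound
#' x = 1). The rate is nonnegative and nondecreasing in x.
#'
#' @param kind `"constant"` or `"linear"`.
#' @param value Constant rate (for `kind = "constant"`) or linear
#'   coefficient (for `kind = "linear"`); must be >= 0.
#' @return An object of class `death_model`.
#' @export
death_model <- function(kind = c("linear", "constant"), value = 0.6) {
  kind <- match.arg(kind)
  if (!is.finite(value) || value < 0)
    stop("death model parameter must be nonnegative", call. = FALSE)
  structure(list(kind = kind, value = value), class = "death_model")
}

#' Evaluate a death model at damage levels x
#'
#' @param model A [death_model()].
#' @param x Damage level(s), all >= 0.
#' @return The death rate(s) `delta(x)`.
#' @examples
#' death_rate(death_model("linear", 0.6), 0.5)   # 0.3
#' @export
death_rate <- function(model, x) {
  stopifnot(inherits(model, "death_model"))
  if (any(x < 0)) stop("damage 'x' must be nonnegative", call. = FALSE)
  switch(model$kind,
    constant = rep(model$value, length(x)),
    linear   = model$value * x
  )
}

#' Dedifferentiation rule
#'
#' How TD cells revert to the stem compartment at rate `lambdaR`:
#' \describe{
#'   \item{`"constant"`}{all TD cells revert, keeping their damage
#'     (full retention, rho = 1).}
#'   \item{`"threshold"`}{only cells with damage `x >= xc` revert
#'     (threshold-dependent dedifferentiation, the detoxification loop);
#'     `xc = 0` reduces to the constant rule.}
#'   \item{`"partial_repair"`}{all cells revert but retain only the
#'     fraction `rho` of their damage (kernel `r(x|x') =
#'     delta(x - rho x')`); `rho = 1` reduces to the constant rule.
#'     `rho = 0` (complete repair) deposits all returning mass at the
#'     zero-damage node.}
#'   \item{`"state_dependent"`}{retention varies with the cell's damage:
#'     a cell with damage `x'` returns at `rho(x') x'`, with
#'     `rho(x') = rho_min + (rho_max - rho_min) s(x')` for a monotone
#'     shape `s`; supply the full retention function via `rho_fun`.}
#' }
#'
#' @param variant One of the rule names above.
#' @param xc Damage threshold (>= 0), used by `"threshold"`.
#' @param rho Retention fraction in \[0, 1\], used by `"partial_repair"`.
#' @param rho_fun Function `x' -> rho(x')` in \[0, 1\], required for
#'   `"state_dependent"`.
#' @return An object of class `dediff_rule`.
#' @export
dediff_rule <- function(variant = c("constant", "threshold",
                                    "partial_repair", "state_dependent"),
                        xc = 0.6, rho = 1, rho_fun = NULL) {
  variant <- match.arg(variant)
  if (variant == "threshold" && (!is.finite(xc) || xc < 0))
    stop("threshold 'xc' must be nonnegative", call. = FALSE)
  if (variant == "partial_repair" && (!is.finite(rho) || rho < 0 || rho > 1))
    stop("retention fraction 'rho' must lie in [0, 1]", call. = FALSE)
  if (variant == "state_dependent" && !is.function(rho_fun))
    stop("'rho_fun' must be a function for the state-dependent rule",
         call. = FALSE)
  structure(list(variant = variant, xc = xc, rho = rho, rho_fun = rho_fun),
            class = "dediff_rule")
}

#' Full model parameterization
#'
#' Collects everything the PDE solver needs: drift speeds, partition
#' fractions, feedback-regulated rates, the TD death model, the
#' dedifferentiation rule, the boundary inflow and the Courant number.
#' Optional reduced-model parameters (stem attrition `deltaP`) extend
#' the stem equation with a constant death sink.
#'
#' @param vP,vW Damage drift speeds (damage/time, >= 0).
#' @param fractions A [partition_fractions()] object.
#' @param feedback A [feedback_params()] object.
#' @param death A [death_model()].
#' @param dediff A [dediff_rule()].
#' @param g Boundary inflow density at x = 0 (>= 0; 0 is the
#'   homogeneous Dirichlet condition — no influx of pristine cells).
#' @param courant Courant number in (0, 1) used when `dt` is derived
#'   from the CFL bound.
#' @param deltaP Constant stem attrition rate (>= 0, default 0).
#' @return An object of class `model_params`.
#' @export
model_params <- function(vP, vW,
                         fractions = partition_fractions(),
                         feedback,
                         death = death_model("linear", 0.6),
                         dediff = dediff_rule("constant"),
                         g = 0, courant = 0.25, deltaP = 0) {
  stopifnot(inherits(fractions, "partition_fractions"),
            inherits(feedback, "feedback_params"),
            inherits(death, "death_model"),
            inherits(dediff, "dediff_rule"))
  if (vP < 0 || vW < 0) stop("drift speeds must be >= 0", call. = FALSE)
  if (g < 0) stop("boundary inflow 'g' must be >= 0", call. = FALSE)
  if (courant <= 0 || courant >= 1)
    stop("'courant' must lie in (0, 1)", call. = FALSE)
  if (deltaP < 0) stop("'deltaP' must be >= 0", call. = FALSE)
  structure(
    list(vP = vP, vW = vW, fractions = fractions, feedback = feedback,
         death = death, dediff = dediff, g = g, courant = courant,
         deltaP = deltaP),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  fb <- x$feedback
  cat("<model_params>\n")
  cat(sprintf("  drift: vP = %g, vW = %g; inflow g = %g; C = %g\n",
              x$vP, x$vW, x$g, x$courant))
  cat(sprintf("  baselines: p1 = %g, p2 = %g, lambdaP = %g, lambdaR = %g\n",
              fb$p1_hat, fb$p2_hat, fb$lambdaP_hat, fb$lambdaR_hat))
  cat(sprintf("  feedback k = (%s), m = (%s)\n",
              paste(signif(fb$k, 4), collapse = ", "),
              paste(fb$m, collapse = ", ")))
  cat(sprintf("  death: %s (%g); dediff: %s\n",
              x$death$kind, x$death$value, x$dediff$variant))
  invisible(x)
}
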