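test_that("totals ODE right-hand side matches the balance laws", {
  tp <- totals_params(f = 0.5, lambdaP = 1, lambdaR = 0, deltaW = 0.5)
  expect_equal(totals_rhs(20, 40, tp), c(0, 0))
  tp2 <- totals_params(f = 1, lambdaP = 0.8, lambdaR = 0, deltaW = 0.3)
  expect_equal(totals_rhs(5, 0, tp2), c(0.8 * 5, 0))
  # renewal-fraction conventions coincide under normalization
  p1 <- 0.35; p2 <- 0.45; p3 <- 1 - p1 - p2
  expect_equal(renewal_fraction(p1, p2), (2 * p1 + p3) / 2)
})

test_that("totals drift matches the structured model's first step", {
  g <- make_grid(2, 800)
  params <- baseline_params()
  params$vP <- 0.05; params$vW <- 0.05
  ic <- gaussian_ic(g, 3, 0.5, 0.1)
  dt <- cfl_timestep(g, 0.05, 0.05, 0.25)
  st <- pde_step(list(t = 0, P = ic, W = ic), params, g, dt)
  tp <- totals_params(f = 0.5, lambdaP = 1, lambdaR = 0, deltaW = 0.5)
  d <- totals_rhs(density_mass(ic, g), density_mass(ic, g), tp)
  expect_equal((density_mass(st$P, g) - density_mass(ic, g)) / dt, d[1],
               tolerance = 1e-10)
  expect_equal((density_mass(st$W, g) - density_mass(ic, g)) / dt, d[2],
               tolerance = 1e-10)
})

test_that("no-partition comparator: fixed point and identical totals", {
  g <- make_grid(2, 200)
  # all reactions off, no drift: the profile is a fixed point
  frozen <- model_params(
    vP = 0, vW = 0,
    feedback = feedback_params(0, 0, lambdaP_hat = 0, lambdaR_hat = 0),
    death = death_model("constant", 0))
  ic <- gaussian_ic(g, 1, 0.7, 0.1)
  traj <- simulate_no_partition(frozen, g, ic, ic, t_end = 1, dt = 0.05)
  expect_equal(traj$final$P, ic, tolerance = 1e-14)
  # the partitioned and no-partition systems share total-count dynamics
  g4 <- make_grid(20, 400)
  params <- baseline_params()
  ic4 <- indicator_ic(g4, 10, 2, 4)
  t_with <- simulate_pde(params, g4, ic4, ic4, t_end = 10)
  t_without <- simulate_no_partition(params, g4, ic4, ic4, t_end = 10)
  expect_equal(t_with$Pbar, t_without$Pbar, tolerance = 1e-10)
  expect_equal(t_with$Wbar, t_without$Wbar, tolerance = 1e-10)
})

test_that("linear stability report implements the Routh-Hurwitz test", {
  z <- totals_params(f = 0.5, lambdaP = 0, lambdaR = 0, deltaW = 0)
  rz <- linear_stability(z)
  expect_equal(rz$trace, 0); expect_equal(rz$determinant, 0)
  expect_false(rz$stable)
  tp <- totals_params(f = 0.3, lambdaP = 1, lambdaR = 0.1, deltaW = 0.5,
                      deltaP = 0.05)
  r <- linear_stability(tp)
  expect_equal(r$a, (2 * 0.3 - 1) * 1 - 0.05)
  expect_equal(r$b, 0.1)
  expect_equal(r$c, 2 * 0.7 * 1)
  expect_equal(r$d, -(0.1 + 0.5))
  expect_equal(r$stable, r$trace < 0 && r$determinant > 0)
  # determinant vanishes exactly at the critical renewal fraction
  fc <- critical_renewal_attrition(0.05, 0.5, 1, 0.1)
  at <- function(f) linear_stability(totals_params(
    f = f, lambdaP = 1, lambdaR = 0.1, deltaW = 0.5,
    deltaP = 0.05))$determinant
  expect_equal(at(fc), 0, tolerance = 1e-12)
  expect_gt(at(fc - 1e-6), 0)
  expect_lt(at(fc + 1e-6), 0)
})

test_that("critical renewal fraction and steady ratio formulas", {
  expect_equal(critical_renewal_attrition(0, 0.5, 1, 0.1), 0.4)
  expect_equal(critical_renewal_attrition(0, 0.3, 1, 0.3), 0)
  # decomposition: f_crit = f_tilde + attrition surcharge
  fc <- critical_renewal_attrition(0.07, 0.4, 0.9, 0.12)
  f_tilde <- (0.4 - 0.12) / (2 * 0.4)
  expect_equal(fc, f_tilde + 0.07 * (0.4 + 0.12) / (2 * 0.4 * 0.9),
               tolerance = 1e-14)
  expect_equal(attrition_steady_ratio(0, 0.5, 1), 0.5)
  expect_equal(attrition_steady_ratio(0.5, 0.5, 1), 1)
  expect_error(attrition_steady_ratio(1, 0.5, 1), "lambdaP > deltaP")
  expect_error(critical_renewal_attrition(0, 0, 1, 0.1), "positive")
})

test_that("attrition totals model relaxes to the predicted steady ratio", {
  # choose f = f_crit so a nontrivial stationary direction exists
  lamP <- 1; dW <- 0.5; dP <- 0.1; lamR <- 0.05
  f <- critical_renewal_attrition(dP, dW, lamP, lamR)
  tp <- totals_params(f = f, lambdaP = lamP, lambdaR = lamR, deltaW = dW,
                      deltaP = dP)
  sim <- simulate_totals(tp, P0 = 1, W0 = 1, t_end = 400, dt = 0.01)
  n <- length(sim$ratio)
  expect_equal(1 / sim$ratio[n], attrition_steady_ratio(dP, dW, lamP),
               tolerance = 1e-3)
})

test_that("quiescence surcharge obeys its limits and the QSSA reduction", {
  expect_equal(quiescence_delta_f(0.2, 0.1, 0, 1, 0.5, 0.1), 0)
  # decreasing in the reactivation rate
  dfs <- vapply(c(0.05, 0.1, 0.5, 2, 10), function(rQ)
    quiescence_delta_f(0.2, rQ, 0.1, 1, 0.5, 0.1), numeric(1))
  expect_true(all(diff(dfs) < 0))
  # increasing in entry rate and quiescent death
  expect_gt(quiescence_delta_f(0.4, 0.1, 0.1, 1, 0.5, 0.1),
            quiescence_delta_f(0.2, 0.1, 0.1, 1, 0.5, 0.1))
  expect_gt(quiescence_delta_f(0.2, 0.1, 0.2, 1, 0.5, 0.1),
            quiescence_delta_f(0.2, 0.1, 0.1, 1, 0.5, 0.1))
  # QSSA: determinant of the reduced 2x2 system vanishes at f_crit + df
  sP <- 0.2; rQ <- 0.1; dQ <- 0.15; lamP <- 1; dW <- 0.5; lamR <- 0.1
  dP <- 0.05
  df <- quiescence_delta_f(sP, rQ, dQ, lamP, dW, lamR)
  fc <- critical_renewal_attrition(dP, dW, lamP, lamR)
  f <- fc + df
  dP_eff <- dP + sP * dQ / (rQ + dQ)   # quiescence leak as extra attrition
  a <- (2 * f - 1) * lamP - dP_eff; b <- lamR
  cc <- 2 * (1 - f) * lamP; d <- -(lamR + dW)
  expect_equal(a * d - b * cc, 0, tolerance = 1e-12)
  expect_error(quiescence_delta_f(0.2, 0, 0, 1, 0.5, 0.1), "positive")
})

test_that("steady states balance replication against death (constant delta)", {
  g <- make_grid(2, 200)
  params <- model_params(
    vP = 0.05, vW = 0.05,
    feedback = feedback_params(0.5, 0.5, lambdaP_hat = 1, lambdaR_hat = 0.05,
                               k = feedback_preset("sweeps_default", 0.1)),
    death = death_model("constant", 0.3))
  ic <- indicator_ic(g, 10, 0.2, 0.4)
  rs <- run_to_steady(params, g, ic, ic, tol = 1e-8, t_max = 400)
  expect_true(rs$converged)
  Pb <- density_mass(rs$state$P, g); Wb <- density_mass(rs$state$W, g)
  lamP <- effective_rates(Pb, Wb, params$feedback)$lambdaP
  expect_equal(lamP * Pb, 0.3 * Wb, tolerance = 0.01)
})
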