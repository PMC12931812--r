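test_that("grid construction gives uniform nodes and validates input", {
  g <- make_grid(2, 400)
  expect_equal(g$dx, 0.005)
  expect_equal(g$x[11], 0.05)          # x_10
  expect_equal(g$x[1], 0)
  expect_equal(g$x[g$N + 1], 2)
  expect_true(all(diff(g$x) > 0))
  expect_equal(max(abs(diff(g$x) - g$dx)), 0, tolerance = 1e-15)
  g2 <- make_grid(20, 100)
  expect_equal(g2$dx, 0.2)
  expect_error(make_grid(2, 0), "integer >= 2")
  expect_error(make_grid(-1, 10), "positive")
})

test_that("CFL timestep matches the stability bound exactly", {
  expect_equal(cfl_timestep(make_grid(2, 100), 0.05, 0.05, 0.005), 0.002)
  expect_equal(cfl_timestep(make_grid(2, 200), 0.05, 0.05, 0.005), 0.001)
  g <- make_grid(2, 400)
  for (C in c(0.005, 0.25, 0.9)) {
    dt <- cfl_timestep(g, 0.1, 0.02, C)
    expect_equal(dt * 0.1 / g$dx, C)   # dt * max(v) / dx = C exactly
  }
  expect_error(cfl_timestep(g, 0, 0, 0.25), "supply 'dt'")
  expect_error(cfl_timestep(g, 0.1, 0.1, 1.2), "\\(0, 1\\)")
})

test_that("Hill regulation is correct, bounded, and monotone", {
  expect_equal(hill_regulation(0.5, 0, 2, 10), 0.5)
  expect_equal(hill_regulation(0.5, 1, 2, 1), 0.25)
  expect_equal(hill_regulation(1.0, 0.1, 2, 10), 0.5)
  # monotone nonincreasing in the signal and in k; baseline at zero signal
  sig <- seq(0, 50, length.out = 40)
  for (k in c(0.01, 0.1, 1)) {
    v <- hill_regulation(0.7, k, 2, sig)
    expect_true(all(diff(v) <= 0))
    expect_true(all(v > 0 & v <= 0.7))
    expect_equal(v[1], 0.7)
  }
  expect_true(all(hill_regulation(0.7, 0.5, 2, sig) <=
                  hill_regulation(0.7, 0.1, 2, sig)))
})

test_that("effective rates normalize division probabilities exactly", {
  fb0 <- feedback_params(0.5, 0.5, 1, 0)
  r0 <- effective_rates(3, 10, fb0)
  expect_equal(r0$p1, 0.5); expect_equal(r0$p2, 0.5)
  expect_equal(r0$p3, 0)
  fb <- feedback_params(0.5, 0.3, 1, 0.1,
                        k = c(0.1, 0.01, 0, 0), m = rep(2, 4))
  r <- effective_rates(0, 10, fb)
  expect_equal(r$p1, 0.25)
  expect_equal(r$p2, 0.3 / 1.01, tolerance = 1e-12)
  expect_equal(r$p3, 1 - 0.25 - 0.3 / 1.01, tolerance = 1e-12)
  # zero signal returns baselines
  rz <- effective_rates(0, 0, fb)
  expect_equal(rz$p1, 0.5); expect_equal(rz$p2, 0.3)
  expect_equal(rz$p3, 0.2)
  # sum to one exactly for arbitrary totals
  set.seed(4)
  for (i in 1:20) {
    ri <- effective_rates(runif(1, 0, 50), runif(1, 0, 50), fb)
    expect_equal(ri$p1 + ri$p2 + ri$p3, 1, tolerance = 1e-15)
    expect_true(all(c(ri$p1, ri$p2, ri$p3) >= 0 &
                    c(ri$p1, ri$p2, ri$p3) <= 1))
  }
  expect_error(feedback_params(0.6, 0.6, 1, 0), "p3")
})

test_that("death models evaluate and validate", {
  expect_equal(death_rate(death_model("linear", 0.6), 0.5), 0.3)
  expect_equal(death_rate(death_model("constant", 0.5), 17), 0.5)
  expect_error(death_rate(death_model("linear", 0.6), -0.1), "nonnegative")
  x <- seq(0, 2, by = 0.1)
  d <- death_rate(death_model("linear", 0.6), x)
  expect_true(all(diff(d) >= 0))       # nondecreasing
})

test_that("parameter containers enforce their invariants", {
  fr <- partition_fractions(1 / 3, 0.5, 0.25)
  expect_equal(fr$alpha1 + fr$alpha2, 1)
  expect_equal(fr$beta1 + fr$beta2, 1)
  expect_equal(fr$gamma1 + fr$gamma2, 1)
  expect_error(partition_fractions(0), "strictly in")
  expect_error(partition_fractions(1), "strictly in")
  expect_error(dediff_rule("partial_repair", rho = 1.2), "\\[0, 1\\]")
  expect_error(dediff_rule("state_dependent"), "rho_fun")
  expect_error(model_params(vP = -1, vW = 0,
                            feedback = feedback_params(0.5, 0.5, 1, 0)),
               ">= 0")
  k <- feedback_preset("sweeps_default", 0.2)
  expect_equal(k, c(0.2, 0.02, 0, 0))
  k2 <- feedback_preset("calibration_text", 0.2)
  expect_equal(k2, c(0.2, 0.02, 0.02, 2))
})

test_that("indicator initial conditions carry exact printed mass", {
  g <- make_grid(2, 400)
  ic <- indicator_ic(g, 5, 0.2, 0.4)
  expect_equal(density_mass(ic, g), 1)           # 5 * 0.2 exactly
  g2 <- make_grid(20, 2000)
  ic2 <- indicator_ic(g2, 10, 2, 4)
  expect_equal(density_mass(ic2, g2), 20)
})
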