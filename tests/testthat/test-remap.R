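test_that("remap is the identity at a = 1 and errors outside (0, 1]", {
  g <- make_grid(2, 400)
  u <- random_density(g)
  expect_identical(remap_density(u, 1, g), u)
  expect_error(remap_density(u, 0, g), "\\(0, 1\\]")
  expect_error(remap_density(u, 1.5, g), "\\(0, 1\\]")
})

test_that("node-aligned point mass moves to the contracted node", {
  g <- make_grid(2, 400)                      # dx = 0.005
  u <- numeric(g$N + 1); u[g$x == 0.4] <- 1   # point mass at x = 0.4
  v <- remap_density(u, 0.5, g)
  expect_equal(v[g$x == 0.2], 1)
  expect_equal(sum(v > 0), 1L)
})

test_that("remap conserves mass exactly and scales the moment by a", {
  g <- make_grid(2, 317)                      # deliberately awkward N
  u <- random_density(g, seed = 7)
  for (a in c(1 / 3, 0.5, 2 / 3, 0.9, 0.123)) {
    v <- remap_density(u, a, g)
    expect_true(all(v >= 0))
    # brute-force rectangle sums as the oracle
    expect_equal(sum(v), sum(u), tolerance = 1e-13)
    expect_equal(sum(g$x * v), a * sum(g$x * u), tolerance = 1e-12)
  }
})

test_that("remap is linear in the density", {
  g <- make_grid(1, 200)
  u1 <- random_density(g, 1); u2 <- random_density(g, 2)
  a <- 2 / 3
  expect_equal(remap_density(2 * u1 + 3 * u2, a, g),
               2 * remap_density(u1, a, g) + 3 * remap_density(u2, a, g),
               tolerance = 1e-13)
})

test_that("remap of a Gaussian matches the closed-form rescaled density", {
  # oracle: (1/a) u(x/a) for u a Gaussian, evaluated analytically
  g <- make_grid(2, 400)
  a <- 1 / 3
  u <- gaussian_ic(g, 1.5, 0.9, 0.12)
  v <- remap_density(u, a, g)
  exact <- (1 / a) * gaussian_ic(g, 1.5, a * 0.9, a * 0.12)
  expect_lt(g$dx * sum(abs(v - exact)), 0.05 * g$dx * sum(exact))
  # refined grid halves the discrepancy (first-order-or-better)
  g2 <- make_grid(2, 800)
  v2 <- remap_density(gaussian_ic(g2, 1.5, 0.9, 0.12), a, g2)
  exact2 <- (1 / a) * gaussian_ic(g2, 1.5, a * 0.9, a * 0.12)
  expect_lt(g2$dx * sum(abs(v2 - exact2)),
            0.6 * g$dx * sum(abs(v - exact)))
})

test_that("composition of remaps multiplies the moment scaling", {
  g <- make_grid(2, 250)
  u <- random_density(g, 3)
  w <- remap_density(remap_density(u, 0.7, g), 0.4, g)
  expect_equal(sum(g$x * w), 0.7 * 0.4 * sum(g$x * u), tolerance = 1e-12)
  expect_equal(sum(w), sum(u), tolerance = 1e-13)
})

test_that("division sources realize the kernel bookkeeping identities", {
  g <- make_grid(2, 400)
  fr <- partition_fractions()
  # single self-renewal kernel on a node-aligned point mass
  u <- numeric(g$N + 1); u[g$x == 0.4] <- 1
  s <- division_sources(u, list(p1 = 1, p2 = 0, p3 = 0, lambdaP = 1),
                        fr, g)
  expect_equal(s$source_P[g$x == 0.2], 2)    # two daughters at x/2
  expect_equal(s$source_P[g$x == 0.4], -1)   # mother leaves
  expect_true(all(s$source_W == 0))
  # symmetric division: stem count preserved, TD gains Pbar per time
  u2 <- random_density(g, 5)
  Pbar <- density_mass(u2, g)
  s2 <- division_sources(u2, list(p1 = 0.5, p2 = 0.5, p3 = 0, lambdaP = 1),
                         fr, g)
  expect_equal(s2$net_cells_P, 0, tolerance = 1e-13)
  expect_equal(s2$net_cells_W, Pbar, tolerance = 1e-12)
  # general rates: cell-number identities and exact damage conservation
  set.seed(11)
  for (i in 1:10) {
    p1 <- runif(1, 0, 0.6); p2 <- runif(1, 0, 1 - p1); p3 <- 1 - p1 - p2
    lamP <- runif(1, 0.2, 2)
    fri <- partition_fractions(runif(1, 0.05, 0.95), runif(1, 0.05, 0.95),
                               runif(1, 0.05, 0.95))
    si <- division_sources(u2, list(p1 = p1, p2 = p2, p3 = p3,
                                    lambdaP = lamP), fri, g)
    expect_equal(si$net_cells_P, (2 * p1 + p3 - 1) * lamP * Pbar,
                 tolerance = 1e-11)
    expect_equal(si$net_cells_W, (2 * p2 + p3) * lamP * Pbar,
                 tolerance = 1e-11)
    # division conserves the total damage first moment
    expect_lt(abs(si$net_damage_P + si$net_damage_W),
              1e-12 * lamP * density_moment(u2, g))
  }
})

test_that("dedifferentiation sources cover all mechanism variants", {
  g <- make_grid(2, 400)
  W <- random_density(g, 6)
  # constant: local identity
  s <- dedifferentiation_sources(W, 0.05, dediff_rule("constant"), g)
  expect_equal(s$source_P, 0.05 * W)
  expect_equal(s$source_W, -0.05 * W)
  # threshold with support below the threshold: no flux
  Wlow <- indicator_ic(g, 2, 0.1, 0.5)
  s2 <- dedifferentiation_sources(Wlow, 1, dediff_rule("threshold", xc = 0.6),
                                  g)
  expect_true(all(s2$source_P == 0) && all(s2$source_W == 0))
  # partial repair on a node-aligned point mass
  Wp <- numeric(g$N + 1); Wp[g$x == 0.8] <- 1
  s3 <- dedifferentiation_sources(Wp, 1,
                                  dediff_rule("partial_repair", rho = 0.5), g)
  expect_equal(s3$source_P[g$x == 0.4], 1)
  # state-dependent retention conserves cell number; moment is the
  # rho(x)-weighted loss moment (brute-force oracle)
  rule <- dediff_rule("state_dependent",
                      rho_fun = function(x) 0.9 - 0.4 * x / 2)
  s4 <- dedifferentiation_sources(W, 0.7, rule, g)
  loss <- 0.7 * W
  expect_equal(sum(s4$source_P), sum(loss), tolerance = 1e-12)
  rho_x <- 0.9 - 0.4 * g$x / 2
  expect_equal(g$dx * sum(g$x * s4$source_P),
               g$dx * sum(rho_x * g$x * loss), tolerance = 1e-12)
  expect_error(dedifferentiation_sources(W, -1, dediff_rule("constant"), g),
               ">= 0")
})

test_that("dedifferentiation variants coincide in their degenerate limits", {
  g <- make_grid(2, 300)
  W <- random_density(g, 8)
  ref <- dedifferentiation_sources(W, 0.3, dediff_rule("constant"), g)
  thr0 <- dedifferentiation_sources(W, 0.3, dediff_rule("threshold", xc = 0),
                                    g)
  rho1 <- dedifferentiation_sources(W, 0.3,
                                    dediff_rule("partial_repair", rho = 1), g)
  expect_equal(thr0$source_P, ref$source_P)
  expect_equal(rho1$source_P, ref$source_P)
  expect_equal(thr0$source_W, ref$source_W)
  expect_equal(rho1$source_W, ref$source_W)
})
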