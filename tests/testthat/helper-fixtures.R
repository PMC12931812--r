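# Shared fixtures: parameter sets and deterministic pseudo-random
# densities used across the unit tests.

conservation_params <- function(drift = 0) {
  model_params(
    vP = drift, vW = drift,
    feedback = feedback_params(0.5, 0.5, lambdaP_hat = 1, lambdaR_hat = 0),
    death = death_model("constant", 0),
    dediff = dediff_rule("constant")
  )
}

baseline_params <- function() {
  model_params(
    vP = 0.2, vW = 0.2,
    feedback = feedback_params(0.5, 0.5, lambdaP_hat = 1, lambdaR_hat = 0),
    death = death_model("constant", 0.5),
    dediff = dediff_rule("constant")
  )
}

# nonnegative pseudo-random density on a grid, reproducible
random_density <- function(grid, seed = 1) {
  set.seed(seed)
  u <- stats::runif(grid$N + 1L)^2
  u[1L] <- 0                       # boundary node empty, like all model ICs
  u
}
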