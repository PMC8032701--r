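# Shared fixtures: small configurations, hand-built parameter sets, and
# random valid draws used across the test files.

tiny_config <- function(M = 2L, D_max = 3L, q = 1L, p = 1L,
                        family = "weibull") {
  model_config(M = M, D_max = D_max, duration_family = family, q = q, p = p)
}

# Any real vector maps to a valid parameter set; random draws through the
# unconstrained map therefore give arbitrary valid parameters.
random_params <- function(config, sd = 0.5) {
  from_unconstrained(rnorm(actihsmm:::param_layout(config)$length, sd = sd), config)
}

random_series <- function(config, T, lam = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  activity_series(
    "test", rpois(T, lam),
    x = if (config$q > 0) matrix(rbinom(T * config$q, 1, 0.5), T) else NULL,
    z = if (config$p > 0) matrix(rbinom(T * config$p, 1, 0.5), T) else NULL)
}

# Two-state truth with well-separated intensities, used by the recovery and
# simulation tests (q = 0, p = 0: no covariates).
twostate_params <- function(b0 = log(c(1, 5)), b00 = 0,
                            shape = c(1.2, 1.2), scale = c(4, 2.5)) {
  subject_parameters(
    delta = c(0.5, 0.5),
    emission = emission_coefficients(
      b00 = b00, b10 = numeric(0), gamma0 = numeric(0),
      b0 = b0, b1 = matrix(0, 2, 0), gamma = matrix(0, 2, 0)),
    duration = duration_model(shape = shape, scale = scale,
                              c = matrix(0, 2, 0), eta = matrix(0, 2, 0)),
    transition = transition_coefficients(array(0, c(2, 2, 0)),
                                         array(0, c(2, 2, 0))))
}

twostate_config <- function(D_max = 12L)
  model_config(M = 2, D_max = D_max, q = 0, p = 0)

constant_schedule <- function(T, q = 0L, p = 0L)
  list(x = matrix(0, T, q), z = matrix(0, T, p))
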