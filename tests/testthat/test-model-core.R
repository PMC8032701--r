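# Component distributions, constraints, and the unconstrained
# reparameterization.

test_that("zip_log_pmf matches its closed forms and rejects bad input", {
  # degenerate point mass at zero
  expect_identical(zip_log_pmf(0, 1, 5), 0)
  # p_zero = 0 reduces to plain Poisson
  expect_equal(zip_log_pmf(3, 0, 2), log(2^3 * exp(-2) / factorial(3)),
               tolerance = 1e-12)
  expect_equal(zip_log_pmf(3, 0, 2), -1.71231792754822, tolerance = 1e-10)
  # mixture value (arbitrary-precision closed form)
  expect_equal(zip_log_pmf(0, 0.5, 1), log(0.5 + 0.5 * exp(-1)),
               tolerance = 1e-12)
  expect_equal(zip_log_pmf(0, 0.5, 1), -0.37988549304172, tolerance = 1e-10)

  expect_error(zip_log_pmf(-1, 0.5, 1), "nonnegative integer")
  expect_error(zip_log_pmf(1.5, 0.5, 1), "nonnegative integer")
  expect_error(zip_log_pmf(1, 1.5, 1), "\\[0, 1\\]")
  expect_error(zip_log_pmf(2, 0.5, 0), "y = 0")
})

test_that("zip_log_pmf with p_zero = 0 equals the Poisson log-pmf on 0..50", {
  y <- 0:50
  expect_equal(zip_log_pmf(y, 0, 3.7), dpois(y, 3.7, log = TRUE),
               tolerance = 1e-12)
})

test_that("expected count under the state-1 emission is (1 - p_zero) * lambda", {
  set.seed(99)
  n <- 1e6
  p0 <- 0.6; lam <- 2.5
  draws <- ifelse(runif(n) < p0, 0L, rpois(n, lam))
  mc_se <- sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws) - (1 - p0) * lam), 4 * mc_se)
})

test_that("emission_params evaluates the link models", {
  # all-zero coefficients, state 1
  coef0 <- emission_coefficients(0, 0, 0, c(0, 1), matrix(0, 2, 1),
                                 matrix(0, 2, 1))
  ep <- emission_params(1, 0, 0, coef0)
  expect_equal(ep$p_zero, 0.5)
  expect_equal(ep$lam, 1)
  # zero inflation confined to state 1
  expect_identical(emission_params(2, 1, 1, coef0)$p_zero, 0)
  # log-link evaluation with a reported-scale coefficient
  coef4 <- emission_coefficients(
    0, 0, numeric(0), b0 = c(log(2) - 3, log(2) - 2, log(2) - 1, log(2)),
    b1 = matrix(0.0914, 4, 1), gamma = matrix(0, 4, 0))
  ep4 <- emission_params(4, x = 1, z = numeric(0), coef4)
  expect_equal(ep4$lam, 2 * exp(0.0914), tolerance = 1e-12)
  expect_equal(ep4$lam, 2.19141440098755, tolerance = 1e-10)
  expect_identical(ep4$p_zero, 0)

  expect_error(emission_params(5, 1, numeric(0), coef4), "out of range")
  expect_error(emission_params(1, c(1, 1), numeric(0), coef4), "dimension")
})

test_that("transition_row is a proper softmax over allowed destinations", {
  # symmetric case
  tc3 <- transition_coefficients(array(0, c(3, 3, 1)), array(0, c(3, 3, 1)))
  expect_equal(transition_row(2, 0, 0, tc3), c(0.5, 0, 0.5))
  # M = 2: single allowed destination regardless of coefficients
  tc2 <- transition_coefficients(array(rnorm(4 * 1), c(2, 2, 1)),
                                 array(0, c(2, 2, 0)))
  expect_equal(transition_row(1, 1, numeric(0), tc2), c(0, 1))
  # hand-computed softmax: logits (0, log 2) over destinations {1, 3}
  d3 <- array(0, c(3, 3, 1)); d3[2, 3, 1] <- log(2)
  tcl <- transition_coefficients(d3, array(0, c(3, 3, 0)))
  expect_equal(transition_row(2, 1, numeric(0), tcl), c(1/3, 0, 2/3),
               tolerance = 1e-12)
  # M = 1 has no transitions
  tc1 <- transition_coefficients(array(0, c(1, 1, 1)), array(0, c(1, 1, 1)))
  expect_error(transition_row(1, 0, 0, tc1), "M >= 2")
})

test_that("transition rows have a zero diagonal and sum to one", {
  set.seed(42)
  for (i in 1:1000) {
    M <- sample(2:5, 1)
    tc <- transition_coefficients(array(rnorm(M * M), c(M, M, 1)),
                                  array(rnorm(M * M), c(M, M, 1)))
    m <- sample(M, 1)
    row <- transition_row(m, rnorm(1), rnorm(1), tc)
    expect_identical(row[m], 0)
    expect_lt(abs(sum(row) - 1), 1e-12)
  }
})

test_that("duration_pmf matches the exponential closed form", {
  # Weibull with shape 1, scale 1 is the standard exponential; with a = 1
  # and a large support the normalized pmf is (1 - e^-1) e^-(v-1)
  cfg <- model_config(M = 1, D_max = 200, q = 0, p = 0)
  dm <- duration_model(1, 1, matrix(0, 1, 0), matrix(0, 1, 0))
  dp <- duration_pmf(1, numeric(0), numeric(0), dm, cfg)
  expect_equal(dp$pmf[1], 1 - exp(-1), tolerance = 1e-8)
  expect_equal(dp$pmf[2], (1 - exp(-1)) * exp(-1), tolerance = 1e-8)
  expect_equal(dp$pmf[1], 0.632120558828558, tolerance = 1e-8)
  expect_equal(dp$pmf[2], 0.232544157934830, tolerance = 1e-8)
})

test_that("duration pmf normalizes, its survivor starts at 1, and
           acceleration shortens dwells", {
  set.seed(7)
  cfg <- model_config(M = 2, D_max = 40, q = 1, p = 0)
  for (i in 1:50) {
    dm <- duration_model(shape = exp(rnorm(2, 0, 0.4)),
                         scale = exp(rnorm(2, 1, 0.5)),
                         c = matrix(rnorm(2, 0, 0.3), 2, 1),
                         eta = matrix(0, 2, 0))
    dp <- duration_pmf(sample(2, 1), rbinom(1, 1, 0.5), numeric(0), dm, cfg)
    expect_lt(abs(sum(dp$pmf) - 1), 1e-10)
    expect_equal(dp$survivor[1], 1)
    expect_true(all(diff(dp$survivor) <= 1e-12))
  }
  # AFT property: doubling the acceleration shrinks the mean dwell
  dm <- duration_model(1.3, 6, matrix(log(2), 1, 1), matrix(0, 1, 0))
  cfg1 <- model_config(M = 1, D_max = 60, q = 1, p = 0)
  m_base <- sum(seq_len(60) * duration_pmf(1, 0, numeric(0), dm, cfg1)$pmf)
  m_fast <- sum(seq_len(60) * duration_pmf(1, 1, numeric(0), dm, cfg1)$pmf)
  expect_lt(m_fast, m_base)
  # degenerate support errors
  dm_bad <- duration_model(1, 1e-6, matrix(0, 1, 0), matrix(0, 1, 0))
  expect_error(duration_pmf(1, numeric(0), numeric(0), dm_bad, cfg1),
               "degenerate")
  dm_neg <- duration_model(-1, 1, matrix(0, 1, 0), matrix(0, 1, 0))
  expect_error(duration_pmf(1, numeric(0), numeric(0), dm_neg, cfg1),
               "positive")
})

test_that("intensities are strictly ordered across states whenever the
           emission invariants hold", {
  set.seed(11)
  cfg <- tiny_config(M = 4, q = 2, p = 2)
  for (i in 1:200) {
    th <- random_params(cfg, sd = 0.8)
    x <- rbinom(2, 1, 0.5); z <- rbinom(2, 1, 0.5)
    lams <- vapply(1:4, function(m)
      emission_params(m, x, z, th$emission)$lam, 0)
    expect_true(all(diff(lams) > 0))
  }
})

test_that("unconstrained round trip is the identity on valid parameters", {
  set.seed(23)
  for (i in 1:100) {
    cfg <- tiny_config(M = sample(1:4, 1), q = sample(0:2, 1),
                       p = sample(0:2, 1))
    u <- rnorm(actihsmm:::param_layout(cfg)$length)
    th <- from_unconstrained(u, cfg)
    expect_equal(nrow(validate_parameters(th, cfg)), 0L)
    th2 <- from_unconstrained(to_unconstrained(th, cfg), cfg)
    expect_equal(th2, th, tolerance = 1e-10)
  }
  # zero vector maps to a valid default
  cfg <- tiny_config(M = 3)
  expect_equal(nrow(validate_parameters(default_parameters(cfg), cfg)), 0L)
  # extreme intercept increments still keep the strict ordering
  cfg2 <- tiny_config(M = 3, q = 0, p = 0)
  u <- rep(0, actihsmm:::param_layout(cfg2)$length)
  u[actihsmm:::param_layout(cfg2)$idx$b0] <- c(0, -50, -50)
  th <- from_unconstrained(u, cfg2)
  expect_true(all(diff(th$emission$b0) > 0))
  expect_equal(nrow(validate_parameters(th, cfg2)), 0L)
  # wrong length errors
  expect_error(from_unconstrained(u[-1], cfg2), "length")
})

test_that("validate_parameters reports each violated invariant by code", {
  cfg <- model_config(M = 2, D_max = 5, q = 0, p = 0)
  ok <- default_parameters(cfg)
  expect_equal(nrow(validate_parameters(ok, cfg)), 0L)

  bad <- ok; bad$emission$b0 <- c(1.0, 0.5)
  v <- validate_parameters(bad, cfg)
  expect_true("b0_order" %in% v$code)

  bad <- ok; bad$delta <- c(0.6, 0.6)
  expect_true("delta_simplex" %in% validate_parameters(bad, cfg)$code)

  bad <- ok; bad$duration$shape <- c(-1, 1)
  expect_true("shape_pos" %in% validate_parameters(bad, cfg)$code)

  bad <- ok; bad$delta <- c(0.2, 0.2, 0.6)
  expect_true("delta_dim" %in% validate_parameters(bad, cfg)$code)
})
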