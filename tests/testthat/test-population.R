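# Second-stage least squares, sandwich covariance, Wald tests, and the
# effect table.

make_fake_fit <- function(id, b1, b10 = 0.05, converged = TRUE, M = 2) {
  cfg <- model_config(M = M, D_max = 10, q = 1, p = 0)
  th <- default_parameters(cfg)
  th$emission$b1 <- matrix(cummax(b1), M, 1)
  th$emission$b10 <- b10
  th$duration$c <- matrix(seq(0.01, by = 0.01, length.out = M), M, 1)
  structure(list(subject_id = id, params_hat = th, loglik = -1, n_params = 5,
                 bic = 10, converged = converged, M = M, T = 100,
                 config = cfg),
            class = "subject_fit")
}

test_that("stack_subject_estimates reshapes and reports exclusions", {
  fits <- list(make_fake_fit("a", c(0.1, 0.2)), make_fake_fit("b", c(0.3, 0.4)))
  est <- stack_subject_estimates(fits, "emission")
  expect_identical(dim(est), c(2L, 2L))
  expect_equal(est["a", ], c(state1 = 0.1, state2 = 0.2))
  # an unconverged subject is dropped and listed
  fits3 <- c(fits, list(make_fake_fit("c", c(0, 0.1), converged = FALSE)))
  est3 <- stack_subject_estimates(fits3, "emission")
  expect_identical(nrow(est3), 2L)
  expect_identical(attr(est3, "excluded"), "c")
  # other families
  expect_identical(colnames(stack_subject_estimates(fits, "zero")), "zero")
  expect_identical(ncol(stack_subject_estimates(fits, "duration")), 2L)
  # empty input and inconsistent M error
  expect_error(stack_subject_estimates(list()), "no subject fits")
  expect_error(stack_subject_estimates(
    list(make_fake_fit("a", c(0.1, 0.2)),
         make_fake_fit("b", c(0.1, 0.2, 0.3), M = 3))), "inconsistent")
})

test_that("intercept-only regression reduces to the mean with its HC0
           standard error", {
  e <- c(0.8, 1.1, 1.4, 0.9, 1.3)
  pop <- population_regress(matrix(e, ncol = 1))
  expect_equal(unname(pop$coefficients[1, 1]), mean(e), tolerance = 1e-12)
  expect_equal(unname(pop$se[1, 1]),
               sqrt(sum((e - mean(e))^2) / length(e)^2), tolerance = 1e-12)
})

test_that("exactly linear responses give a zero sandwich covariance", {
  W <- matrix(c(-1, 0, 1, 2), 4, 1)
  y <- 2 + 3 * W[, 1]
  pop <- population_regress(matrix(y, ncol = 1), baseline = W)
  expect_lt(max(abs(pop$vcov)), 1e-20)
})

test_that("three-subject toy matches the hand-computed sandwich", {
  W <- matrix(c(-1, 0, 1), 3, 1)
  y <- c(1, 2, 4)
  pop <- population_regress(matrix(y, ncol = 1), baseline = W, center = TRUE)
  expect_equal(unname(pop$coefficients[2, 1]), 1.5, tolerance = 1e-12)
  expect_equal(unname(pop$coefficients[1, 1]), 7 / 3, tolerance = 1e-12)
  # hand oracle: V = (X'X)^-1 X' diag(e^2) X (X'X)^-1 with X = [1, W]
  X <- cbind(1, W)
  e <- y - X %*% solve(crossprod(X), crossprod(X, y))
  V <- solve(crossprod(X)) %*% t(X) %*% diag(as.numeric(e)^2) %*% X %*%
    solve(crossprod(X))
  expect_equal(unname(pop$vcov[, , 1]), unname(V), tolerance = 1e-10)
})

test_that("sandwich equals the brute-force HC0 form on random small
           instances", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(5:10, 1); d <- sample(0:2, 1)
    W <- if (d > 0) matrix(rnorm(n * d), n, d) else NULL
    y <- rnorm(n)
    pop <- population_regress(matrix(y, ncol = 1), baseline = W,
                              center = FALSE)
    X <- matrix(1, n, 1)
    if (d > 0) X <- cbind(X, W)
    beta <- solve(crossprod(X), crossprod(X, y))
    e <- as.numeric(y - X %*% beta)
    V <- solve(crossprod(X)) %*% crossprod(X * e) %*% solve(crossprod(X))
    expect_equal(as.numeric(pop$vcov[, , 1]), as.numeric(V),
                 tolerance = 1e-10)
  }
})

test_that("centering baseline covariates changes only the intercept", {
  set.seed(3)
  W <- matrix(rnorm(20), 20, 1)
  y <- matrix(0.4 + 0.7 * W[, 1] + rnorm(20, sd = 0.3), ncol = 1)
  p1 <- population_regress(y, W, center = TRUE)
  p2 <- population_regress(y, W, center = FALSE)
  expect_equal(p1$coefficients[2, ], p2$coefficients[2, ], tolerance = 1e-12)
  expect_equal(p1$se[2, ], p2$se[2, ], tolerance = 1e-10)
  expect_false(isTRUE(all.equal(p1$coefficients[1, ], p2$coefficients[1, ])))
})

test_that("rank deficiency and tiny samples are rejected", {
  W <- matrix(c(1, 2, 3, 4, 2, 4, 6, 8), 4, 2)   # collinear columns
  expect_error(population_regress(matrix(rnorm(4), ncol = 1), W),
               "collinear")
  expect_error(population_regress(matrix(rnorm(2), ncol = 1),
                                  matrix(rnorm(2), 2, 1)), "at least")
})

test_that("wald_test reconstructs reported estimate/SE -> p triples", {
  # reference rows reconstruct to the printed precision (+- 0.0015)
  expect_lt(abs(wald_test(-0.0299, 0.0433)$p - 0.4899), 0.0015)
  expect_lt(abs(wald_test(0.0819, 0.0235)$p - 0.0005), 0.0015)
  expect_equal(wald_test(0, 1)$p, 1)
  expect_error(wald_test(1, 0), "positive")
})

test_that("effect_size_percent uses the linear convention by default", {
  expect_equal(effect_size_percent(0.0914), 9.14)
  expect_equal(effect_size_percent(0.0728), 7.28)
  expect_equal(effect_size_percent(0), 0)
  expect_equal(effect_size_percent(0.1, exponential = TRUE),
               100 * (exp(0.1) - 1))
})

test_that("effect_table emits one odds row plus one row per state with
           consistent Wald columns", {
  set.seed(8)
  n <- 12
  em <- matrix(rnorm(n * 6, mean = 0.05, sd = 0.02), n, 6,
               dimnames = list(NULL, paste0("state", 1:6)))
  ze <- matrix(rnorm(n, -0.03, 0.02), n, 1, dimnames = list(NULL, "zero"))
  tab <- effect_table(population_regress(em), population_regress(ze))
  expect_identical(nrow(tab), 7L)
  expect_identical(tab$parameter[1], "State 1: odds of zero")
  expect_identical(tab$parameter[7], "State 6: mean activity count")
  expect_equal(tab$z, tab$estimate / tab$se, tolerance = 1e-12)
  # zero mean estimates (with positive SEs) give p = 1
  em0 <- matrix(c(-1, 1, -1, 1) * 1e-6, 4, 2,
                dimnames = list(NULL, paste0("state", 1:2)))
  tab0 <- effect_table(population_regress(em0))
  expect_true(all(tab0$p > 0.999))
  # round trip through CSV and markdown
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".md")
  write_effect_table(tab, f1, "csv")
  expect_identical(nrow(read.csv(f1)), 7L)
  write_effect_table(tab, f2, "markdown")
  expect_identical(length(readLines(f2)), 9L)
  unlink(c(f1, f2))
})
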