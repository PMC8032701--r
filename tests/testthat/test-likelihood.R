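# Exact forward likelihood vs the exhaustive enumeration oracle, and the
# consistency of the compiled fit objective with the R-level pipeline.

test_that("forward likelihood equals brute-force enumeration on random
           small instances", {
  set.seed(1234)
  tested <- 0
  for (i in 1:120) {
    cfg <- tiny_config(M = sample(2:3, 1), D_max = sample(2:3, 1))
    th <- random_params(cfg, sd = 0.6)
    s <- random_series(cfg, sample(3:8, 1))
    f <- tryCatch(forward_log_likelihood(s, th, cfg), error = function(e) NULL)
    if (is.null(f)) next                       # degenerate duration draw
    b <- brute_force_log_likelihood(s, th, cfg)
    expect_lt(abs(f - b), 1e-8)
    expect_lte(f, 0)
    tested <- tested + 1
  }
  expect_gte(tested, 50)
})

test_that("M = 1 reduces the likelihood to the emission-only sum", {
  set.seed(5)
  cfg <- tiny_config(M = 1, q = 1, p = 1)
  th <- random_params(cfg)
  s <- random_series(cfg, 12)
  expected <- sum(vapply(seq_len(12), function(t) {
    ep <- emission_params(1, s$x[t, ], s$z[t, ], th$emission)
    zip_log_pmf(s$y[t], ep$p_zero, ep$lam)
  }, 0))
  expect_equal(forward_log_likelihood(s, th, cfg), expected,
               tolerance = 1e-10)
  expect_equal(brute_force_log_likelihood(s, th, cfg), expected,
               tolerance = 1e-10)
})

test_that("a single-minute series uses the censored single-dwell closed
           form", {
  set.seed(6)
  cfg <- tiny_config(M = 2, D_max = 3, q = 0, p = 0)
  th <- random_params(cfg)
  s <- activity_series("one", 2L)
  # S_m(1) = 1, so the likelihood is log sum_m delta_m P(y | m)
  ems <- vapply(1:2, function(m) {
    ep <- emission_params(m, numeric(0), numeric(0), th$emission)
    exp(zip_log_pmf(2, ep$p_zero, ep$lam))
  }, 0)
  expect_equal(brute_force_log_likelihood(s, th, cfg),
               log(sum(th$delta * ems)), tolerance = 1e-10)
  expect_equal(forward_log_likelihood(s, th, cfg),
               log(sum(th$delta * ems)), tolerance = 1e-10)
})

test_that("brute force refuses long series and invalid parameters error", {
  cfg <- tiny_config()
  th <- default_parameters(cfg)
  s <- random_series(cfg, 13, seed = 2)
  expect_error(brute_force_log_likelihood(s, th, cfg), "T > 12")
  bad <- th; bad$emission$b0 <- rev(bad$emission$b0)
  s2 <- random_series(cfg, 5, seed = 3)
  expect_error(forward_log_likelihood(s2, bad, cfg), "invalid")
})

test_that("the compiled fit objective agrees with the R likelihood
           pipeline", {
  set.seed(77)
  for (fam in c("weibull", "gamma")) {
    cfg <- model_config(M = 3, D_max = 5, duration_family = fam, q = 1, p = 1)
    for (i in 1:10) {
      u <- rnorm(actihsmm:::param_layout(cfg)$length, sd = 0.4)
      th <- from_unconstrained(u, cfg)
      s <- random_series(cfg, 60)
      pat <- actihsmm:::covariate_patterns(s)
      nll <- actihsmm:::cpp_neg_loglik(u, s$y, lgamma(s$y + 1), pat$index - 1L,
                            pat$X, pat$Z, cfg$M, cfg$D_max,
                            match(fam, c("weibull", "gamma")) - 1L)
      fw <- tryCatch(forward_log_likelihood(s, th, cfg),
                     error = function(e) NULL)
      if (is.null(fw)) next
      expect_equal(nll, -fw, tolerance = 1e-8)
    }
  }
})

test_that("the analytic objective gradient matches central finite
           differences", {
  set.seed(88)
  for (spec in list(list(M = 2, q = 1, p = 0, fam = "weibull"),
                    list(M = 3, q = 1, p = 1, fam = "weibull"),
                    list(M = 2, q = 1, p = 1, fam = "gamma"))) {
    cfg <- model_config(M = spec$M, D_max = 5, duration_family = spec$fam,
                        q = spec$q, p = spec$p)
    L <- actihsmm:::param_layout(cfg)$length
    famc <- match(spec$fam, c("weibull", "gamma")) - 1L
    for (i in 1:4) {
      u <- rnorm(L, sd = 0.3)
      s <- random_series(cfg, 150)
      pat <- actihsmm:::covariate_patterns(s)
      lgy <- lgamma(s$y + 1)
      g <- actihsmm:::cpp_neg_loglik_grad(u, s$y, lgy, pat$index - 1L, pat$X, pat$Z,
                               cfg$M, cfg$D_max, famc)
      if (g$value >= 1e9) next
      h <- 1e-4                                # steep coords need a wide step
      fd <- vapply(seq_len(L), function(j) {
        e <- numeric(L); e[j] <- h
        (actihsmm:::cpp_neg_loglik(u + e, s$y, lgy, pat$index - 1L, pat$X, pat$Z,
                        cfg$M, cfg$D_max, famc) -
         actihsmm:::cpp_neg_loglik(u - e, s$y, lgy, pat$index - 1L, pat$X, pat$Z,
                        cfg$M, cfg$D_max, famc)) / (2 * h)
      }, 0)
      expect_lt(max(abs(g$gradient - fd) / pmax(1, abs(fd))), 1e-4)
    }
  }
})
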