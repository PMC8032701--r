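# Study designs, covariate schedules, the subject-level generator, and the
# hierarchical study simulator.

test_that("crossover schedule places treatment, night, and weekend
           indicators deterministically", {
  des <- study_design(n_subjects = 2)
  schA <- make_crossover_schedule(des, "A")
  schB <- make_crossover_schedule(des, "B")
  Tn <- des$total_minutes
  expect_identical(Tn, as.integer(11 * 7 * 1440))
  wk <- 7 * 1440
  # sequence A: active exactly during weeks 3-5; B: weeks 9-11
  expect_identical(which(schA$x[, 1] == 1), (2 * wk + 1):(5 * wk))
  expect_identical(which(schB$x[, 1] == 1), (8 * wk + 1):(11 * wk))
  # night window 18:00-06:00
  mod <- schA$minute_of_day
  expect_identical(schA$z[, "night"], as.numeric(mod >= 1080 | mod < 360))
  # weekend: exactly 2/7 of whole weeks
  expect_identical(sum(schA$z[, "weekend"]), 2 / 7 * Tn)
  expect_identical(schA$z[, "weekend"][1], 0)       # day 1 is a Monday
  expect_error(make_crossover_schedule(des, "C"))
  # z_vars subsetting
  sch0 <- make_crossover_schedule(des, "A", z_vars = character(0))
  expect_identical(ncol(sch0$z), 0L)
})

test_that("simulated Poisson counts have the configured mean", {
  cfg <- model_config(M = 1, D_max = 10, q = 0, p = 0)
  th <- subject_parameters(
    delta = 1,
    emission = emission_coefficients(-20, numeric(0), numeric(0), log(3),
                                     matrix(0, 1, 0), matrix(0, 1, 0)),
    duration = duration_model(1, 3, matrix(0, 1, 0), matrix(0, 1, 0)),
    transition = transition_coefficients(array(0, c(1, 1, 0)),
                                         array(0, c(1, 1, 0))))
  sim <- simulate_subject(th, constant_schedule(100000), cfg, seed = 2)
  mc_se <- sd(sim$series$y) / sqrt(100000)
  expect_lt(abs(mean(sim$series$y) - 3), 4 * mc_se)
})

test_that("generated dwell lengths follow the configured duration pmf", {
  cfg <- twostate_config(D_max = 15)
  th <- twostate_params(b0 = log(c(0.5, 6)), scale = c(4, 2.5))
  sim <- simulate_subject(th, constant_schedule(200000), cfg, seed = 42)
  # completed dwells of state 1 from the generating path
  r <- rle(sim$path)
  d1 <- r$lengths[r$values == 1]
  d1 <- d1[-length(d1)]                      # final dwell may be truncated
  pmf <- duration_pmf(1, numeric(0), numeric(0), th$duration, cfg)$pmf
  obs <- tabulate(d1, nbins = 15)
  keep <- pmf * length(d1) >= 5
  chi <- suppressWarnings(chisq.test(obs[keep], p = pmf[keep] / sum(pmf[keep])))
  expect_gt(chi$p.value, 0.001)
})

test_that("the same seed reproduces a simulation exactly", {
  cfg <- twostate_config()
  th <- twostate_params()
  s1 <- simulate_subject(th, constant_schedule(2000), cfg, seed = 5)
  s2 <- simulate_subject(th, constant_schedule(2000), cfg, seed = 5)
  expect_identical(s1$series$y, s2$series$y)
  expect_identical(s1$path, s2$path)
})

test_that("decoded jump frequencies match the transition model", {
  cfg <- model_config(M = 3, D_max = 12, q = 0, p = 0)
  u <- rep(0, actihsmm:::param_layout(cfg)$length)
  th <- from_unconstrained(u, cfg)
  th$emission$b0 <- log(c(0.3, 5, 40))
  sim <- simulate_subject(th, constant_schedule(150000), cfg, seed = 8)
  r <- rle(sim$path)
  from <- head(r$values, -1); to <- r$values[-1]
  for (m in 1:3) {
    emp <- tabulate(to[from == m], nbins = 3) / sum(from == m)
    model <- transition_row(m, numeric(0), numeric(0), th$transition)
    expect_lt(sum(abs(emp - model)) / 2, 0.05)     # total-variation distance
  }
})

test_that("zero fraction rises monotonely with the zero-inflation
           intercept", {
  cfg <- twostate_config()
  zf <- vapply(c(-1, 0, 1, 2), function(b00) {
    th <- twostate_params(b0 = log(c(0.4, 5)), b00 = b00)
    mean(simulate_subject(th, constant_schedule(20000), cfg,
                          seed = 3)$series$y == 0)
  }, 0)
  expect_true(all(diff(zf) > 0))
})

test_that("simulate_study with zero noise and zero slopes replicates the
           template subject", {
  cfg <- model_config(M = 2, D_max = 10, q = 1, p = 0, d = 1)
  base <- subject_parameters(
    delta = c(0.5, 0.5),
    emission = emission_coefficients(0, 0.05, numeric(0), log(c(0.5, 6)),
                                     matrix(c(0.05, 0.1), 2, 1),
                                     matrix(0, 2, 0)),
    duration = duration_model(c(1.2, 1.2), c(4, 3), matrix(0, 2, 1),
                              matrix(0, 2, 0)),
    transition = transition_coefficients(array(0, c(2, 2, 1)),
                                         array(0, c(2, 2, 0))))
  truth <- simulation_truth(base, cfg,
                            noise_sd = list(emission = 0, duration = 0,
                                            zero = 0, other = 0))
  des <- study_design(n_subjects = 3, phase_minutes = c(0, 300, 0, 300))
  study <- simulate_study(truth, des, seed = 11, z_vars = character(0))
  for (ps in study$subject_params)
    expect_equal(ps$emission, base$emission, tolerance = 1e-12)
  # master-seed reproducibility
  study2 <- simulate_study(truth, des, seed = 11, z_vars = character(0))
  expect_identical(lapply(study$activity, `[[`, "y"),
                   lapply(study2$activity, `[[`, "y"))
  # realized treatment effects are returned aligned with subjects
  expect_identical(dim(study$subject_b1), c(3L, 2L))
})

test_that("an overtight noise scale triggers the constraint projection
           error", {
  cfg <- model_config(M = 2, D_max = 10, q = 1, p = 0, d = 0)
  base <- subject_parameters(
    delta = c(0.5, 0.5),
    emission = emission_coefficients(0, 0, numeric(0), log(c(0.5, 6)),
                                     matrix(c(0.05, 0.06), 2, 1),
                                     matrix(0, 2, 0)),
    duration = duration_model(c(1.2, 1.2), c(4, 3), matrix(0, 2, 1),
                              matrix(0, 2, 0)),
    transition = transition_coefficients(array(0, c(2, 2, 1)),
                                         array(0, c(2, 2, 0))))
  truth <- simulation_truth(base, cfg,
                            noise_sd = list(emission = 0.5))
  des <- study_design(n_subjects = 2, phase_minutes = c(0, 100, 0, 100))
  expect_error(simulate_study(truth, des, seed = 1, z_vars = character(0)),
               "projection failure")
})
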