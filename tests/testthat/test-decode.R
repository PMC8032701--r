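# Viterbi decoding against the exhaustive-argmax oracle, occupancy tables,
# and the quantile fit check.

test_that("Viterbi equals the exhaustive argmax over all segmentations", {
  set.seed(4321)
  tested <- 0
  for (i in 1:80) {
    cfg <- tiny_config(M = sample(2:3, 1), D_max = sample(2:3, 1), p = 0)
    th <- random_params(cfg, sd = 0.5)
    s <- random_series(cfg, sample(4:8, 1))
    en <- tryCatch(actihsmm:::enumerate_paths(s, th, cfg),
                   error = function(e) NULL)
    if (is.null(en)) next
    vt <- viterbi_decode(s, th, cfg)
    best <- max(en$logp)
    expect_lt(abs(vt$logp - best), 1e-9)
    amax <- which(en$logp > best - 1e-9)
    hit <- any(apply(en$states[amax, , drop = FALSE], 1,
                     function(pp) all(pp == vt$states)))
    expect_true(hit)
    tested <- tested + 1
  }
  expect_gte(tested, 50)
})

test_that("Viterbi path probability never exceeds the total likelihood", {
  set.seed(99)
  for (i in 1:30) {
    cfg <- tiny_config(M = 3, D_max = 4)
    th <- random_params(cfg, sd = 0.4)
    s <- random_series(cfg, 30)
    f <- tryCatch(forward_log_likelihood(s, th, cfg), error = function(e) NULL)
    if (is.null(f)) next
    vt <- viterbi_decode(s, th, cfg)
    expect_lte(vt$logp, f + 1e-10)
  }
})

test_that("M = 1 decodes to a single censored segment", {
  cfg <- tiny_config(M = 1, q = 0, p = 0)
  th <- default_parameters(cfg)
  s <- activity_series("s", c(0L, 2L, 1L))
  vt <- viterbi_decode(s, th, cfg)
  expect_identical(vt$states, rep(1L, 3))
  expect_identical(nrow(vt$segments), 1L)
  expect_true(vt$segments$censored[1])
})

test_that("decoded segments partition the series and long series decode
           matches the generating path when states are far apart", {
  cfg <- twostate_config(D_max = 15)
  th <- twostate_params(b0 = log(c(0.1, 50)))
  sim <- simulate_subject(th, constant_schedule(4000), cfg, seed = 21)
  vt <- viterbi_decode(sim$series, th, cfg)
  expect_identical(sum(vt$segments$duration), 4000L)
  expect_identical(vt$segments$start,
                   cumsum(c(1L, head(vt$segments$duration, -1L))))
  expect_gte(mean(vt$states == sim$path), 0.95)
})

test_that("state occupancy averages percent time per condition", {
  # single path, one condition
  occ <- state_occupancy(list(c(1L, 1L, 2L)), list(rep("all", 3)))
  expect_equal(occ$all, c(200/3, 100/3), tolerance = 1e-10)
  expect_equal(sum(occ$all), 100, tolerance = 0.1)
  # two subjects with identical paths equal the single-subject table
  occ2 <- state_occupancy(list(c(1L, 1L, 2L), c(1L, 1L, 2L)),
                          list(rep("all", 3), rep("all", 3)))
  expect_equal(occ2$all, occ$all)
  # per-condition split
  occ3 <- state_occupancy(list(c(1L, 2L, 1L, 2L)),
                          list(c("a", "a", "b", "b")))
  expect_equal(occ3$a, c(50, 50))
  expect_equal(colSums(occ3[, c("a", "b")]), c(a = 100, b = 100),
               tolerance = 0.1)
  # empty factor level warns and is excluded
  expect_warning(
    occ4 <- state_occupancy(list(c(1L, 1L)),
                            list(factor(c("a", "a"), levels = c("a", "b")))),
    "no minutes")
  expect_false("b" %in% names(occ4))
})

test_that("quantile check is self-consistent on model-simulated data", {
  cfg <- twostate_config()
  th <- twostate_params(b0 = log(c(0.5, 6)), b00 = 0.5)
  sim <- simulate_subject(th, constant_schedule(20000), cfg, seed = 31)
  fit <- list(params_hat = th, converged = TRUE)
  qq <- model_quantile_check(fit, sim$series, cfg, quantile_grid = seq(5, 95, 5),
                             seed = 7, length_factor = 3)
  expect_lte(max(abs(qq$model - qq$observed)), 1)
  # all-zero data at the median
  s0 <- activity_series("z", rep(0L, 200))
  fit0 <- list(params_hat = twostate_params(b0 = log(c(0.2, 1)), b00 = 2),
               converged = TRUE)
  qq0 <- model_quantile_check(fit0, s0, cfg, quantile_grid = 50, seed = 1,
                              length_factor = 2)
  expect_identical(qq0$observed, 0)
  expect_identical(qq0$model, 0)
  # unconverged fits are refused
  expect_error(model_quantile_check(list(converged = FALSE), s0, cfg),
               "converged")
})

test_that("segment export uses half-open intervals", {
  cfg <- tiny_config(M = 1, q = 0, p = 0)
  th <- default_parameters(cfg)
  vt <- viterbi_decode(activity_series("s", c(0L, 1L, 0L)), th, cfg)
  seg <- export_segments(list(vt))
  expect_identical(seg$end - seg$start, 3L)
  path <- tempfile(fileext = ".csv")
  export_segments(list(vt), path)
  expect_identical(read.csv(path)$end, seg$end)
  unlink(path)
})
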