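params <- priorityParams(10, 100, "step")

test_that("priority parameters enforce 0 <= p_base <= p_crit", {
  expect_error(priorityParams(-1, 10), "p_base")
  expect_error(priorityParams(50, 10), "p_base")
  expect_silent(priorityParams(10, 10))
})

test_that("step priority follows its three branches", {
  # all demand-bearing positions hard-blocked -> no execution -> 0
  ev <- mkEval(4, affected = rep(TRUE, 4), hard = rep(TRUE, 4))
  expect_equal(priorityStep(ev, params)$value, 0)
  # no violation -> p_base
  ev <- mkCountEval(3, 4)
  expect_equal(priorityStep(ev, params)$value, 10)
  # soft violation -> p_crit
  ev <- mkCountEval(3, 4, soft_any = TRUE)
  expect_equal(priorityStep(ev, params)$value, 100)
  # nothing to do -> 0
  expect_equal(priorityStep(mkCountEval(0, 4), params)$value, 0)
})

test_that("step-specific priority scales with the affected share", {
  p <- priorityParams(10, 100, "step_specific")
  expect_equal(priorityStepSpecific(mkCountEval(24, 48), p)$value, 5.0)
  expect_equal(priorityStepSpecific(mkCountEval(0, 48), p)$value, 0)
  # full fleet under soft violation reaches exactly p_crit
  expect_equal(priorityStepSpecific(mkCountEval(48, 48, soft_any = TRUE),
                                    p)$value, 100)
  # no active reactors is a signal, not an error
  expect_equal(priorityStepSpecific(mkCountEval(0, 0), p)$value, 0)
})

test_that("dynamic volume priority is linear in span fractions", {
  p <- priorityParams(10, 100, "dynamic_volume")
  # n_all = 2, one affected position mid-span: 10 + (90/2) * 0.5 = 32.5
  ev <- mkCountEval(1, 2)
  out <- priorityDynamicVolume(ev, c(50, 0), c(25, 25), c(50, 50), p)
  expect_equal(out$value, 32.5)
  # all affected at the lower limit -> p_base
  ev <- mkCountEval(3, 3)
  expect_equal(priorityDynamicVolume(ev, rep(25, 3), rep(25, 3),
                                     rep(50, 3), p)$value, 10)
  # all active positions at the upper limit -> p_crit exactly
  expect_equal(priorityDynamicVolume(ev, rep(75, 3), rep(25, 3),
                                     rep(50, 3), p)$value, 100)
  # non-positive span is a configuration error
  expect_error(priorityDynamicVolume(ev, rep(30, 3), rep(25, 3),
                                     rep(0, 3), p), "positive")
})

test_that("dynamic time priority matches its hand-evaluated cases", {
  p <- priorityParams(10, 100, "dynamic_time")
  ev <- mkCountEval(48, 48)
  # all 48 positions mid-span: 10 + 90 * (48 * 0.5) / 48 = 55
  out <- priorityDynamicTime(ev, rep(1800, 48), rep(1500, 48),
                             rep(600, 48), p)
  expect_equal(out$value, 55.0)
  expect_length(out$per_reactor_terms, 48)
  # all at the lower limit -> p_base
  expect_equal(priorityDynamicTime(ev, rep(1500, 48), rep(1500, 48),
                                   rep(600, 48), p)$value, 10)
  # every position hard-blocked -> 0
  evh <- mkEval(48, rep(TRUE, 48), hard = rep(TRUE, 48))
  expect_equal(priorityDynamicTime(evh, rep(1800, 48), rep(1500, 48),
                                   rep(600, 48), p)$value, 0)
})

test_that("no algorithm ever exceeds the critical priority", {
  set.seed(11)
  for (rep in 1:200) {
    n_all <- sample(1:48, 1)
    n_aff <- sample(0:n_all, 1)
    p <- priorityParams(stats::runif(1, 0, 50), stats::runif(1, 50, 200),
                        "step")
    ev <- mkCountEval(n_aff, n_all, soft_any = stats::runif(1) > 0.5)
    vals <- c(
      priorityStep(ev, p)$value,
      priorityStepSpecific(ev, p)$value,
      priorityDynamicVolume(ev, stats::runif(n_all, 0, 400),
                            rep(10, n_all), rep(50, n_all), p)$value,
      priorityDynamicTime(ev, stats::runif(n_all, 0, 4000),
                          rep(1000, n_all), rep(500, n_all), p)$value
    )
    expect_true(all(vals >= 0 & vals <= p$p_crit))
  }
})

test_that("dynamic volume at the upper limit agrees with step-specific under soft violation", {
  set.seed(13)
  for (rep in 1:100) {
    n_all <- sample(1:48, 1)
    n_aff <- sample(1:n_all, 1)
    p <- priorityParams(10, 100, "dynamic_volume")
    ev <- mkCountEval(n_aff, n_all)
    at_upper <- priorityDynamicVolume(ev, rep(60, n_all), rep(10, n_all),
                                      rep(50, n_all), p)$value
    ss <- priorityStepSpecific(mkCountEval(n_aff, n_all, soft_any = TRUE),
                               p)$value
    expect_equal(at_upper, ss, tolerance = 1e-12)
  }
})

test_that("dynamic priorities are monotone in their driving quantity", {
  set.seed(17)
  p <- priorityParams(10, 100, "dynamic_time")
  ev <- mkCountEval(5, 8)
  lower <- rep(100, 8); delta <- rep(200, 8)
  t1 <- stats::runif(8, 100, 300)
  for (rep in 1:50) {
    bump <- stats::runif(8, 0, 50) * (stats::runif(8) > 0.5)
    v1 <- priorityDynamicTime(ev, t1, lower, delta, p)$value
    v2 <- priorityDynamicTime(ev, t1 + bump, lower, delta, p)$value
    expect_gte(v2, v1)
  }
  # step_specific monotone in n_aff at fixed n_all
  ps <- priorityParams(10, 100, "step_specific")
  vals <- vapply(0:8, function(k)
    priorityStepSpecific(mkCountEval(k, 8), ps)$value, numeric(1))
  expect_true(all(diff(vals) >= 0))
})
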