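test_that("constraint specs validate their fields", {
  cs <- constraintSpec("min_vol", "hard", "volume", "lower", 10)
  expect_s3_class(cs, "constraintSpec")
  expect_error(constraintSpec("bad", "hard", "volume", "lower", -1),
               "non-negative")
  expect_error(constraintSpec("bad", "hard", "volume", "lower", Inf),
               "finite")
  expect_error(taskSpec("t", "feeding",
                        demand = demandModel("constant_volume", volume = 50),
                        constraints = list(
                          constraintSpec("lo", "hard", "volume", "lower", 100),
                          constraintSpec("hi", "hard", "volume", "upper", 10))),
               "exceeds its upper bound")
})

test_that("hard violations block, soft violations carry their extent", {
  n <- 3
  reactors <- reactorStates(n)
  state <- newTaskState(taskSpec(
    "feed", "feeding",
    demand = demandModel("constant_volume", volume = 50,
                         plant_effect = "feed"),
    constraints = list(
      constraintSpec("min_vol", "hard", "volume", "lower", 10),
      constraintSpec("max_gap", "soft", "elapsed_time", "upper", 1200)
    )), n)

  # below the minimum pipettable volume: hard violation, never affected
  ev <- evaluateConstraints(state, reactors, now = 100,
                            demand = c(0.2, 50, 50))
  expect_true(ev$hard_violated[1])
  expect_false(ev$affected[1])
  expect_true(all(ev$affected[2:3]))

  # 1500 s since last feed against a 1200 s soft ceiling: extent 300 s
  ev <- evaluateConstraints(state, reactors, now = 1500,
                            demand = rep(50, n))
  expect_true(all(ev$soft_violated))
  expect_equal(ev$violation_extent, rep(300, n))

  # strictly interior: nothing violated, all demand-bearing affected
  state$last_execution <- rep(500, n)
  ev <- evaluateConstraints(state, reactors, now = 1500,
                            demand = c(50, 50, 0))
  expect_false(any(ev$hard_violated) || any(ev$soft_violated))
  expect_equal(ev$n_aff, 2L)
})

test_that("zero-demand and inactive reactors are non-violating and unaffected", {
  n <- 4
  reactors <- reactorStates(n)
  reactors$active[4] <- FALSE
  state <- newTaskState(taskSpec(
    "feed", "feeding",
    demand = demandModel("constant_volume", volume = 50),
    constraints = list(constraintSpec("min_vol", "hard", "volume", "lower", 10))
  ), n)
  ev <- evaluateConstraints(state, reactors, now = 10,
                            demand = c(50, 0, 50, 50))
  expect_equal(ev$affected, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(ev$n_all, 3L)
  expect_false(any(ev$hard_violated[c(2, 4)]))

  # empty active set: all-false vectors, a signal rather than a failure
  reactors$active[] <- FALSE
  ev <- evaluateConstraints(state, reactors, now = 10, demand = rep(50, n))
  expect_equal(ev$n_aff, 0L)
  expect_equal(ev$n_all, 0L)
  expect_false(any(ev$affected))
})

test_that("evaluation invariants hold over random instances", {
  set.seed(42)
  state0 <- newTaskState(taskSpec(
    "feed", "feeding",
    demand = demandModel("constant_volume", volume = 50),
    constraints = list(
      constraintSpec("min_vol", "hard", "volume", "lower", 10),
      constraintSpec("soft_hi", "soft", "volume", "upper", 80)
    )), 12)
  for (rep in 1:50) {
    reactors <- reactorStates(12)
    reactors$active <- stats::runif(12) > 0.2
    demand <- stats::runif(12, 0, 120) * (stats::runif(12) > 0.3)
    ev <- evaluateConstraints(state0, reactors, now = 100, demand = demand)
    expect_lte(ev$n_aff, ev$n_all)
    expect_false(any(ev$hard_violated & ev$affected))
    expect_true(all(ev$violation_extent >= 0))
    # purity: identical inputs, identical output
    expect_identical(ev, evaluateConstraints(state0, reactors, now = 100,
                                             demand = demand))
  }
})

test_that("tightening a soft limit never decreases the violation count", {
  set.seed(7)
  mkState <- function(limit) newTaskState(taskSpec(
    "feed", "feeding",
    demand = demandModel("constant_volume", volume = 50),
    constraints = list(constraintSpec("soft_hi", "soft", "volume", "upper",
                                      limit))), 20)
  reactors <- reactorStates(20)
  for (rep in 1:25) {
    demand <- stats::runif(20, 0, 150)
    lims <- sort(stats::runif(2, 10, 140), decreasing = TRUE)
    loose <- evaluateConstraints(mkState(lims[1]), reactors, 0, demand)
    tight <- evaluateConstraints(mkState(lims[2]), reactors, 0, demand)
    expect_gte(sum(tight$soft_violated), sum(loose$soft_violated))
  }
})

test_that("unknown constraint quantity is a configuration error", {
  state <- newTaskState(taskSpec(
    "feed", "feeding", demand = demandModel("constant_volume", volume = 50)), 2)
  state$spec$constraints <- list(list(name = "x", kind = "hard",
                                      quantity = "mass", bound = "lower",
                                      limit = 1, applies_to = "all"))
  expect_error(evaluateConstraints(state, reactorStates(2), 0,
                                   demand = c(1, 1)),
               "unknown constraint quantity")
})
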