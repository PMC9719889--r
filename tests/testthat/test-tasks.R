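test_that("titration demand is one-sided with a deadband", {
  state <- mkTitrationTask(n = 3, gain = 50)
  reactors <- reactorStates(3, pH = c(7.00, 6.5, 7.4))
  d <- computeDemand(state, reactors, now = 0)
  expect_equal(d[1], 0)            # inside the deadband
  expect_equal(d[2], 20)           # 50 * (7.0 - 0.1 - 6.5)
  expect_equal(d[3], 0)            # above setpoint: base cannot lower pH
})

test_that("feed demand follows the exponential profile and ignores pH", {
  spec <- taskSpec("feed", "feeding",
                   demand = demandModel("exponential_feed", base_volume = 60,
                                        mu_set = 0.2, plant_effect = "feed"))
  state <- newTaskState(spec, 2)
  d0 <- computeDemand(state, reactorStates(2, pH = c(5, 9)), now = 0)
  expect_equal(d0, rep(60, 2))
  d1 <- computeDemand(state, reactorStates(2), now = 3600)
  expect_equal(d1, rep(60 * exp(0.2), 2))
  # clamped to the channel maximum when a profile is supplied
  d2 <- computeDemand(state, reactorStates(2), now = 100 * 3600,
                      profile = lhsProfile())
  expect_equal(d2, rep(1000, 2))
})

test_that("sampling stages are gated by their predecessor per reactor", {
  n <- 3
  s1 <- newTaskState(taskSpec("stage1", "sampling_stage", stage_index = 1,
                              demand = demandModel("time_trigger")), n)
  s2 <- newTaskState(taskSpec("stage2", "sampling_stage", stage_index = 2,
                              predecessor = "stage1",
                              demand = demandModel("time_trigger")), n)
  tasks <- list(stage1 = s1, stage2 = s2)
  reactors <- reactorStates(n)
  expect_equal(computeDemand(s2, reactors, 100, tasks), rep(0, n))

  # stage 1 completes on reactors 1 and 3 only
  rec <- structure(list(command = NULL, start_time = 50, end_time = 90,
                        serviced_reactors = c(1L, 3L),
                        delivered_volumes = c(500, 500),
                        validation_findings = character(0)),
                   class = "executionRecord")
  tasks$stage1 <- onExecutionComplete(s1, rec)
  expect_equal(computeDemand(s2, reactors, 100, tasks), c(1, 0, 1))
  expect_error(computeDemand(s2, reactors, 100, tasks = list()),
               "not in registry")
})

test_that("stale sensor values suppress sensor-driven demand with a warning", {
  state <- mkTitrationTask(n = 2)
  reactors <- reactorStates(2, pH = 6.5)
  expect_equal(computeDemand(state, reactors, 1000, sensor_age = 60),
               rep(20, 2))   # 50 * (7.0 - 0.1 - 6.5)
  expect_warning(d <- computeDemand(state, reactors, 1000, sensor_age = 400),
                 "sensor values")
  expect_equal(d, rep(0, 2))
  # feed demand is not sensor-driven and is unaffected by staleness
  feed <- newTaskState(taskSpec("feed", "feeding",
    demand = demandModel("constant_volume", volume = 50)), 2)
  expect_equal(computeDemand(feed, reactors, 1000, sensor_age = 400),
               rep(50, 2))
})

test_that("reportPriority chains demand, constraints and the algorithm", {
  state <- mkTitrationTask(n = 4)
  reactors <- reactorStates(4, pH = 6.5)   # demand 60*(6.9-6.5) = 24 uL
  state <- reportPriority(state, reactors, now = 100)
  p1 <- state$current_priority$value
  expect_gt(p1, 0)
  expect_equal(state$current_eval$n_aff, 4L)

  # pH recovering towards the setpoint lowers the reported priority
  reactors$pH <- rep(6.7, 4)
  state2 <- reportPriority(state, reactors, now = 200)
  expect_lt(state2$current_priority$value, p1)

  # an executing task retains its last report (non-preemptive contract)
  state2$status <- "executing"
  reactors$pH <- rep(5.5, 4)
  state3 <- reportPriority(state2, reactors, now = 300)
  expect_identical(state3$current_priority, state2$current_priority)

  # all positions hard-blocked (demand below minimum volume) -> priority 0
  reactors$pH <- rep(6.88, 4)  # demand 1.2 uL < 5 uL minimum
  state4 <- reportPriority(state, reactors, now = 400)
  expect_equal(state4$current_priority$value, 0)
})

test_that("completion updates only serviced reactors", {
  state <- mkTitrationTask(n = 5)
  state$status <- "executing"
  rec <- structure(list(command = NULL, start_time = 100, end_time = 160,
                        serviced_reactors = c(2L, 4L),
                        delivered_volumes = c(12, 20),
                        validation_findings = character(0)),
                   class = "executionRecord")
  out <- onExecutionComplete(state, rec)
  expect_equal(out$last_execution, c(0, 160, 0, 160, 0))
  expect_equal(out$exec_count, c(0L, 1L, 0L, 1L, 0L))
  expect_equal(out$status, "idle")
  rec$serviced_reactors <- 9L
  expect_error(onExecutionComplete(state, rec), "unknown reactor")
})

test_that("induction demands once per reactor inside its window", {
  ind <- newTaskState(inductionTask(3600, 5400), 2)
  reactors <- reactorStates(2)
  # before the window: demand exists but the clock-time hard bound blocks it
  ind <- reportPriority(ind, reactors, 1000)
  expect_equal(ind$current_priority$value, 0)
  ind <- reportPriority(ind, reactors, 4000)
  expect_gt(ind$current_priority$value, 0)
  # past the soft window end the task escalates to critical
  ind <- reportPriority(ind, reactors, 6000)
  expect_equal(ind$current_priority$value, ind$spec$priority$p_crit)
  # after execution the demand is gone
  rec <- structure(list(command = NULL, start_time = 6000, end_time = 6060,
                        serviced_reactors = 1:2,
                        delivered_volumes = c(50, 50),
                        validation_findings = character(0)),
                   class = "executionRecord")
  ind <- onExecutionComplete(ind, rec)
  ind <- reportPriority(ind, reactors, 6200)
  expect_equal(ind$current_priority$value, 0)
})
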