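test_that("initialization sizes the registry from the configuration", {
  cfg <- fedBatchConfig(n_reactors = 48, duration_h = 1)
  st <- initializeScheduler(cfg)
  expect_equal(st$phase, "run")
  expect_length(st$tasks, 7L)
  expect_equal(sum(st$reactors$active), 48L)

  cfg24 <- fedBatchConfig(n_reactors = 24, duration_h = 1)
  st24 <- initializeScheduler(cfg24)
  expect_length(st24$reactors$active, 24L)
  expect_length(st24$tasks$feed$last_execution, 24L)
})

test_that("the dispatcher picks the highest positive priority when idle", {
  # a tiny world with two competing constant-volume tasks
  mk <- function(name, p_base) taskSpec(
    name, "feeding",
    demand = demandModel("constant_volume", volume = 50,
                         plant_effect = "feed"),
    priority = priorityParams(p_base, 100, "step"),
    constraints = list(constraintSpec("min", "hard", "volume", "lower", 5)),
    source = "substrate", method_name = name)
  cfg <- experimentConfig(
    n_reactors = 4,
    lhs_profile = lhsProfile(deck_sequences = defaultDeck(4)),
    tasks = list(mk("high", 40), mk("low", 10)),
    plant = plantParams(q_glc_max = 0, noise_sd = c(pH = 0, DO = 0)),
    clock = list(tick = 10, duration = 600))
  set.seed(1)
  st <- initializeScheduler(cfg)
  st <- schedulerStep(st)
  expect_equal(st$executing$task, "high")

  # while the LHS is busy nothing else is dispatched regardless of priority
  busy_until <- st$executing$record$end_time
  st <- schedulerStep(st)
  expect_equal(st$executing$task, "high")
  expect_equal(st$executing$record$end_time, busy_until)
})

test_that("priority ties fall to the task serviced longest ago, then declaration order", {
  mk <- function(name) taskSpec(
    name, "feeding",
    demand = demandModel("constant_volume", volume = 50,
                         plant_effect = "feed"),
    priority = priorityParams(40, 100, "step"),
    source = "substrate", method_name = name)
  cfg <- experimentConfig(
    n_reactors = 2, lhs_profile = lhsProfile(deck_sequences = defaultDeck(2)),
    tasks = list(mk("a"), mk("b")),
    plant = plantParams(q_glc_max = 0, noise_sd = c(pH = 0, DO = 0)),
    clock = list(tick = 10, duration = 400))
  set.seed(1)
  st <- initializeScheduler(cfg)
  # equal priorities, equal (zero) last execution: declaration order wins
  st <- schedulerStep(st)
  expect_equal(st$executing$task, "a")
  # 'b' is now the task with the older last execution: it wins the next tie
  while (length(st$dispatch_log) < 2L) st <- schedulerStep(st)
  expect_equal(dispatchLog(st)$task[2], "b")
})

test_that("reactor exclusion is permanent, shrinking, and idempotent", {
  cfg <- fedBatchConfig(n_reactors = 8, duration_h = 0.5)
  set.seed(1)
  st <- initializeScheduler(cfg)
  st <- excludeReactor(st, 3L, "stirrer malfunction", now = 0)
  expect_false(st$reactors$active[3])
  st <- schedulerStep(st)
  pr <- queryPoints(st$ds, "priority")
  expect_true(all(pr$n_all == 7))
  expect_warning(st2 <- excludeReactor(st, 3L), "already excluded")
  expect_equal(st2$reactors$active, st$reactors$active)
})

test_that("a scheduled abort task ends the run with cause scheduled_abort", {
  cfg <- fedBatchConfig(n_reactors = 4, duration_h = 4,
                        extra_tasks = list(abortTask(at = 3600)))
  run <- runExperiment(cfg)
  expect_equal(run$status, "clean")
  expect_equal(run$cause, "scheduled_abort")
  # the run ended within a tick plus the abort execution of t = 1 h
  expect_lt(run$state$clock$now, 3600 + 300)
  expect_true(all(vapply(run$state$tasks, function(t) t$status,
                         character(1)) == "stopped"))
})

test_that("the termination sequence runs even when the loop crashes", {
  cfg <- fedBatchConfig(n_reactors = 4, duration_h = 1)
  # a dynamic-volume task without volume bounds fails at first report
  broken <- taskSpec(
    "broken", "ph_control",
    demand = demandModel("proportional_titration", gain = 60, setpoint = 7,
                         deadband = 0.1, plant_effect = "base"),
    priority = priorityParams(10, 80, "dynamic_volume"),
    source = "base")
  cfg$tasks <- c(cfg$tasks, list(broken = broken))
  cfg <- validateExperimentConfig(cfg)
  run <- runExperiment(cfg)
  expect_equal(run$status, "aborted")
  expect_equal(run$cause, "unexpected_exit")
  expect_equal(run$state$phase, "stopped")
  expect_true(run$state$ds$closed)
  expect_true(run$state$twin$closed)
  # terminating an already-stopped scheduler is a no-op
  expect_equal(terminateScheduler(run$state, "api_abort")$phase, "stopped")
})

test_that("the run directory is self-describing and replayable", {
  cfg <- fedBatchConfig(n_reactors = 8, duration_h = 1, seed = 4)
  run <- runExperiment(cfg)
  rd <- loadRunDir(run$dir)
  expect_gt(nrow(rd$points), 0)
  expect_equal(nrow(rd$dispatches), length(run$state$dispatch_log))
  expect_equal(rd$metadata$experiment$name, "fedbatch")
  rp <- replayDispatches(run$dir)
  expect_true(rp$match)
})

test_that("sampling stages execute in strict stage order per reactor", {
  run <- cachedRun("std1", function()
    runExperiment(fedBatchConfig(n_reactors = 48, duration_h = 8, seed = 1)))
  dl <- dispatchLog(run)
  stages <- c("sample_withdraw", "sample_prepare", "sample_to_reader",
              "sample_read", "sample_wash")
  for (k in seq_len(length(stages) - 1)) {
    a <- dl[dl$task == stages[k], ]
    b <- dl[dl$task == stages[k + 1], ]
    expect_equal(nrow(a), nrow(b))
    # every stage k+1 dispatch starts at or after the completion of the
    # corresponding stage k execution
    expect_true(all(b$start_time >= a$end_time))
  }
})

test_that("configuration errors surface at initialization", {
  cfg <- fedBatchConfig(n_reactors = 4, duration_h = 1)
  cfg$tasks$sample_prepare$predecessor <- "no_such_task"
  expect_error(initializeScheduler(cfg), "undefined task")
})
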