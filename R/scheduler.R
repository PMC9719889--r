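#' Initialize a scheduler instance
#'
#' First of the three scheduler phases. Loads the experiment definition,
#' connects the device twins in simulation mode, opens the datastore
#' stream, creates one runtime state per declared task and marks all
#' declared reactor positions active, then enters the `run` phase.
#'
#' @param config A validated [experimentConfig()].
#' @param ds_path Optional path for the datastore's JSON-lines log.
#' @return A `schedulerState` list: `phase`, `clock`, `reactors`, `tasks`
#'   (runtime registry), `twin`, `ds`, `dispatch_log`, `executing`.
#' @export
initializeScheduler <- function(config, ds_path = NULL) {
  config <- validateExperimentConfig(config)
  reactors <- do.call(reactorStates,
                      c(list(n = config$n_reactors), config$reactor_init))
  tasks <- lapply(config$tasks, newTaskState, n = config$n_reactors)
  names(tasks) <- vapply(config$tasks, `[[`, character(1), "name")
  structure(
    list(phase = "run",
         clock = c(config$clock, list(now = 0)),
         reactors = reactors,
         tasks = tasks,
         task_index = stats::setNames(seq_along(tasks), names(tasks)),
         twin = createLHSTwin(config$lhs_profile, config),
         ds = openDatastore(ds_path),
         dispatch_log = list(),
         executing = NULL,
         pH_read = reactors$pH,
         last_read_time = 0,
         abort_requested = FALSE,
         fault_done = FALSE,
         termination_cause = NULL,
         config = config),
    class = "schedulerState"
  )
}

#' @export
print.schedulerState <- function(x, ...) {
  cat(sprintf("<schedulerState> phase=%s t=%gs, %d/%d reactors active, %d dispatch(es)\n",
              x$phase, x$clock$now, sum(x$reactors$active),
              length(x$reactors$active), length(x$dispatch_log)))
  invisible(x)
}

# Oldest per-reactor last-execution time of a task over active positions
# (tie-break key 2 and a persisted field of every priority point).
.oldestLastExec <- function(task, active) {
  le <- task$last_execution[active]
  if (length(le) == 0L) Inf else min(le)
}

# Assemble the LHS command for a chosen task from its current evaluation.
.buildCommand <- function(task, state) {
  spec <- task$spec
  aff <- which(task$current_eval$affected)
  deck <- state$config$lhs_profile$deck_sequences
  dm <- spec$demand
  volumes <- if (dm$kind == "time_trigger") {
    rep(dm$event_volume, length(aff))
  } else {
    task$pending_demand[aff]
  }
  targets <- switch(spec$target_mode,
    reactors = deck$reactors[aff],
    per_sample = deck[[spec$target]][seq_along(aff)],
    single = deck[[spec$target]][1L]
  )
  if (spec$target_mode == "single") volumes <- dm$event_volume
  sources <- if (!is.null(spec$source))
    rep_len(deck[[spec$source]], length(targets))
  lhsCommand(spec$method_name, volumes, targets, sources, reactors = aff)
}

# Fold a finished execution back: plant coupling, task bookkeeping,
# dispatch log, execution and lhs_state idle points.
.completeExecution <- function(state) {
  ex <- state$executing
  rec <- ex$record
  nm <- ex$task
  task <- state$tasks[[nm]]

  pe <- task$spec$demand$plant_effect
  if (pe != "none" && length(rec$serviced_reactors))
    state$reactors <- applyAddition(state$reactors, rec$serviced_reactors,
                                    pe, rec$delivered_volumes,
                                    state$config$plant)
  state$tasks[[nm]] <- onExecutionComplete(task, rec)
  rec$task <- nm
  state$dispatch_log[[length(state$dispatch_log) + 1L]] <- rec

  sr <- rec$serviced_reactors
  if (length(sr)) {
    vols <- if (length(rec$delivered_volumes) == length(sr))
      rec$delivered_volumes else rep(0, length(sr))
    writePoints(state$ds, pointBatch(
      "execution", rec$end_time, state$config$experiment$name,
      reactor = sr, task = nm, value = vols,
      start_time = rec$start_time))
  }
  writePoints(state$ds, pointBatch(
    "lhs_state", rec$end_time, state$config$experiment$name,
    task = nm, value = 0))
  if (task$spec$task_class == "abort") state$abort_requested <- TRUE
  state$executing <- NULL
  state
}

#' Advance the scheduler by one tick
#'
#' One pass of the run-loop, advancing the internal clock by `clock$tick`
#' seconds: finish a due execution, step the plant, exclude freshly
#' malfunctioning reactors, acquire sensors on their interval, collect a
#' fresh priority report from every non-executing task, and — if the LHS is
#' available and some task holds positive priority — dispatch the
#' highest-priority task (ties broken by older per-reactor last execution,
#' then declaration order). Dispatch is non-preemptive.
#'
#' @param state A `schedulerState` in phase `run`.
#' @return The updated state.
#' @export
schedulerStep <- function(state) {
  if (state$phase != "run")
    stop("schedulerStep requires phase 'run'", call. = FALSE)
  clock <- state$clock
  t <- clock$now + clock$tick
  exp_name <- state$config$experiment$name

  if (!is.null(state$executing) && t >= state$executing$record$end_time)
    state <- .completeExecution(state)

  state$reactors <- stepPlant(state$reactors, state$config$plant, clock$tick)

  for (i in which(!state$reactors$stirrer_ok & state$reactors$active))
    state <- excludeReactor(state, i, "stirrer malfunction", now = t)

  if (t %% clock$acquisition_interval == 0) {
    sweep <- readSensors(state$reactors, state$config$plant, t, exp_name)
    writePoints(state$ds, sweep)
    state$pH_read <- sweep$value[sweep$measurement == "pH"]
    state$last_read_time <- t
  }

  # tasks see the acquired readings, not plant internals
  sensed <- state$reactors
  sensed$pH <- state$pH_read
  nm_all <- names(state$tasks)
  active <- state$reactors$active
  for (nm in nm_all)
    state$tasks[[nm]] <- reportPriority(state$tasks[[nm]], sensed, t,
                                        state$tasks,
                                        state$config$lhs_profile,
                                        sensor_age = t - state$last_read_time)
  prio <- vapply(state$tasks, function(tk) tk$current_priority$value,
                 numeric(1))
  oldest <- vapply(state$tasks, .oldestLastExec, numeric(1), active = active)
  n_aff <- vapply(state$tasks, function(tk)
    if (is.null(tk$current_eval)) 0L else tk$current_eval$n_aff, integer(1))
  writePoints(state$ds, pointBatch(
    "priority", t, exp_name, task = nm_all, value = prio,
    n_aff = as.numeric(n_aff), n_all = sum(active),
    oldest_last_exec = oldest,
    task_index = as.numeric(state$task_index)))

  if (is.null(state$executing) && any(prio > 0)) {
    ord <- order(-prio, oldest, state$task_index)
    pick <- nm_all[ord[1L]]
    state <- .dispatchTask(state, pick, t)
  }

  if (clock$mode %in% c("realtime", "accelerated"))
    Sys.sleep(clock$tick / clock$acceleration)

  state$clock$now <- t
  state
}

# Dispatch one task: build, validate, then execute on the twin or reject.
.dispatchTask <- function(state, nm, t) {
  task <- state$tasks[[nm]]
  cmd <- .buildCommand(task, state)

  fault <- state$config$fault
  if (!is.null(fault) && !state$fault_done && nm == fault$task &&
      t >= fault$time) {
    cmd$volumes <- cmd$volumes * fault$scale
    state$fault_done <- TRUE
  }

  findings <- validateCommand(cmd, state$config$lhs_profile, state$config,
                              now = t)
  blocking <- attr(findings, "blocking")
  .twinLogFindings(state$twin, t, cmd$method_name, findings)
  if (any(blocking)) {
    writePoints(state$ds, pointBatch(
      "dispatch_rejected", t, state$config$experiment$name, task = nm,
      value = sum(blocking)))
    return(state)
  }

  state$tasks[[nm]]$status <- "executing"
  rec <- executeCommand(state$twin, cmd, t, findings)
  state$executing <- list(task = nm, record = rec)
  writePoints(state$ds, pointBatch(
    "lhs_state", t, state$config$experiment$name, task = nm, value = 1))
  state
}

#' Exclude a reactor position for the remainder of the run
#'
#' Malfunctioning positions are removed permanently: `n_all` shrinks for
#' every subsequent priority calculation and no later command addresses the
#' position. Excluding an already-excluded position is an idempotent no-op
#' (with a warning).
#'
#' @param state A `schedulerState`.
#' @param reactor 1-based position index.
#' @param reason Text recorded with the exclusion event.
#' @param now Event timestamp (defaults to the scheduler clock).
#' @return The updated state.
#' @export
excludeReactor <- function(state, reactor, reason = "malfunction",
                           now = state$clock$now) {
  if (!state$reactors$active[reactor]) {
    warning("reactor ", reactor, " is already excluded", call. = FALSE)
    return(state)
  }
  state$reactors$active[reactor] <- FALSE
  writePoints(state$ds, pointBatch(
    "exclusion", now, state$config$experiment$name, reactor = reactor,
    task = reason, value = 1))
  state
}

#' Run the safety termination sequence
#'
#' Always completes, best-effort on every sub-step: stops all task
#' runtimes, closes the twin's availability stream, persists the
#' termination cause and closes the datastore, and leaves the plant's
#' stirrer drive in a safe state. Idempotent on an already-stopped state.
#'
#' @param state A `schedulerState`.
#' @param cause `"api_abort"`, `"scheduled_abort"` or `"unexpected_exit"`.
#' @return The stopped state.
#' @export
terminateScheduler <- function(state,
                               cause = c("api_abort", "scheduled_abort",
                                         "unexpected_exit")) {
  cause <- match.arg(cause)
  if (state$phase == "stopped") return(state)
  try({
    for (nm in names(state$tasks)) state$tasks[[nm]]$status <- "stopped"
  }, silent = TRUE)
  try({
    if (!is.null(state$executing))
      state <- .completeExecution(state)
  }, silent = TRUE)
  try(writePoints(state$ds, pointBatch(
    "termination", state$clock$now, state$config$experiment$name,
    task = cause, value = 1)), silent = TRUE)
  try(closeDatastore(state$ds), silent = TRUE)
  try(state$twin$closed <- TRUE, silent = TRUE)
  state$phase <- "stopped"
  state$termination_cause <- cause
  state
}

#' Execute a full in-silico experiment
#'
#' Orchestrates initialization, the run-loop until the simulated horizon
#' (or a scheduled abort), and the termination sequence — which also runs
#' if the loop fails unexpectedly. The run directory receives the datastore
#' log (`datastore.jsonl`), the dispatch log (`dispatch_log.jsonl`), the
#' twin's discrepancy log (`discrepancy.log`) and the resolved run metadata
#' (`metadata.json`), making the run self-describing and replayable.
#'
#' @param config An [experimentConfig()].
#' @param out_dir Run directory (created); default a fresh temporary one.
#' @param seed Experiment seed; defaults to `config$seed`.
#' @return Invisibly, a `lhsRun`: `status` (`"clean"`/`"aborted"`),
#'   `cause`, `dir`, and the final `state`.
#' @export
runExperiment <- function(config, out_dir = tempfile("lhsrun-"),
                          seed = config$seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  state <- initializeScheduler(
    config, ds_path = file.path(out_dir, "datastore.jsonl"))
  status <- "clean"
  cause <- "api_abort"
  run_error <- NULL

  tryCatch({
    while (state$phase == "run" && !state$abort_requested &&
           state$clock$now < state$clock$duration) {
      state <- schedulerStep(state)
    }
    if (state$abort_requested) cause <- "scheduled_abort"
  }, error = function(e) {
    status <<- "aborted"
    cause <<- "unexpected_exit"
    run_error <<- conditionMessage(e)
  })

  state <- terminateScheduler(state, cause)

  con <- file(file.path(out_dir, "dispatch_log.jsonl"), open = "w")
  for (rec in state$dispatch_log) {
    rec$command <- unclass(rec$command)
    writeLines(jsonlite::toJSON(unclass(rec)[c("task", "start_time",
                                               "end_time",
                                               "serviced_reactors",
                                               "delivered_volumes",
                                               "validation_findings",
                                               "command")],
                                auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
  }
  close(con)

  fnd <- twinFindings(state$twin)
  writeLines(sprintf("%g\t%s\t%s", fnd$time, fnd$method, fnd$finding),
             file.path(out_dir, "discrepancy.log"))
  saveRunMetadata(config, file.path(out_dir, "metadata.json"))

  invisible(structure(
    list(status = status, cause = cause, dir = out_dir, state = state,
         error = run_error),
    class = "lhsRun"
  ))
}

#' @export
print.lhsRun <- function(x, ...) {
  cat(sprintf("<lhsRun> %s (%s) after %.2f h simulated, %d dispatch(es)\n  %s\n",
              x$status, x$cause, x$state$clock$now / 3600,
              length(x$state$dispatch_log), x$dir))
  invisible(x)
}

#' Dispatch log as a data frame
#'
#' @param x An `lhsRun` or `schedulerState`.
#' @return A `data.frame`: task, start/end time, number of serviced
#'   reactors, total delivered volume.
#' @export
dispatchLog <- function(x) {
  log <- if (inherits(x, "lhsRun")) x$state$dispatch_log else x$dispatch_log
  if (length(log) == 0L)
    return(data.frame(task = character(0), start_time = numeric(0),
                      end_time = numeric(0), n_serviced = integer(0),
                      total_volume = numeric(0)))
  data.frame(
    task = vapply(log, `[[`, character(1), "task"),
    start_time = vapply(log, `[[`, numeric(1), "start_time"),
    end_time = vapply(log, `[[`, numeric(1), "end_time"),
    n_serviced = vapply(log, function(r) length(r$serviced_reactors),
                        integer(1)),
    total_volume = vapply(log, function(r) sum(r$delivered_volumes),
                          numeric(1))
  )
}
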