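#' Demand model of a task
#'
#' How a task computes, per reactor position, the quantity of work it
#' currently requires:
#'
#' * `constant_volume` — a fixed bolus (`volume`, uL) per execution;
#'   execution frequency is governed by the task's elapsed-time constraints.
#' * `exponential_feed` — an intermittent bolus growing with process time,
#'   `base_volume * exp(mu_set * t_h)` uL (the profile an exponential-growth
#'   fed-batch prescribes for interval feeding).
#' * `proportional_titration` — one-sided base addition,
#'   `gain * max(0, setpoint - deadband - pH_i)` uL; zero inside the
#'   deadband.
#' * `time_trigger` — binary demand (sampling stages, induction, abort):
#'   1 when the position needs the event. A stage with a predecessor is
#'   demanded once the predecessor has completed more recently than the
#'   stage itself; `once = TRUE` (induction, abort) demands until the first
#'   execution.
#'
#' Volumes produced are clamped to the pipettable range of the LHS profile
#' at dispatch time. `event_volume` (uL, default 0) is the volume a
#' triggered event transfers (e.g. sample withdrawal volume); 0 marks a
#' transport-only step. `plant_effect` declares how executed volumes couple
#' back into the plant: `"feed"`, `"base"`, `"sample"` or `"none"`.
#'
#' @param kind One of the four model kinds.
#' @param ... Named numeric parameters of the model (see above).
#' @param event_volume Transfer volume of a triggered event, uL.
#' @param plant_effect Plant coupling of delivered volumes.
#' @param once Trigger tasks: demand only until first execution.
#' @return An object of class `demandModel`.
#' @export
demandModel <- function(kind = c("constant_volume", "exponential_feed",
                                 "proportional_titration", "time_trigger"),
                        ..., event_volume = 0,
                        plant_effect = c("none", "feed", "base", "sample"),
                        once = FALSE) {
  kind <- match.arg(kind)
  plant_effect <- match.arg(plant_effect)
  pars <- list(...)
  need <- switch(kind,
    constant_volume = "volume",
    exponential_feed = c("base_volume", "mu_set"),
    proportional_titration = c("gain", "setpoint", "deadband"),
    time_trigger = character(0))
  missing <- setdiff(need, names(pars))
  if (length(missing))
    stop("demand model '", kind, "' needs parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(kind = kind, parameters = pars,
                 event_volume = event_volume,
                 plant_effect = plant_effect, once = once),
            class = "demandModel")
}

#' Define a schedulable LHS task
#'
#' @param name Unique task name.
#' @param task_class One of `feeding`, `ph_control`, `sampling_stage`,
#'   `induction`, `abort`.
#' @param demand A [demandModel()].
#' @param priority A [priorityParams()].
#' @param constraints List of [constraintSpec()]s.
#' @param method_name LHS method invoked on dispatch (defaults to the task
#'   name).
#' @param stage_index Sampling stage number (>= 1), 0 otherwise.
#' @param predecessor Name of the preceding sampling stage, or `NULL`.
#' @param target Deck sequence the command targets: `"reactors"` (one
#'   position per serviced reactor), the name of another deck sequence
#'   (one well per serviced sample), or `list(sequence, "single")` handled
#'   via `target_mode`.
#' @param target_mode `"reactors"`, `"per_sample"` (one target well per
#'   serviced reactor in `target`), or `"single"` (one position, e.g. a
#'   plate transport).
#' @param source Deck sequence name to draw from (substrate/base container),
#'   or `NULL`.
#' @return An object of class `taskSpec`.
#' @export
taskSpec <- function(name, task_class = c("feeding", "ph_control",
                                          "sampling_stage", "induction",
                                          "abort"),
                     demand, priority = priorityParams(),
                     constraints = list(), method_name = name,
                     stage_index = 0L, predecessor = NULL,
                     target = "reactors",
                     target_mode = c("reactors", "per_sample", "single"),
                     source = NULL) {
  task_class <- match.arg(task_class)
  target_mode <- match.arg(target_mode)
  stopifnot(inherits(demand, "demandModel"), inherits(priority, "priorityParams"))
  if (!all(vapply(constraints, inherits, logical(1), "constraintSpec")))
    stop("constraints must be a list of constraintSpec objects", call. = FALSE)
  for (q in c("volume", "elapsed_time", "clock_time", "fill_level")) {
    lims <- Filter(function(cs) cs$quantity == q, constraints)
    lo <- vapply(Filter(function(cs) cs$bound == "lower", lims),
                 `[[`, numeric(1), "limit")
    hi <- vapply(Filter(function(cs) cs$bound == "upper", lims),
                 `[[`, numeric(1), "limit")
    if (length(lo) && length(hi) && max(lo) > min(hi))
      stop("task '", name, "': lower bound on ", q,
           " exceeds its upper bound", call. = FALSE)
  }
  if (stage_index < 0) stop("stage_index must be >= 0", call. = FALSE)
  structure(
    list(name = name, method_name = method_name, task_class = task_class,
         constraints = constraints, priority = priority, demand = demand,
         stage_index = as.integer(stage_index), predecessor = predecessor,
         target = target, target_mode = target_mode, source = source),
    class = "taskSpec"
  )
}

#' @export
print.taskSpec <- function(x, ...) {
  cat(sprintf("<taskSpec> %s (%s, %s priority, %d constraint(s))%s\n",
              x$name, x$task_class, x$priority$algorithm,
              length(x$constraints),
              if (!is.null(x$predecessor))
                paste0(" after ", x$predecessor) else ""))
  invisible(x)
}

#' Create the runtime state of a task
#'
#' @param spec A [taskSpec()].
#' @param n Number of declared reactor positions.
#' @return A `taskState`: per-reactor `last_execution` / `last_start` times
#'   (s, start at 0), execution counts, `pending_demand`, the current
#'   priority and eval, and the lifecycle `status` (`idle`,
#'   `awaiting_dispatch`, `executing`, `stopped`).
#' @export
newTaskState <- function(spec, n) {
  structure(
    list(spec = spec, n = n,
         last_execution = numeric(n), last_start = numeric(n),
         exec_count = integer(n), pending_demand = numeric(n),
         current_priority = .priorityResult(0, timestamp = 0),
         current_eval = NULL, status = "idle"),
    class = "taskState"
  )
}

#' @export
print.taskState <- function(x, ...) {
  cat(sprintf("<taskState> %s: %s, priority %g, %d execution(s)\n",
              x$spec$name, x$status, x$current_priority$value,
              sum(x$exec_count > 0)))
  invisible(x)
}

#' Compute a task's per-reactor demand
#'
#' Evaluates the task's demand model against current plant readings.
#' Demands of inactive (excluded) positions are zero. Volume demands are
#' clamped to the channel maximum of `profile` when given.
#'
#' @param state A `taskState`.
#' @param reactors A [reactorStates()] carrying the current sensor readings
#'   (the scheduler passes the latest acquired values, not plant internals).
#' @param now Simulated time (s).
#' @param tasks Full task-state registry (predecessor gating of sampling
#'   stages); may be `NULL` for tasks without predecessor.
#' @param profile Optional [lhsProfile()] for volume clamping.
#' @param sensor_age Seconds since the sensor values in `reactors` were
#'   acquired; sensor-driven demand goes to zero (with a warning) past the
#'   staleness threshold of 300 s.
#' @return Numeric demand vector over all declared positions.
#' @export
computeDemand <- function(state, reactors, now, tasks = NULL, profile = NULL,
                          sensor_age = 0) {
  dm <- state$spec$demand
  n <- state$n
  p <- dm$parameters
  d <- switch(dm$kind,
    constant_volume = rep(p$volume, n),
    exponential_feed = rep(p$base_volume * exp(p$mu_set * now / 3600), n),
    proportional_titration = {
      if (sensor_age > 300) {
        warning("task '", state$spec$name, "': sensor values are ",
                sensor_age, " s old; demand suppressed", call. = FALSE)
        rep(0, n)
      } else {
        p$gain * pmax(0, p$setpoint - p$deadband - reactors$pH)
      }
    },
    time_trigger = {
      if (!is.null(state$spec$predecessor)) {
        pred <- tasks[[state$spec$predecessor]]
        if (is.null(pred))
          stop("task '", state$spec$name, "': predecessor '",
               state$spec$predecessor, "' not in registry", call. = FALSE)
        as.numeric(pred$exec_count > state$exec_count &
                   pred$last_execution > state$last_execution)
      } else if (isTRUE(dm$once)) {
        as.numeric(state$exec_count == 0L)
      } else {
        rep(1, n)
      }
    }
  )
  if (dm$kind != "time_trigger" && !is.null(profile))
    d <- pmin(d, profile$channel_volume_max)
  d[!reactors$active] <- 0
  d
}

#' Recompute and report a task's priority
#'
#' Chains demand computation, constraint evaluation and the configured
#' priority algorithm, storing the result in the state. Execution is
#' non-preemptive: a task that is currently `executing` (or `stopped`)
#' retains its last reported priority and is not recomputed.
#'
#' @inheritParams computeDemand
#' @return The updated `taskState` (read `$current_priority`).
#' @export
reportPriority <- function(state, reactors, now, tasks = NULL,
                           profile = NULL, sensor_age = 0) {
  if (state$status %in% c("executing", "stopped")) return(state)
  demand <- computeDemand(state, reactors, now, tasks, profile, sensor_age)
  eval <- evaluateConstraints(state, reactors, now, demand)
  state$pending_demand <- demand
  state$current_eval <- eval
  state$current_priority <- computePriority(state, eval, reactors, now, demand)
  state
}

#' Fold a completed execution back into the task state
#'
#' Only the serviced positions advance: their `last_execution` moves to the
#' record's end time (enabling successor sampling stages and restarting
#' elapsed-time constraints), their pending demand clears, and the task
#' returns to `idle`.
#'
#' @param state A `taskState` (status `executing`).
#' @param record An `executionRecord` from [executeCommand()].
#' @return The updated `taskState`.
#' @export
onExecutionComplete <- function(state, record) {
  idx <- record$serviced_reactors
  if (length(idx) && (any(idx < 1L) || any(idx > state$n)))
    stop("execution record names unknown reactor position(s): ",
         paste(setdiff(idx, seq_len(state$n)), collapse = ", "),
         call. = FALSE)
  state$last_execution[idx] <- record$end_time
  state$last_start[idx] <- record$start_time
  state$exec_count[idx] <- state$exec_count[idx] + 1L
  state$pending_demand[idx] <- 0
  if (state$status != "stopped") state$status <- "idle"
  state
}
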