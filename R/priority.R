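#' Priority parameters of a task
#'
#' Every task carries a baseline priority `p_base` and a critical priority
#' `p_crit`; no computed priority may exceed `p_crit` (the cap
#' `p_max = p_crit`). Priorities are dimensionless and comparable only
#' across tasks within one experiment.
#'
#' @param p_base Baseline priority, `0 <= p_base <= p_crit`. Default 10.
#' @param p_crit Critical (maximum) priority. Default 100.
#' @param algorithm Which priority algorithm the task uses: `"step"`,
#'   `"step_specific"`, `"dynamic_volume"` or `"dynamic_time"`.
#' @return An object of class `priorityParams`.
#' @export
priorityParams <- function(p_base = 10, p_crit = 100,
                           algorithm = c("step", "step_specific",
                                         "dynamic_volume", "dynamic_time")) {
  algorithm <- match.arg(algorithm)
  if (!is.numeric(p_base) || !is.numeric(p_crit) ||
      length(p_base) != 1L || length(p_crit) != 1L)
    stop("p_base and p_crit must be single numbers", call. = FALSE)
  if (p_base < 0 || p_base > p_crit)
    stop("priority parameters must satisfy 0 <= p_base <= p_crit (got p_base=",
         p_base, ", p_crit=", p_crit, ")", call. = FALSE)
  structure(list(p_base = as.numeric(p_base), p_crit = as.numeric(p_crit),
                 algorithm = algorithm),
            class = "priorityParams")
}

.priorityResult <- function(value, terms = numeric(0), timestamp = NA_real_) {
  structure(list(value = value, per_reactor_terms = terms,
                 timestamp = timestamp),
            class = "priorityResult")
}

#' @export
print.priorityResult <- function(x, ...) {
  cat(sprintf("<priorityResult> value=%g (t=%s)\n", x$value,
              format(x$timestamp)))
  invisible(x)
}

#' Step priority
#'
#' Static priority from constraint evaluation alone: zero if the task needs
#' no execution (no affected position, which includes the case that every
#' demand-bearing position is blocked by a hard constraint), the baseline
#' `p_base` while all constraints hold, and the critical priority `p_crit`
#' as soon as a soft constraint is violated on an affected position.
#'
#' @param eval A [evaluateConstraints()] result.
#' @param params A [priorityParams()].
#' @param timestamp Simulated time attached to the result.
#' @return A `priorityResult` with `0 <= value <= p_crit`.
#' @export
priorityStep <- function(eval, params, timestamp = NA_real_) {
  value <- if (eval$n_aff == 0L) {
    0
  } else if (any(eval$soft_violated & eval$affected)) {
    params$p_crit
  } else {
    params$p_base
  }
  .priorityResult(value, timestamp = timestamp)
}

#' Step-specific priority
#'
#' Like [priorityStep()] but scaled by the share of reactor positions that
#' require action: `n_aff / n_all`, where `n_all` counts the active
#' positions (malfunctioning positions are excluded by the scheduler and
#' shrink `n_all`). Under soft violation the priority interpolates from
#' `p_base` towards `p_crit` with that share.
#'
#' @inheritParams priorityStep
#' @return A `priorityResult`; value 0 when no position is affected or no
#'   reactor is active.
#' @export
priorityStepSpecific <- function(eval, params, timestamp = NA_real_) {
  if (eval$n_all == 0L || eval$n_aff == 0L)
    return(.priorityResult(0, timestamp = timestamp))
  share <- eval$n_aff / eval$n_all
  value <- if (any(eval$soft_violated & eval$affected)) {
    params$p_base + (params$p_crit - params$p_base) * share
  } else {
    params$p_base * share
  }
  .priorityResult(min(value, params$p_crit), timestamp = timestamp)
}

# Shared linear form of the two dynamic algorithms: p_base plus
# (p_crit - p_base)/n_all times the sum over affected positions of the
# position's progress through its [lower, lower + delta] span, each summand
# clamped to [0, 1], the total capped at p_crit.
.priorityDynamic <- function(eval, values, lim_lower, lim_delta, params,
                             timestamp, what) {
  if (eval$n_all == 0L || eval$n_aff == 0L)
    return(.priorityResult(0, timestamp = timestamp))
  aff <- which(eval$affected)
  stopifnot(length(values) == length(eval$affected),
            length(lim_lower) == length(eval$affected),
            length(lim_delta) == length(eval$affected))
  if (any(!is.finite(lim_delta[aff])) || any(lim_delta[aff] <= 0))
    stop("dynamic ", what, " priority: the span between lower and upper ",
         "limit must be positive for every affected reactor", call. = FALSE)
  terms <- pmin(pmax((values[aff] - lim_lower[aff]) / lim_delta[aff], 0), 1)
  value <- params$p_base +
    (params$p_crit - params$p_base) / eval$n_all * sum(terms)
  .priorityResult(min(value, params$p_crit), terms = terms,
                  timestamp = timestamp)
}

#' Dynamic volume priority
#'
#' Linear in the requested volumes: for each affected position the summand
#' is the fraction of the allowed volume span `(v_i - v_lim_lower_i) /
#' delta_v_lim_i` already used, so the priority grows from `p_base` (all
#' positions at their lower volume limit) towards `p_crit` (all active
#' positions at their upper limit). Intended for volume-driven tasks such
#' as substrate feeding or base addition for pH control.
#'
#' @inheritParams priorityStep
#' @param volumes Per-reactor requested volumes (uL), full-length vector;
#'   only entries at affected positions are read.
#' @param lim_lower Per-reactor lower volume limits `v_lim,lower` (uL).
#' @param lim_delta Per-reactor allowed spans `delta_v_lim = v_lim,upper -
#'   v_lim,lower` (uL); must be positive for affected positions.
#' @return A `priorityResult` with the clamped per-position summands in
#'   `per_reactor_terms`.
#' @export
priorityDynamicVolume <- function(eval, volumes, lim_lower, lim_delta, params,
                                  timestamp = NA_real_) {
  .priorityDynamic(eval, volumes, lim_lower, lim_delta, params, timestamp,
                   "volume")
}

#' Dynamic time priority
#'
#' Linear in the time since each position was last serviced; the summand per
#' affected position is `(t_i - t_lim_lower_i) / delta_t_lim_i`, clamped to
#' `[0, 1]`. Intended for time-driven tasks such as sampling or induction.
#'
#' @inheritParams priorityDynamicVolume
#' @param elapsed Per-reactor seconds since last execution, full-length.
#' @param lim_lower Per-reactor lower time limits `t_lim,lower` (s).
#' @param lim_delta Per-reactor spans `delta_t_lim` (s), positive for
#'   affected positions.
#' @export
priorityDynamicTime <- function(eval, elapsed, lim_lower, lim_delta, params,
                                timestamp = NA_real_) {
  .priorityDynamic(eval, elapsed, lim_lower, lim_delta, params, timestamp,
                   "time")
}

# Extract per-reactor (lower, delta) limit vectors for a dynamic algorithm
# from the task's constraints on `quantity`. The lower limit comes from the
# lower-bound constraint on that quantity, the span from the upper-bound
# constraint; both must exist for the dynamic algorithms.
.limitVectors <- function(spec, quantity, n) {
  lower <- rep(NA_real_, n)
  upper <- rep(NA_real_, n)
  for (cs in spec$constraints) {
    if (cs$quantity != quantity) next
    idx <- if (identical(cs$applies_to, "all")) seq_len(n) else cs$applies_to
    if (cs$bound == "lower") lower[idx] <- cs$limit else upper[idx] <- cs$limit
  }
  if (anyNA(lower) || anyNA(upper))
    stop("task '", spec$name, "': the ", sub("_", " ", quantity),
         " limits required by its dynamic priority algorithm are not fully ",
         "declared (need a lower and an upper bound on '", quantity, "')",
         call. = FALSE)
  list(lower = lower, delta = upper - lower)
}

#' Compute a task's priority with its configured algorithm
#'
#' Dispatches to the configured algorithm, deriving the per-reactor limit
#' vectors the dynamic algorithms need from the task's declared constraints
#' (`volume` bounds for dynamic-volume, `elapsed_time` bounds for
#' dynamic-time).
#'
#' @param task_state A `taskState`.
#' @param eval The task's current [evaluateConstraints()] result.
#' @param reactors A [reactorStates()].
#' @param now Simulated time (s).
#' @param demand Per-reactor demand used for the volume algorithm.
#' @return A `priorityResult`.
#' @export
computePriority <- function(task_state, eval, reactors, now,
                            demand = task_state$pending_demand) {
  params <- task_state$spec$priority
  n <- length(reactors$active)
  switch(params$algorithm,
    step = priorityStep(eval, params, now),
    step_specific = priorityStepSpecific(eval, params, now),
    dynamic_volume = {
      lim <- .limitVectors(task_state$spec, "volume", n)
      priorityDynamicVolume(eval, demand, lim$lower, lim$delta, params, now)
    },
    dynamic_time = {
      lim <- .limitVectors(task_state$spec, "elapsed_time", n)
      priorityDynamicTime(eval, now - task_state$last_execution,
                          lim$lower, lim$delta, params, now)
    }
  )
}
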