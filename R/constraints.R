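#' Declare a per-reactor execution constraint
#'
#' A constraint bounds one observable quantity of a task, per reactor
#' position. Hard constraints prohibit execution for the violating position
#' (the position drops out of the set of affected reactors); soft constraints
#' may be violated and instead escalate the task's priority.
#'
#' @param name Short identifier, used in logs and validation messages.
#' @param kind `"hard"` (prohibits execution) or `"soft"` (escalates
#'   priority).
#' @param quantity What is bounded: `"volume"` (requested transfer volume,
#'   uL), `"elapsed_time"` (seconds since the task last serviced the
#'   position), `"clock_time"` (seconds since experiment start, for fixed
#'   execution windows such as induction), or `"fill_level"` (reactor fill
#'   volume, uL).
#' @param bound `"lower"` or `"upper"`.
#' @param limit Numeric limit in the quantity's native unit (uL or seconds).
#' @param applies_to `"all"` or an integer vector of 1-based reactor
#'   positions the constraint applies to.
#'
#' @return An object of class `constraintSpec`.
#' @examples
#' constraintSpec("min_feed_interval", "hard", "elapsed_time", "lower", 1500)
#' @export
constraintSpec <- function(name, kind, quantity, bound, limit,
                           applies_to = "all") {
  kind <- match.arg(kind, c("hard", "soft"))
  quantity <- match.arg(quantity,
                        c("volume", "elapsed_time", "clock_time", "fill_level"))
  bound <- match.arg(bound, c("lower", "upper"))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(limit) || length(limit) != 1L || !is.finite(limit))
    stop("constraint '", name, "': limit must be a finite number", call. = FALSE)
  if (quantity %in% c("volume", "fill_level") && limit < 0)
    stop("constraint '", name, "': volume/fill limits must be non-negative",
         call. = FALSE)
  if (!identical(applies_to, "all")) {
    applies_to <- as.integer(applies_to)
    if (anyNA(applies_to) || any(applies_to < 1L))
      stop("constraint '", name, "': applies_to must be 'all' or positive indices",
           call. = FALSE)
  }
  structure(
    list(name = name, kind = kind, quantity = quantity, bound = bound,
         limit = as.numeric(limit), applies_to = applies_to),
    class = "constraintSpec"
  )
}

#' @export
print.constraintSpec <- function(x, ...) {
  cat(sprintf("<constraintSpec> %s: %s %s bound on %s at %g %s\n",
              x$name, x$kind, x$bound, x$quantity, x$limit,
              if (x$quantity %in% c("volume", "fill_level")) "uL" else "s"))
  invisible(x)
}

# Per-reactor value of a constrained quantity. `demand` is the task's
# requested quantity (uL, or a 0/1 flag for trigger tasks), `elapsed` the
# seconds since last execution per position.
.constraintQuantity <- function(quantity, demand, elapsed, reactors, now) {
  switch(quantity,
    volume       = demand,
    elapsed_time = elapsed,
    clock_time   = rep(now, length(demand)),
    fill_level   = reactors$fill_mL * 1000,
    stop("unknown constraint quantity '", quantity, "'", call. = FALSE)
  )
}

#' Evaluate a task's constraints over all reactor positions
#'
#' Produces the boolean vectors the priority calculus consumes: which
#' positions violate a hard constraint (and are therefore excluded from
#' dispatch), which violate a soft constraint (and by how much), and which
#' are *affected* — i.e. require action and pass every hard constraint.
#' Positions with zero demand, and inactive (excluded) positions, are
#' non-violating and not affected.
#'
#' Evaluation is a pure function of its inputs; it inspects instantaneous
#' state only and performs no look-ahead.
#'
#' @param task_state A `taskState` (see [newTaskState()]); its
#'   `spec$constraints` are evaluated.
#' @param reactors A [reactorStates()] object.
#' @param now Simulated time, seconds since experiment start.
#' @param demand Per-reactor requested quantity (uL, or 0/1 for trigger
#'   tasks). Defaults to the task's `pending_demand`.
#'
#' @return An object of class `constraintEvaluation`: logical vectors
#'   `hard_violated`, `soft_violated`, `affected` (all over declared reactor
#'   positions), numeric `violation_extent` (how far past the nearest soft
#'   bound, native units, >= 0), and counts `n_aff` (affected positions) and
#'   `n_all` (active positions).
#' @export
evaluateConstraints <- function(task_state, reactors, now,
                                demand = task_state$pending_demand) {
  n <- length(reactors$active)
  stopifnot(length(demand) == n)
  active <- reactors$active
  elapsed <- now - task_state$last_execution

  hard <- logical(n)
  soft <- logical(n)
  extent <- numeric(n)
  considered <- active & demand > 0

  if (any(considered)) {
    for (cs in task_state$spec$constraints) {
      value <- .constraintQuantity(cs$quantity, demand, elapsed, reactors, now)
      scope <- considered
      if (!identical(cs$applies_to, "all")) {
        scope <- scope & seq_len(n) %in% cs$applies_to
      }
      viol <- if (cs$bound == "lower") value < cs$limit else value > cs$limit
      viol <- viol & scope
      if (cs$kind == "hard") {
        hard <- hard | viol
      } else {
        soft <- soft | viol
        over <- if (cs$bound == "lower") cs$limit - value else value - cs$limit
        extent <- pmax(extent, ifelse(viol, pmax(over, 0), 0))
      }
    }
  }

  affected <- considered & !hard
  structure(
    list(hard_violated = hard, soft_violated = soft, affected = affected,
         violation_extent = extent,
         n_aff = sum(affected), n_all = sum(active)),
    class = "constraintEvaluation"
  )
}

#' @export
print.constraintEvaluation <- function(x, ...) {
  cat(sprintf("<constraintEvaluation> n_all=%d n_aff=%d hard=%d soft=%d\n",
              x$n_all, x$n_aff, sum(x$hard_violated), sum(x$soft_violated)))
  invisible(x)
}
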