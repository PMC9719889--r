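#' Assemble an experiment configuration
#'
#' The configuration is the in-silico equivalent of the user script that
#' configures a real run: experiment identity, reactor fleet, LHS profile,
#' task definitions with constraints and priority parameters, plant-model
#' parameters, clock settings and output paths.
#'
#' @param name Experiment name (tag on every persisted point).
#' @param operator Operator name, recorded in the run metadata.
#' @param n_reactors Number of declared reactor positions (>= 1).
#' @param reactor_init Named list of initial values passed to
#'   [reactorStates()] (biomass, glucose, acetate, pH, DO, fill_mL).
#' @param lhs_profile An [lhsProfile()].
#' @param tasks List of [taskSpec()]s; names must be unique and sampling
#'   predecessors must resolve acyclically with increasing stage indices.
#' @param plant A [plantParams()].
#' @param clock List: `tick` (priority re-evaluation period, s, default 10),
#'   `duration` (simulated horizon, s), `mode` (`"event_driven"`,
#'   `"accelerated"` or `"realtime"`), `acceleration` (> 0),
#'   `acquisition_interval` (sensor sweep period, s, default 60).
#' @param seed Integer experiment seed; all randomness (plant noise,
#'   malfunctions, duration jitter) derives from it.
#' @param fault Optional fault injection for twin verification:
#'   `list(task = <feeding task name>, time = <s>, scale = <factor>)` scales
#'   the volumes of the first dispatch of that task after `time`.
#' @return A validated object of class `experimentConfig`.
#' @export
experimentConfig <- function(name = "sim", operator = "in-silico",
                             n_reactors = 48L, reactor_init = list(),
                             lhs_profile = lhsProfile(
                               deck_sequences = defaultDeck(n_reactors)),
                             tasks = list(), plant = plantParams(),
                             clock = list(), seed = 1L, fault = NULL) {
  clock <- utils::modifyList(
    list(tick = 10, duration = 8 * 3600, mode = "event_driven",
         acceleration = 1, acquisition_interval = 60), clock)
  cfg <- structure(
    list(experiment = list(name = name, operator = operator),
         n_reactors = as.integer(n_reactors), reactor_init = reactor_init,
         lhs_profile = lhs_profile, tasks = tasks, plant = plant,
         clock = clock, seed = as.integer(seed), fault = fault),
    class = "experimentConfig"
  )
  validateExperimentConfig(cfg)
}

#' Validate an experiment configuration
#'
#' Checks cross-field invariants (unique task names, resolvable and acyclic
#' sampling predecessor chains with strictly increasing stage indices,
#' positive reactor count and clock settings) and raises errors naming the
#' offending field.
#'
#' @param cfg An `experimentConfig`.
#' @return The configuration, invisibly valid (returned for chaining).
#' @export
validateExperimentConfig <- function(cfg) {
  fail <- function(field, msg)
    stop("config: ", field, ": ", msg, call. = FALSE)
  if (cfg$n_reactors < 1L) fail("reactors.count", "must be >= 1")
  if (!cfg$clock$mode %in% c("event_driven", "accelerated", "realtime"))
    fail("clock.mode", "unknown mode")
  if (cfg$clock$tick <= 0) fail("clock.tick", "must be > 0")
  if (cfg$clock$duration <= 0) fail("clock.duration", "must be > 0")
  if (cfg$clock$acceleration <= 0) fail("clock.acceleration", "must be > 0")
  if (!all(vapply(cfg$tasks, inherits, logical(1), "taskSpec")))
    fail("tasks", "every entry must be a taskSpec")

  nm <- vapply(cfg$tasks, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    fail("tasks.name", paste0("duplicate task name(s): ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  names(cfg$tasks) <- nm
  for (t in cfg$tasks) {
    if (!is.null(t$predecessor)) {
      if (!t$predecessor %in% nm)
        fail(paste0("tasks.", t$name, ".predecessor"),
             paste0("undefined task '", t$predecessor, "'"))
      pred <- cfg$tasks[[t$predecessor]]
      if (pred$stage_index >= t$stage_index)
        fail(paste0("tasks.", t$name, ".stage_index"),
             "must strictly increase along predecessor links")
    }
  }
  # cycle check along predecessor links
  for (t in cfg$tasks) {
    seen <- character(0)
    cur <- t
    while (!is.null(cur$predecessor)) {
      if (cur$predecessor %in% seen || identical(cur$predecessor, t$name))
        fail("tasks", "cycle in sampling predecessor graph")
      seen <- c(seen, cur$name)
      cur <- cfg$tasks[[cur$predecessor]]
    }
  }
  if (!is.null(cfg$fault)) {
    if (!all(c("task", "time", "scale") %in% names(cfg$fault)))
      fail("fault", "needs fields task, time, scale")
    if (!cfg$fault$task %in% nm)
      fail("fault.task", "refers to an undefined task")
  }
  cfg
}

#' @export
print.experimentConfig <- function(x, ...) {
  cat(sprintf("<experimentConfig> '%s': %d reactors, %d task(s), %.1f h horizon, seed %d\n",
              x$experiment$name, x$n_reactors, length(x$tasks),
              x$clock$duration / 3600, x$seed))
  invisible(x)
}

.CONFIG_KEYS <- list(
  top = c("experiment", "reactors", "lhs_profile", "tasks", "plant", "clock",
          "datastore", "seed", "fault"),
  experiment = c("name", "operator"),
  reactors = c("count", "biomass", "glucose", "acetate", "pH", "DO",
               "fill_mL"),
  lhs_profile = c("n_channels", "channel_volume_max", "channel_volume_min",
                  "per_cycle_duration", "per_method_overhead",
                  "default_overhead", "jitter_sdlog", "deck_sequences"),
  clock = c("tick", "duration", "mode", "acceleration",
            "acquisition_interval"),
  task = c("name", "task_class", "method_name", "stage_index", "predecessor",
           "target", "target_mode", "source", "priority", "demand",
           "constraints"),
  priority = c("p_base", "p_crit", "algorithm"),
  demand = c("kind", "parameters", "event_volume", "plant_effect", "once"),
  constraint = c("name", "kind", "quantity", "bound", "limit", "applies_to")
)

.checkKeys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop("config: ", where, ": unknown key(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  x
}

#' Load and validate an experiment configuration file
#'
#' Accepts YAML or JSON (by extension). Unknown keys are rejected as typo
#' protection; schema violations report the offending field path. Defaults
#' are resolved through the same constructors the programmatic interface
#' uses.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated [experimentConfig()].
#' @export
loadExperimentConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  .configFromList(raw)
}

.configFromList <- function(raw) {
  .checkKeys(raw, .CONFIG_KEYS$top, "top level")
  exp <- .checkKeys(raw$experiment %||% list(), .CONFIG_KEYS$experiment,
                    "experiment")
  rea <- .checkKeys(raw$reactors %||% list(), .CONFIG_KEYS$reactors,
                    "reactors")
  n <- as.integer(rea$count %||% 48L)

  prof_raw <- .checkKeys(raw$lhs_profile %||% list(),
                         .CONFIG_KEYS$lhs_profile, "lhs_profile")
  if (!is.null(prof_raw$per_method_overhead))
    prof_raw$per_method_overhead <- unlist(prof_raw$per_method_overhead)
  if (is.null(prof_raw$deck_sequences))
    prof_raw$deck_sequences <- defaultDeck(n)
  profile <- do.call(lhsProfile, prof_raw)

  plant <- do.call(plantParams, {
    pp <- raw$plant %||% list()
    if (!is.null(pp$noise_sd)) pp$noise_sd <- unlist(pp$noise_sd)
    pp
  })

  tasks <- lapply(raw$tasks %||% list(), function(tr) {
    .checkKeys(tr, .CONFIG_KEYS$task, paste0("tasks.", tr$name %||% "?"))
    pr <- .checkKeys(tr$priority %||% list(), .CONFIG_KEYS$priority,
                     paste0("tasks.", tr$name, ".priority"))
    dm_raw <- .checkKeys(tr$demand %||% list(), .CONFIG_KEYS$demand,
                         paste0("tasks.", tr$name, ".demand"))
    dm <- do.call(demandModel, c(
      list(kind = dm_raw$kind), as.list(dm_raw$parameters %||% list()),
      dm_raw[intersect(names(dm_raw), c("event_volume", "plant_effect",
                                        "once"))]))
    cons <- lapply(tr$constraints %||% list(), function(cr) {
      .checkKeys(cr, .CONFIG_KEYS$constraint,
                 paste0("tasks.", tr$name, ".constraints"))
      do.call(constraintSpec, cr)
    })
    args <- tr[intersect(names(tr), c("name", "task_class", "method_name",
                                      "stage_index", "predecessor", "target",
                                      "target_mode", "source"))]
    do.call(taskSpec, c(args, list(demand = dm,
                                   priority = do.call(priorityParams, pr),
                                   constraints = cons)))
  })

  experimentConfig(
    name = exp$name %||% "sim", operator = exp$operator %||% "in-silico",
    n_reactors = n,
    reactor_init = rea[setdiff(names(rea), "count")],
    lhs_profile = profile, tasks = tasks, plant = plant,
    clock = raw$clock %||% list(), seed = raw$seed %||% 1L,
    fault = raw$fault
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize the resolved configuration to run metadata
#'
#' Writes the fully resolved configuration (all defaults filled) as JSON so
#' a run directory is self-describing; [loadRunMetadata()] reads it back.
#'
#' @param cfg An `experimentConfig`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
saveRunMetadata <- function(cfg, path) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- if (is.null(names(x))) NULL else list(names = names(x))
    }
    x
  }
  meta <- strip(unclass(cfg))
  meta$wall_clock <- format(Sys.time(), tz = "UTC", usetz = TRUE)
  meta$task_order <- vapply(cfg$tasks, `[[`, character(1), "name")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read run metadata back
#'
#' @param path Path of a [saveRunMetadata()] file.
#' @return The metadata as a nested list.
#' @export
loadRunMetadata <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}
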