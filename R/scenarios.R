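#' Reference fed-batch scheduling scenario
#'
#' The package's stated in-silico world: 48 parallel 10 mL reactors on an
#' eight-channel LHS running an intermittent exponential feed (minimum
#' interval 1500 s, soft ceiling 2100 s, dynamic-time priority), one-sided
#' proportional pH control with NaOH (dynamic-volume priority), and an
#' hourly five-stage sampling chain (withdraw, prepare/dilute, transport to
#' reader, read, wash). Parameter choices are documented in the methods
#' vignette and are deliberately not arguments: vary the returned object if
#' you need a different world.
#'
#' @param n_reactors Reactor positions (default 48).
#' @param duration_h Simulated horizon in hours (default 8).
#' @param seed Experiment seed.
#' @param malfunction_rate Stirrer malfunction rate, events/h per reactor
#'   (default 0).
#' @param noise Apply sensor noise (default `TRUE`; `FALSE` gives the
#'   noise-free world used for conservation checks).
#' @param extra_tasks Additional [taskSpec()]s appended to the mix (e.g. an
#'   induction or abort task).
#' @param name Experiment name tag.
#' @return An [experimentConfig()].
#' @export
fedBatchConfig <- function(n_reactors = 48L, duration_h = 8, seed = 1L,
                           malfunction_rate = 0, noise = TRUE,
                           extra_tasks = list(), name = "fedbatch") {
  min_pip <- 5    # uL, minimum pipettable volume of the 1000 uL channels

  feed <- taskSpec(
    "feed", "feeding",
    demand = demandModel("exponential_feed", base_volume = 60, mu_set = 0.2,
                         plant_effect = "feed"),
    priority = priorityParams(10, 100, "dynamic_time"),
    constraints = list(
      constraintSpec("min_feed_interval", "hard", "elapsed_time", "lower", 1500),
      constraintSpec("max_feed_interval", "soft", "elapsed_time", "upper", 2100),
      constraintSpec("min_pipettable", "hard", "volume", "lower", min_pip),
      constraintSpec("max_channel_volume", "hard", "volume", "upper", 1000),
      constraintSpec("working_volume_cap", "hard", "fill_level", "upper", 15000)
    ),
    source = "substrate"
  )

  ph <- taskSpec(
    "ph_control", "ph_control",
    demand = demandModel("proportional_titration", gain = 60, setpoint = 7.0,
                         deadband = 0.1, plant_effect = "base"),
    priority = priorityParams(10, 80, "dynamic_volume"),
    constraints = list(
      constraintSpec("min_pipettable", "hard", "volume", "lower", min_pip),
      constraintSpec("base_volume_ceiling", "soft", "volume", "upper", 60),
      constraintSpec("working_volume_cap", "hard", "fill_level", "upper", 15000)
    ),
    source = "base"
  )

  stages <- list(
    taskSpec("sample_withdraw", "sampling_stage", stage_index = 1L,
             demand = demandModel("time_trigger", event_volume = 500,
                                  plant_effect = "sample"),
             priority = priorityParams(10, 60, "dynamic_time"),
             constraints = list(
               constraintSpec("sampling_interval", "hard", "elapsed_time",
                              "lower", 3600),
               constraintSpec("sampling_ceiling", "soft", "elapsed_time",
                              "upper", 4500)
             )),
    taskSpec("sample_prepare", "sampling_stage", stage_index = 2L,
             predecessor = "sample_withdraw",
             demand = demandModel("time_trigger", event_volume = 100),
             priority = priorityParams(20, 60, "step"),
             target = "sample_mtp", target_mode = "per_sample"),
    taskSpec("sample_to_reader", "sampling_stage", stage_index = 3L,
             predecessor = "sample_prepare",
             demand = demandModel("time_trigger"),
             priority = priorityParams(20, 60, "step"),
             target = "reader", target_mode = "single"),
    taskSpec("sample_read", "sampling_stage", stage_index = 4L,
             predecessor = "sample_to_reader",
             demand = demandModel("time_trigger"),
             priority = priorityParams(20, 60, "step"),
             target = "reader", target_mode = "single"),
    taskSpec("sample_wash", "sampling_stage", stage_index = 5L,
             predecessor = "sample_read",
             demand = demandModel("time_trigger"),
             priority = priorityParams(20, 60, "step"),
             target = "washer", target_mode = "single")
  )

  overheads <- c(feed = 30, ph_control = 30, sample_withdraw = 30,
                 sample_prepare = 30, sample_to_reader = 60,
                 sample_read = 120, sample_wash = 120)

  noise_sd <- if (noise) c(pH = 0.005, DO = 0.3) else c(pH = 0, DO = 0)

  experimentConfig(
    name = name,
    n_reactors = n_reactors,
    lhs_profile = lhsProfile(per_method_overhead = overheads,
                             channel_volume_min = min_pip,
                             deck_sequences = defaultDeck(n_reactors)),
    tasks = c(list(feed, ph), stages, extra_tasks),
    plant = plantParams(noise_sd = noise_sd,
                        malfunction_rate = malfunction_rate),
    clock = list(tick = 10, duration = duration_h * 3600,
                 mode = "event_driven", acquisition_interval = 60),
    seed = seed
  )
}

#' Contention-free single-feed scenario
#'
#' The reference world reduced to its feeding task only, used to verify
#' that realized inter-feed intervals recover the configured minimum
#' interval when nothing competes for the LHS.
#'
#' @inheritParams fedBatchConfig
#' @return An [experimentConfig()] with one feeding task.
#' @export
singleFeedConfig <- function(n_reactors = 48L, duration_h = 8, seed = 1L) {
  cfg <- fedBatchConfig(n_reactors, duration_h, seed, noise = FALSE,
                        name = "single-feed")
  cfg$tasks <- cfg$tasks["feed"]
  validateExperimentConfig(cfg)
}

#' Scheduled abort task
#'
#' A step-priority task that fires once its clock-time window opens and,
#' on completion, triggers the scheduler's termination sequence.
#'
#' @param at Simulated time (s) at which the abort becomes due.
#' @return A [taskSpec()] of class `abort`.
#' @export
abortTask <- function(at) {
  taskSpec(
    "abort", "abort",
    demand = demandModel("time_trigger", once = TRUE),
    priority = priorityParams(100, 100, "step"),
    constraints = list(
      constraintSpec("abort_window", "hard", "clock_time", "lower", at)
    ),
    target = "washer", target_mode = "single"
  )
}

#' Induction task with a fixed execution window
#'
#' Binary-demand task that becomes executable when the clock-time window
#' opens (hard lower bound) and escalates to critical priority past the
#' window's soft end; executes once per reactor.
#'
#' @param start,end Window bounds, simulated seconds.
#' @param volume Inducer volume per reactor, uL.
#' @return A [taskSpec()] of class `induction`.
#' @export
inductionTask <- function(start, end, volume = 50) {
  taskSpec(
    "induction", "induction",
    demand = demandModel("time_trigger", once = TRUE, event_volume = volume),
    priority = priorityParams(30, 90, "step"),
    constraints = list(
      constraintSpec("window_start", "hard", "clock_time", "lower", start),
      constraintSpec("window_end", "soft", "clock_time", "upper", end)
    ),
    source = "substrate"
  )
}
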