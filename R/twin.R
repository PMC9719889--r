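#' Physical profile of the liquid handling station
#'
#' Declares what the pipetting robot can do: number of parallel channels,
#' the per-channel volume range, the timing model (a per-method overhead
#' plus a fixed duration per pipetting cycle, where one cycle serves up to
#' `n_channels` targets), and the deck layout as named position sequences.
#' Defaults describe an eight-channel 1000 uL instrument.
#'
#' @param n_channels Parallel pipetting channels (default 8).
#' @param channel_volume_max Maximum per-channel volume, uL (default 1000).
#' @param channel_volume_min Minimum pipettable volume, uL (default 5);
#'   zero-volume entries (pure transport steps) are always allowed.
#' @param per_cycle_duration Seconds per pipetting cycle (default 30).
#' @param per_method_overhead Named numeric map of fixed per-method overheads
#'   in seconds (needle wash/disinfection folded in); unlisted methods use
#'   `default_overhead`.
#' @param default_overhead Overhead for methods not in the map (default 30).
#' @param jitter_sdlog sdlog of an optional lognormal duration multiplier;
#'   0 disables jitter (default).
#' @param deck_sequences Named list of character position vectors; defaults
#'   to a 48-reactor deck with sample MTP, reader, washer, substrate and
#'   base container positions.
#' @return An object of class `lhsProfile`.
#' @export
lhsProfile <- function(n_channels = 8L, channel_volume_max = 1000,
                       channel_volume_min = 5, per_cycle_duration = 30,
                       per_method_overhead = numeric(0),
                       default_overhead = 30, jitter_sdlog = 0,
                       deck_sequences = defaultDeck()) {
  stopifnot(n_channels >= 1, per_cycle_duration >= 0, default_overhead >= 0,
            jitter_sdlog >= 0)
  if (channel_volume_min >= channel_volume_max)
    stop("channel_volume_min must be below channel_volume_max", call. = FALSE)
  if (!is.list(deck_sequences) || is.null(names(deck_sequences)))
    stop("deck_sequences must be a named list of position vectors",
         call. = FALSE)
  structure(
    list(n_channels = as.integer(n_channels),
         channel_volume_max = channel_volume_max,
         channel_volume_min = channel_volume_min,
         per_cycle_duration = per_cycle_duration,
         per_method_overhead = per_method_overhead,
         default_overhead = default_overhead,
         jitter_sdlog = jitter_sdlog,
         deck_sequences = deck_sequences),
    class = "lhsProfile"
  )
}

#' Default deck layout for a 48-reactor setup
#'
#' @param n_reactors Number of reactor positions (default 48).
#' @return Named list of position-name vectors.
#' @export
defaultDeck <- function(n_reactors = 48L) {
  list(
    reactors   = sprintf("R%02d", seq_len(n_reactors)),
    sample_mtp = sprintf("MTP%02d", seq_len(96L)),
    reader     = "READER1",
    washer     = "WASHER1",
    substrate  = sprintf("SUB%d", 1:2),
    base       = sprintf("NAOH%d", 1:2)
  )
}

#' Construct an LHS dispatch command
#'
#' The minimal message the scheduler sends for execution: a method name, an
#' ordered volume array and the ordered target (and optionally source)
#' position sequence, mapped to the deck's labware definitions.
#'
#' @param method_name LHS method to invoke.
#' @param volumes Ordered numeric volumes, uL (0 allowed for transport-only
#'   steps).
#' @param target_sequence Ordered character vector of deck position names.
#' @param source_sequence Optional ordered source positions (recycled if
#'   shorter is not allowed; must match length when given).
#' @param reactors Optional integer vector: the reactor positions this
#'   command services (for bookkeeping when targets are not reactor
#'   positions, e.g. sample-plate wells).
#' @return An object of class `lhsCommand`.
#' @export
lhsCommand <- function(method_name, volumes, target_sequence,
                       source_sequence = NULL, reactors = NULL) {
  structure(
    list(method_name = as.character(method_name),
         volumes = as.numeric(volumes),
         target_sequence = as.character(target_sequence),
         source_sequence = if (!is.null(source_sequence))
           as.character(source_sequence),
         reactors = if (!is.null(reactors)) as.integer(reactors)),
    class = "lhsCommand"
  )
}

#' @export
print.lhsCommand <- function(x, ...) {
  cat(sprintf("<lhsCommand> %s: %d target(s), volumes %s uL\n",
              x$method_name, length(x$target_sequence),
              paste(utils::head(format(x$volumes, trim = TRUE), 4L),
                    collapse = ", ")))
  invisible(x)
}

#' Create the digital twin of the liquid handling station
#'
#' The twin merges the paper's broker and simulator roles: it receives
#' dispatch commands, checks them against the declared labware and physical
#' limits (and, when given the experiment configuration, against the user's
#' specification, e.g. recomputing expected feed volumes), emulates
#' execution time with the cycle-batched duration model, and publishes
#' busy/idle availability transitions.
#'
#' @param profile An [lhsProfile()].
#' @param config Optional experiment configuration; enables specification
#'   checks such as the miscalculated-feed-volume finding.
#' @return A twin handle (environment of class `lhsTwin`).
#' @export
createLHSTwin <- function(profile, config = NULL) {
  twin <- new.env(parent = emptyenv())
  twin$profile <- profile
  twin$config <- config
  twin$busy_until <- -Inf
  twin$events <- list()       # list of (time, state)
  twin$findings <- list()     # discrepancy log entries
  twin$closed <- FALSE
  class(twin) <- "lhsTwin"
  twin
}

.twinKnownPositions <- function(profile) {
  unlist(profile$deck_sequences, use.names = FALSE)
}

#' Validate a command against the LHS profile and the user specification
#'
#' Findings are data, not errors: they are returned (and logged by the
#' scheduler into the discrepancy log). Findings about unknown methods or
#' positions, out-of-range volumes and length mismatches are *blocking* —
#' the command must not execute; a miscalculated feed volume (delivered
#' volume differing from what the configured feed profile prescribes at
#' dispatch time) is recorded but does not block.
#'
#' @param cmd An [lhsCommand()].
#' @param profile An [lhsProfile()].
#' @param config Optional experiment configuration for specification checks.
#' @param now Simulated dispatch time (s), used for specification checks.
#' @return A character vector of findings (empty when valid) with a logical
#'   attribute `"blocking"` of the same length.
#' @export
validateCommand <- function(cmd, profile, config = NULL, now = 0) {
  msgs <- character(0)
  blocking <- logical(0)
  add <- function(msg, block = TRUE) {
    msgs <<- c(msgs, msg)
    blocking <<- c(blocking, block)
  }

  if (length(cmd$target_sequence) == 0L)
    add("empty target sequence: nothing to execute")
  if (length(cmd$volumes) != length(cmd$target_sequence))
    add(sprintf("length mismatch: %d volumes for %d targets",
                length(cmd$volumes), length(cmd$target_sequence)))
  if (!is.null(cmd$source_sequence) &&
      length(cmd$source_sequence) != length(cmd$target_sequence))
    add(sprintf("length mismatch: %d sources for %d targets",
                length(cmd$source_sequence), length(cmd$target_sequence)))

  known <- .twinKnownPositions(profile)
  unknown <- setdiff(unique(c(cmd$target_sequence, cmd$source_sequence)),
                     known)
  for (p in unknown) add(sprintf("unknown position '%s'", p))

  if (!is.null(config)) {
    methods_known <- vapply(config$tasks, function(t) t$method_name,
                            character(1))
    if (!cmd$method_name %in% methods_known)
      add(sprintf("unknown method '%s'", cmd$method_name))
  }

  nonzero <- cmd$volumes[!is.na(cmd$volumes) & cmd$volumes > 0]
  if (any(nonzero < profile$channel_volume_min))
    add(sprintf("volume below channel minimum (%g uL)",
                profile$channel_volume_min))
  if (any(nonzero > profile$channel_volume_max))
    add(sprintf("volume exceeds channel maximum (%g uL)",
                profile$channel_volume_max))
  if (anyNA(cmd$volumes) || any(cmd$volumes < 0))
    add("negative or missing volume")

  # specification check: recompute the feed volume the user script
  # prescribes at this time and flag miscalculations (non-blocking)
  if (!is.null(config)) {
    spec <- NULL
    for (t in config$tasks)
      if (t$method_name == cmd$method_name && t$task_class == "feeding")
        spec <- t
    if (!is.null(spec)) {
      expected <- .expectedFeedVolume(spec$demand, now, profile)
      off <- abs(cmd$volumes - expected) > 1e-6 & cmd$volumes > 0
      if (any(off))
        add(sprintf(
          "miscalculated feeding volume: got %.6g uL, user script prescribes %.6g uL",
          cmd$volumes[which(off)[1L]], expected), block = FALSE)
    }
  }

  structure(msgs, blocking = blocking)
}

# The feed volume the user script prescribes at time `now` (uL), clamped to
# the pipettable range like the demand model itself.
.expectedFeedVolume <- function(demand, now, profile) {
  v <- switch(demand$kind,
    constant_volume = demand$parameters$volume,
    exponential_feed = demand$parameters$base_volume *
      exp(demand$parameters$mu_set * now / 3600),
    return(NA_real_)
  )
  min(v, profile$channel_volume_max)
}

#' Execute a validated command on the twin
#'
#' Emulates the execution time as a per-method overhead plus one
#' `per_cycle_duration` per batch of up to `n_channels` targets, optionally
#' scaled by a seeded lognormal jitter multiplier. The twin is busy for the
#' whole interval and publishes a busy and an idle availability event.
#' Liquid transfers are applied to the plant by the scheduler when the
#' execution completes.
#'
#' @param twin A [createLHSTwin()] handle.
#' @param cmd An [lhsCommand()]; must have passed [validateCommand()] with
#'   no blocking finding.
#' @param now Simulated start time (s).
#' @param findings Findings already collected for this command (persisted
#'   into the execution record).
#' @return An `executionRecord`: the command, `start_time`, `end_time`,
#'   `serviced_reactors`, `delivered_volumes` and `validation_findings`.
#' @export
executeCommand <- function(twin, cmd, now, findings = character(0)) {
  if (twin$closed) stop("twin is shut down", call. = FALSE)
  if (now < twin$busy_until)
    stop("LHS twin is busy until t=", twin$busy_until,
         "; overlapping dispatch indicates a scheduler bug", call. = FALSE)
  if (length(cmd$target_sequence) == 0L)
    stop("refusing to execute an empty command", call. = FALSE)

  prof <- twin$profile
  overhead <- unname(prof$per_method_overhead[cmd$method_name])
  if (length(overhead) != 1L || is.na(overhead))
    overhead <- prof$default_overhead
  cycles <- ceiling(length(cmd$target_sequence) / prof$n_channels)
  duration <- overhead + cycles * prof$per_cycle_duration
  if (prof$jitter_sdlog > 0)
    duration <- duration * stats::rlnorm(1L, 0, prof$jitter_sdlog)

  end <- now + duration
  twin$busy_until <- end
  twin$events <- c(twin$events, list(list(time = now, state = "busy"),
                                     list(time = end, state = "idle")))
  structure(
    list(command = cmd, start_time = now, end_time = end,
         serviced_reactors = if (!is.null(cmd$reactors)) cmd$reactors
                             else integer(0),
         delivered_volumes = cmd$volumes,
         validation_findings = as.character(findings)),
    class = "executionRecord"
  )
}

#' @export
print.executionRecord <- function(x, ...) {
  cat(sprintf("<executionRecord> %s [%g, %g] s, %d reactor(s)\n",
              x$command$method_name, x$start_time, x$end_time,
              length(x$serviced_reactors)))
  invisible(x)
}

#' Availability transitions published by the twin
#'
#' Every idle->busy and busy->idle transition with its simulated timestamp,
#' in publication order (timestamps are non-decreasing).
#'
#' @param twin A twin handle.
#' @return A `data.frame` with columns `time` and `state`.
#' @export
availabilityEvents <- function(twin) {
  if (twin$closed && length(twin$events) == 0L)
    stop("availability stream is closed", call. = FALSE)
  if (length(twin$events) == 0L)
    return(data.frame(time = numeric(0), state = character(0)))
  data.frame(
    time = vapply(twin$events, `[[`, numeric(1), "time"),
    state = vapply(twin$events, `[[`, character(1), "state")
  )
}

# Record discrepancy-log entries (one line per finding).
.twinLogFindings <- function(twin, now, method, findings) {
  for (f in findings)
    twin$findings <- c(twin$findings,
                       list(list(time = now, method = method, finding = f)))
  invisible(twin)
}

#' Discrepancy log of the twin
#'
#' @param twin A twin handle.
#' @return A `data.frame` with columns `time`, `method`, `finding`; zero
#'   rows for a clean run.
#' @export
twinFindings <- function(twin) {
  if (length(twin$findings) == 0L)
    return(data.frame(time = numeric(0), method = character(0),
                      finding = character(0)))
  data.frame(
    time = vapply(twin$findings, `[[`, numeric(1), "time"),
    method = vapply(twin$findings, `[[`, character(1), "method"),
    finding = vapply(twin$findings, `[[`, character(1), "finding")
  )
}

#' @export
print.lhsTwin <- function(x, ...) {
  cat(sprintf("<lhsTwin> %d channel(s), busy until t=%s, %d finding(s)%s\n",
              x$profile$n_channels,
              if (is.finite(x$busy_until)) format(x$busy_until) else "-",
              length(x$findings), if (x$closed) " (shut down)" else ""))
  invisible(x)
}
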