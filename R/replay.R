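#' Load a persisted run directory
#'
#' @param dir A [runExperiment()] run directory.
#' @return List: `points` (the full datastore as a point table),
#'   `dispatches` (data.frame of the dispatch log), `findings`
#'   (discrepancy-log lines), `metadata` (resolved configuration).
#' @export
loadRunDir <- function(dir) {
  disp_file <- file.path(dir, "dispatch_log.jsonl")
  disp <- if (file.size(disp_file) > 0) {
    recs <- lapply(readLines(disp_file), jsonlite::fromJSON,
                   simplifyVector = TRUE)
    data.frame(
      task = vapply(recs, `[[`, character(1), "task"),
      start_time = vapply(recs, `[[`, numeric(1), "start_time"),
      end_time = vapply(recs, `[[`, numeric(1), "end_time")
    )
  } else {
    data.frame(task = character(0), start_time = numeric(0),
               end_time = numeric(0))
  }
  list(
    points = importPoints(file.path(dir, "datastore.jsonl"), "jsonl"),
    dispatches = disp,
    findings = readLines(file.path(dir, "discrepancy.log")),
    metadata = loadRunMetadata(file.path(dir, "metadata.json"))
  )
}

#' Greedy-replay verification of a run
#'
#' Independent oracle for the scheduler: re-derives the dispatch sequence
#' from the persisted priority log alone — at every report timestamp at
#' which the LHS was available, the task with the highest positive priority
#' must have been dispatched, ties broken by the older per-reactor last
#' execution and then by declaration order (both persisted as fields of
#' every priority point). Busy windows are taken from the actual records'
#' end times; ticks occupied by a rejected dispatch are skipped. The
#' re-derived (time, task) sequence must reproduce the dispatch log
#' exactly.
#'
#' @param run An `lhsRun`, or the path of a persisted run directory.
#' @return List: `match` (logical), `expected` and `actual` dispatch
#'   data.frames, and `first_mismatch` (row index, or `NA`).
#' @export
replayDispatches <- function(run) {
  if (is.character(run)) {
    rd <- loadRunDir(run)
    points <- rd$points
    actual <- rd$dispatches
  } else {
    points <- .dsTable(run$state$ds)
    actual <- dispatchLog(run)[, c("task", "start_time", "end_time")]
  }
  pr <- points[points$measurement == "priority", ]
  rejected <- unique(points$timestamp[points$measurement ==
                                        "dispatch_rejected"])

  exp_task <- character(0)
  exp_time <- numeric(0)
  busy_until <- -Inf
  mismatch <- NA_integer_
  di <- 0L

  for (t in sort(unique(pr$timestamp))) {
    if (t < busy_until) next
    rows <- pr[pr$timestamp == t, ]
    if (max(rows$value) <= 0) next
    if (t %in% rejected) next
    ord <- order(-rows$value, rows$oldest_last_exec, rows$task_index)
    pick <- rows$task[ord[1L]]
    di <- di + 1L
    exp_task[di] <- pick
    exp_time[di] <- t
    if (di > nrow(actual) || actual$task[di] != pick ||
        actual$start_time[di] != t) {
      mismatch <- di
      break
    }
    busy_until <- actual$end_time[di]
  }

  match <- is.na(mismatch) && di == nrow(actual)
  if (is.na(mismatch) && di != nrow(actual)) mismatch <- di + 1L
  list(match = match,
       expected = data.frame(task = exp_task, start_time = exp_time),
       actual = actual,
       first_mismatch = mismatch)
}
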