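#' Build a batch of time-series points
#'
#' A point consists of a measurement name, a timestamp (simulated seconds
#' since experiment start), tags (`experiment`, `reactor`, `task`) and one
#' or more named numeric fields. A point is unique by (measurement,
#' timestamp, tags); writing the same key again overwrites. Batches are
#' plain `data.table`s with one row per point; extra named numeric vectors
#' become additional field columns.
#'
#' @param measurement Character, the measurement name(s).
#' @param timestamp Numeric timestamps (s).
#' @param experiment Experiment-name tag.
#' @param reactor Integer reactor-position tag, `NA` for task-level points.
#' @param task Task-name tag, `NA` for sensor points.
#' @param value Primary numeric field.
#' @param ... Further named numeric field vectors.
#' @return A `data.table` point batch; inputs are recycled to the longest.
#' @export
pointBatch <- function(measurement, timestamp, experiment = "sim",
                       reactor = NA_integer_, task = NA_character_,
                       value = NA_real_, ...) {
  cols <- list(measurement = as.character(measurement),
               timestamp = as.numeric(timestamp),
               experiment = as.character(experiment),
               reactor = as.integer(reactor),
               task = as.character(task),
               value = as.numeric(value), ...)
  n <- max(lengths(cols))
  data.table::setDT(lapply(cols, rep_len, n))[]
}

.DS_KEY <- c("measurement", "timestamp", "experiment", "reactor", "task")
.DS_TAGS <- c("experiment", "reactor", "task")

.dsKeyString <- function(batch) {
  do.call(paste, c(unname(as.list(batch[, .DS_KEY, with = FALSE])),
                   sep = "\x1f"))
}

#' Open a file-backed time-series datastore
#'
#' An append-log store with an in-memory index: points are buffered as they
#' are written, deduplicated by their unique key (last write wins) when
#' queried, and flushed to a JSON-lines file on [closeDatastore()]. One
#' store serves one experiment run.
#'
#' @param path Optional path of the JSON-lines log written on close.
#' @return A datastore handle (environment of class `tsDatastore`).
#' @export
openDatastore <- function(path = NULL) {
  ds <- new.env(parent = emptyenv())
  ds$path <- path
  ds$buffer <- vector("list", 256L)
  ds$n_batches <- 0L
  ds$keys <- new.env(parent = emptyenv(), size = 65536L)
  ds$table <- NULL
  ds$dirty <- FALSE
  ds$closed <- FALSE
  class(ds) <- "tsDatastore"
  ds
}

#' Write a batch of points
#'
#' @param ds A [openDatastore()] handle.
#' @param batch A [pointBatch()].
#' @return Invisibly, the number of *new* unique keys written; rewriting an
#'   existing key overwrites the stored point and counts zero.
#' @export
writePoints <- function(ds, batch) {
  if (ds$closed) stop("datastore is closed", call. = FALSE)
  if (is.null(batch) || nrow(batch) == 0L) return(invisible(0L))
  keys <- .dsKeyString(batch)
  new <- 0L
  for (k in unique(keys)) {
    if (!exists(k, envir = ds$keys, inherits = FALSE)) {
      assign(k, TRUE, envir = ds$keys)
      new <- new + 1L
    }
  }
  ds$n_batches <- ds$n_batches + 1L
  if (ds$n_batches > length(ds$buffer))
    length(ds$buffer) <- 2L * length(ds$buffer)
  ds$buffer[[ds$n_batches]] <- batch
  ds$dirty <- TRUE
  invisible(new)
}

# Collapse the buffer: dedup by key keeping the last write, sort by
# timestamp then reactor tag (then measurement/task for a total order).
.dsTable <- function(ds) {
  if (ds$dirty) {
    dt <- data.table::rbindlist(ds$buffer[seq_len(ds$n_batches)],
                                fill = TRUE, use.names = TRUE)
    dt <- dt[!duplicated(.dsKeyString(dt), fromLast = TRUE)]
    data.table::setorderv(dt, c("timestamp", "reactor", "measurement", "task"),
                          na.last = TRUE)
    ds$table <- dt
    ds$dirty <- FALSE
  }
  ds$table
}

#' Query stored points by measurement, tags and time range
#'
#' Returns exactly the points whose measurement matches, whose tags equal
#' every pair in `tags`, and whose timestamp lies in the half-open interval
#' `[start, end)`, sorted by timestamp then reactor tag. An unknown
#' measurement yields an empty result, not an error.
#'
#' @param ds A datastore handle.
#' @param measurement Measurement name, or `NULL` for all.
#' @param tags Named list/vector of tag values that must match exactly
#'   (names among `experiment`, `reactor`, `task`).
#' @param start,end Time range, half-open `[start, end)`.
#' @return A `data.table` of points (possibly zero rows).
#' @export
queryPoints <- function(ds, measurement = NULL, tags = list(),
                        start = -Inf, end = Inf) {
  if (length(start) != 1L || length(end) != 1L || start > end)
    stop("time range must satisfy start <= end", call. = FALSE)
  dt <- .dsTable(ds)
  if (is.null(dt)) return(pointBatch(character(0), numeric(0))[0L])
  keep <- dt$timestamp >= start & dt$timestamp < end
  if (!is.null(measurement)) keep <- keep & dt$measurement == measurement
  if (length(tags)) {
    bad <- setdiff(names(tags), .DS_TAGS)
    if (length(bad))
      stop("unknown tag(s): ", paste(bad, collapse = ", "), call. = FALSE)
    for (tg in names(tags)) {
      col <- dt[[tg]]
      keep <- keep & !is.na(col) & col == tags[[tg]]
    }
  }
  dt[keep]
}

# Fixed, deterministic column order: key/tags first, then `value`, then any
# further field columns alphabetically.
.dsColumnOrder <- function(dt) {
  fields <- setdiff(names(dt), c(.DS_KEY, "value"))
  c("measurement", "timestamp", .DS_TAGS, "value", sort(fields))
}

.jsonEscape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

# One JSON object per row, numbers written with 17 significant digits so a
# re-import reproduces every double bit-exactly (jsonlite's own writer
# rounds to 15).
.jsonlLines <- function(dt) {
  cols <- lapply(names(dt), function(cn) {
    v <- dt[[cn]]
    s <- if (is.character(v)) {
      paste0("\"", .jsonEscape(v), "\"")
    } else if (is.integer(v)) {
      as.character(v)
    } else {
      sprintf("%.17g", v)
    }
    s[is.na(v) | (is.numeric(v) & !is.finite(v))] <- "null"
    paste0("\"", cn, "\":", s)
  })
  paste0("{", do.call(paste, c(cols, sep = ",")), "}")
}

#' Export queried points to CSV or JSON-lines
#'
#' Column order is deterministic (measurement, timestamp, tags, fields) and
#' numeric values are written so that re-importing with [importPoints()]
#' reproduces the queried points exactly.
#'
#' @param ds A datastore handle.
#' @param file Output path.
#' @param format `"csv"` or `"jsonl"`.
#' @inheritParams queryPoints
#' @return Invisibly, the number of points exported.
#' @export
exportPoints <- function(ds, file, format = c("csv", "jsonl"),
                         measurement = NULL, tags = list(),
                         start = -Inf, end = Inf) {
  format <- match.arg(format)
  dt <- queryPoints(ds, measurement, tags, start, end)
  ord <- intersect(.dsColumnOrder(dt), names(dt))
  dt <- dt[, ord, with = FALSE]
  if (format == "csv") {
    out <- data.table::copy(dt)
    for (cn in names(out)) {
      if (is.numeric(out[[cn]]) && !is.integer(out[[cn]])) {
        v <- sprintf("%.17g", out[[cn]])
        v[is.na(out[[cn]])] <- ""
        data.table::set(out, j = cn, value = v)
      }
    }
    data.table::fwrite(out, file, quote = TRUE, na = "")
  } else {
    writeLines(.jsonlLines(dt), file)
  }
  invisible(nrow(dt))
}

#' Re-import an exported point file
#'
#' @param file Path of a [exportPoints()] CSV or JSON-lines file.
#' @param format `"csv"` or `"jsonl"`; guessed from the extension by default.
#' @return A `data.table` point batch.
#' @export
importPoints <- function(file, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.jsonl?$", file)) "jsonl" else "csv"
  if (format == "csv") {
    dt <- data.table::fread(file, na.strings = "",
                            colClasses = list(character = "measurement"))
    for (cn in setdiff(names(dt), c(.DS_KEY)))
      if (!is.numeric(dt[[cn]])) data.table::set(dt, j = cn,
                                                 value = as.numeric(dt[[cn]]))
  } else {
    dt <- data.table::setDT(jsonlite::stream_in(file(file), verbose = FALSE))
  }
  if (nrow(dt) == 0L) return(pointBatch(character(0), numeric(0))[0L])
  dt$reactor <- as.integer(dt$reactor)
  dt$timestamp <- as.numeric(dt$timestamp)
  dt$task <- as.character(dt$task)
  dt$experiment <- as.character(dt$experiment)
  dt[]
}

#' Close a datastore, flushing the append log to disk
#'
#' @param ds A datastore handle.
#' @return Invisibly, the path written (or `NULL`).
#' @export
closeDatastore <- function(ds) {
  if (ds$closed) return(invisible(ds$path))
  if (!is.null(ds$path)) {
    dt <- .dsTable(ds)
    if (!is.null(dt) && nrow(dt)) {
      ord <- intersect(.dsColumnOrder(dt), names(dt))
      writeLines(.jsonlLines(dt[, ord, with = FALSE]), ds$path)
    } else {
      file.create(ds$path)
    }
  }
  ds$closed <- TRUE
  invisible(ds$path)
}

#' @export
print.tsDatastore <- function(x, ...) {
  nrows <- if (is.null(.dsTable(x))) 0L else nrow(.dsTable(x))
  cat(sprintf("<tsDatastore> %d points%s%s\n", nrows,
              if (!is.null(x$path)) paste0(" -> ", x$path) else "",
              if (x$closed) " (closed)" else ""))
  invisible(x)
}
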