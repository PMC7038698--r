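#' Parse CASAS-dialect sensor event lines
#'
#' Smart-home testbeds of the CASAS family log one sensor event per line:
#' a date, a time (with optional fractional seconds), a sensor id, a message
#' (a binary state such as `ON`/`OFF`/`OPEN`/`CLOSE` or a numeric reading),
#' and optionally an activity annotation — a label followed by a `begin` or
#' `end` marker. Labels may contain spaces ("Wash Dinner Dishes"): everything
#' between the message field and the final marker token is the label.
#'
#' Messages are classified as categorical iff they are one of the four state
#' tokens (case-insensitive); anything else must parse as a number. Events are
#' expected in non-decreasing time order; violations are reported with a
#' warning, never silently reordered.
#'
#' @param lines Character vector, one event per element. Blank lines are
#'   skipped.
#' @param field_order Order of the four mandatory fields at the start of each
#'   line. Permutations of `c("date", "time", "sensor", "message")` cover
#'   minor dialect drift; any annotation always trails the mandatory fields.
#' @return A tibble with one row per event: `line` (source line number),
#'   `date`, `time` (verbatim strings, so writing is lossless), `timestamp`
#'   (POSIXct, UTC), `sensor_id`, `message`, `message_type` (`"categorical"`
#'   or `"numeric"`), `value` (numeric reading, `NA` for categorical events),
#'   `activity` and `marker` (`NA` when the line carries no annotation).
#' @seealso [read_casas_events()], [write_casas_events()],
#'   [segment_activity_instances()]
#' @examples
#' parse_casas_events(c(
#'   "2012-07-18 13:47:05.20 M012 ON",
#'   "2012-07-18 13:47:06.95 D002 OPEN Bathe begin"
#' ))
#' @export
parse_casas_events <- function(lines,
                               field_order = c("date", "time", "sensor", "message")) {
  stopifnot(is.character(lines))
  if (!setequal(field_order, c("date", "time", "sensor", "message")) ||
      length(field_order) != 4) {
    abort("`field_order` must be a permutation of date, time, sensor, message.")
  }
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) {
    return(empty_events())
  }
  fields <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  n_fields <- lengths(fields)
  if (any(n_fields < 4)) {
    bad <- keep[which(n_fields < 4)[1]]
    abort(sprintf("line %d: expected at least 4 whitespace-delimited fields, got %d.",
                  bad, n_fields[which(n_fields < 4)[1]]))
  }

  pick <- function(name) {
    idx <- match(name, field_order)
    vapply(fields, `[[`, character(1), idx)
  }
  date_s <- pick("date")
  time_s <- pick("time")
  sensor <- pick("sensor")
  message_s <- pick("message")

  bad_date <- !grepl("^\\d{4}-\\d{2}-\\d{2}$", date_s)
  if (any(bad_date)) {
    abort(sprintf("line %d: malformed date '%s' (expected YYYY-MM-DD).",
                  keep[which(bad_date)[1]], date_s[which(bad_date)[1]]))
  }
  bad_time <- !grepl("^\\d{2}:\\d{2}:\\d{2}(\\.\\d+)?$", time_s)
  if (any(bad_time)) {
    abort(sprintf("line %d: malformed time '%s' (expected HH:MM:SS[.fff]).",
                  keep[which(bad_time)[1]], time_s[which(bad_time)[1]]))
  }
  timestamp <- as.POSIXct(paste(date_s, time_s), tz = "UTC",
                          format = "%Y-%m-%d %H:%M:%OS")
  if (anyNA(timestamp)) {
    abort(sprintf("line %d: timestamp '%s %s' does not parse.",
                  keep[which(is.na(timestamp))[1]],
                  date_s[which(is.na(timestamp))[1]],
                  time_s[which(is.na(timestamp))[1]]))
  }

  categorical <- toupper(message_s) %in% c("ON", "OFF", "OPEN", "CLOSE")
  value <- rep(NA_real_, length(message_s))
  value[!categorical] <- suppressWarnings(as.numeric(message_s[!categorical]))
  bad_msg <- !categorical & is.na(value)
  if (any(bad_msg)) {
    abort(sprintf(
      "line %d: message '%s' is neither a state token (ON/OFF/OPEN/CLOSE) nor numeric.",
      keep[which(bad_msg)[1]], message_s[which(bad_msg)[1]]))
  }

  activity <- rep(NA_character_, length(keep))
  marker <- rep(NA_character_, length(keep))
  annotated <- which(n_fields >= 5)
  for (i in annotated) {
    extra <- fields[[i]][5:n_fields[i]]
    mk <- tolower(extra[length(extra)])
    if (!mk %in% c("begin", "end")) {
      abort(sprintf("line %d: unknown annotation marker '%s' (expected begin or end).",
                    keep[i], extra[length(extra)]))
    }
    if (length(extra) < 2) {
      abort(sprintf("line %d: annotation marker '%s' without an activity label.",
                    keep[i], mk))
    }
    activity[i] <- paste(extra[-length(extra)], collapse = " ")
    marker[i] <- mk
  }

  out <- tibble::tibble(
    line = keep,
    date = date_s,
    time = time_s,
    timestamp = timestamp,
    sensor_id = sensor,
    message = message_s,
    message_type = ifelse(categorical, "categorical", "numeric"),
    value = value,
    activity = activity,
    marker = marker
  )

  backwards <- which(diff(as.numeric(out$timestamp)) < 0)
  if (length(backwards) > 0) {
    warn(sprintf(
      "events go backwards in time at line(s) %s; order kept as read.",
      paste(out$line[backwards + 1][seq_len(min(5, length(backwards)))],
            collapse = ", ")))
  }
  out
}

empty_events <- function() {
  tibble::tibble(
    line = integer(), date = character(), time = character(),
    timestamp = as.POSIXct(character(), tz = "UTC"),
    sensor_id = character(), message = character(),
    message_type = character(), value = double(),
    activity = character(), marker = character()
  )
}

#' Read a CASAS-dialect event log file
#'
#' @param path Path to a plain-text event log.
#' @inheritParams parse_casas_events
#' @return A tibble of events; see [parse_casas_events()].
#' @export
read_casas_events <- function(path,
                              field_order = c("date", "time", "sensor", "message")) {
  parse_casas_events(readLines(path, warn = FALSE), field_order = field_order)
}

#' Serialize events back to CASAS-dialect lines
#'
#' Uses the verbatim `date`/`time` strings retained at parse time, so a
#' parse–write–parse round trip reproduces the event table exactly.
#'
#' @param events Event tibble from [parse_casas_events()].
#' @param path Optional file path; when `NULL` the lines are returned.
#' @inheritParams parse_casas_events
#' @return Invisibly (or visibly when `path` is `NULL`) the character vector
#'   of formatted lines.
#' @export
write_casas_events <- function(events, path = NULL,
                               field_order = c("date", "time", "sensor", "message")) {
  cols <- list(date = events$date, time = events$time,
               sensor = events$sensor_id, message = events$message)
  lines <- paste(cols[[field_order[1]]], cols[[field_order[2]]],
                 cols[[field_order[3]]], cols[[field_order[4]]])
  ann <- !is.na(events$marker)
  lines[ann] <- paste(lines[ann], events$activity[ann], events$marker[ann])
  if (is.null(path)) {
    return(lines)
  }
  writeLines(lines, path)
  invisible(lines)
}

#' Segment annotated events into labeled activity instances
#'
#' Pairs each `begin` annotation with the next `end` annotation carrying the
#' same label (most-recent-first when the same label is nested). An instance
#' contains exactly the events whose timestamps fall between its begin and
#' end annotations, inclusive — so during interleaved activities an event can
#' belong to more than one instance. Unmatched `begin`/`end` annotations are
#' reported with a warning and skipped.
#'
#' @param events Event tibble from [parse_casas_events()], time-ordered.
#' @return A tibble with one row per matched begin/end pair, in order of the
#'   begin annotation: `instance_id`, `label`, `start`, `end`, `n_events`,
#'   and `events` (a list column holding each instance's event tibble).
#' @export
segment_activity_instances <- function(events) {
  if (nrow(events) == 0) {
    return(empty_instances())
  }
  open <- list()   # label -> integer stack of open begin row indices
  pairs_begin <- integer()
  pairs_end <- integer()
  orphans <- integer()
  for (i in seq_len(nrow(events))) {
    mk <- events$marker[i]
    if (is.na(mk)) next
    lab <- events$activity[i]
    if (mk == "begin") {
      open[[lab]] <- c(open[[lab]], i)
    } else {
      stack <- open[[lab]]
      if (is.null(stack) || length(stack) == 0) {
        orphans <- c(orphans, i)
      } else {
        j <- stack[length(stack)]
        open[[lab]] <- stack[-length(stack)]
        pairs_begin <- c(pairs_begin, j)
        pairs_end <- c(pairs_end, i)
      }
    }
  }
  unopened <- unlist(open, use.names = FALSE)
  if (length(orphans) > 0 || length(unopened) > 0) {
    warn(sprintf(
      "skipped unmatched annotations at line(s) %s.",
      paste(sort(events$line[c(orphans, unopened)]), collapse = ", ")))
  }
  if (length(pairs_begin) == 0) {
    return(empty_instances())
  }
  ord <- order(pairs_begin)
  pairs_begin <- pairs_begin[ord]
  pairs_end <- pairs_end[ord]
  slices <- purrr::map2(pairs_begin, pairs_end, function(b, e) {
    events[events$timestamp >= events$timestamp[b] &
             events$timestamp <= events$timestamp[e], , drop = FALSE]
  })
  tibble::tibble(
    instance_id = seq_along(pairs_begin),
    label = events$activity[pairs_begin],
    start = events$timestamp[pairs_begin],
    end = events$timestamp[pairs_end],
    n_events = vapply(slices, nrow, integer(1)),
    events = slices
  )
}

empty_instances <- function() {
  tibble::tibble(
    instance_id = integer(), label = character(),
    start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"),
    n_events = integer(), events = list()
  )
}
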