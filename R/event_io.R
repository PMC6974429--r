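#' Agonistic-interaction event logs
#'
#' An event log couples a per-pen roster with an ordered table of agonistic
#' interactions.  Each interaction records which animal initiated and which
#' received the attack, who won and who lost, the observation day and clock
#' time of the fight start, and its duration in seconds.  The winner/loser
#' pair must equal the initiator/receiver pair (only fights with a clear
#' outcome are analysed), and every animal must belong to the roster of its
#' pen.
#'
#' @param events data frame with columns `pen_id`, `initiator`, `receiver`,
#'   `winner`, `loser` (character), `day` (integer >= 1), `clock_time`
#'   (minutes after midnight) and `duration_s` (seconds >= 0).
#' @param roster named list: one character vector of animal ids per pen.
#' @param schedule optional [obs_schedule] the events were observed under.
#' @param check_schedule if `TRUE`, every event must fall inside a schedule
#'   block.
#' @return An object of class `event_log` with elements `events`, `roster`
#'   and `schedule`; events are sorted by pen, day and clock time.
#' @export
event_log <- function(events, roster, schedule = NULL, check_schedule = !is.null(schedule)) {
  cols <- c("pen_id", "initiator", "receiver", "winner", "loser",
            "day", "clock_time", "duration_s")
  if (!all(cols %in% names(events)))
    stop("events is missing column(s): ", paste(setdiff(cols, names(events)), collapse = ", "))
  events <- as.data.frame(events)[cols]
  for (col in c("pen_id", "initiator", "receiver", "winner", "loser"))
    events[[col]] <- as.character(events[[col]])
  events$day <- as.integer(events$day)
  if (!is.null(names(roster)) || length(roster) == 0) roster <- as.list(roster)
  else stop("roster must be a named list of animal-id vectors")
  roster <- lapply(roster, as.character)

  validate_events(events, roster, schedule, check_schedule)
  ord <- order(events$pen_id, events$day, events$clock_time, method = "radix")
  events <- events[ord, , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, roster = roster, schedule = schedule),
            class = "event_log")
}

validate_events <- function(events, roster, schedule, check_schedule, line = NULL) {
  where <- function(i) if (is.null(line)) paste0("event ", i) else paste0("line ", line[i])
  n <- nrow(events)
  if (n == 0L) return(invisible(TRUE))
  bad <- which(events$initiator == events$receiver)
  if (length(bad))
    stop(where(bad[1L]), ": initiator equals receiver ('", events$initiator[bad[1L]], "')")
  ok_outcome <- (events$winner == events$initiator & events$loser == events$receiver) |
                (events$winner == events$receiver & events$loser == events$initiator)
  if (any(!ok_outcome))
    stop(where(which(!ok_outcome)[1L]),
         ": winner/loser do not match initiator/receiver")
  if (anyNA(events$day) || any(events$day < 1L))
    stop(where(which(is.na(events$day) | events$day < 1L)[1L]), ": day must be an integer >= 1")
  if (anyNA(events$clock_time) || any(events$clock_time < 0) || any(events$clock_time >= 24 * 60))
    stop("clock_time must lie in [0, 1440) minutes")
  if (anyNA(events$duration_s) || any(events$duration_s < 0))
    stop("duration_s must be >= 0")
  unknown_pen <- setdiff(unique(events$pen_id), names(roster))
  if (length(unknown_pen))
    stop("pen(s) not in roster: ", paste(unknown_pen, collapse = ", "))
  for (pen in unique(events$pen_id)) {
    ev <- events[events$pen_id == pen, c("initiator", "receiver")]
    missing_animal <- setdiff(unique(c(ev$initiator, ev$receiver)), roster[[pen]])
    if (length(missing_animal))
      stop("animal(s) not in roster of pen ", pen, ": ",
           paste(missing_animal, collapse = ", "))
  }
  if (check_schedule) {
    if (is.null(schedule)) stop("check_schedule = TRUE but no schedule given")
    out <- !in_schedule(schedule, events$day, events$clock_time)
    if (any(out))
      stop(where(which(out)[1L]), ": event time outside the observation schedule")
  }
  invisible(TRUE)
}

#' @export
print.event_log <- function(x, ...) {
  cat("Agonistic event log:", nrow(x$events), "events,",
      length(x$roster), "pen(s),",
      sum(lengths(x$roster)), "animals\n")
  if (!is.null(attr(x, "n_dropped")))
    cat("  (", attr(x, "n_dropped"), " row(s) without a clear outcome were dropped on read)\n", sep = "")
  invisible(x)
}

parse_clock <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  hm <- grepl("^\\d{1,2}:\\d{2}$", x)
  out[hm] <- as.numeric(sub(":.*", "", x[hm])) * 60 + as.numeric(sub(".*:", "", x[hm]))
  num <- grepl("^\\d{3,4}$", x)
  out[num] <- (as.numeric(x[num]) %/% 100) * 60 + as.numeric(x[num]) %% 100
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) stop("unparseable clock_time value(s): ", paste(unique(x[bad]), collapse = ", "))
  out
}

format_clock <- function(minutes) {
  sprintf("%02d:%02d", as.integer(minutes) %/% 60L, as.integer(minutes) %% 60L)
}

#' Read / write agonistic event logs
#'
#' The on-disk format is a UTF-8 CSV with header columns `pen_id`,
#' `initiator`, `receiver`, `winner`, `loser`, `day`, `clock_time`,
#' `duration_s`.  Clock times are accepted as `HH:MM` strings or `HHMM`
#' integers and always written as `HH:MM`.  Rows without a clear
#' initiator/receiver or winner/loser (empty or missing ids) are dropped and
#' counted — such fights cannot enter the analysis — and the count is
#' reported via [message()] and stored in the `n_dropped` attribute.
#' Structural violations (unknown animals, initiator equal to receiver,
#' outcome pair not matching the contestants) are errors naming the file
#' line.
#'
#' @param file path to a CSV file (or connection for reading).
#' @param roster named list of per-pen animal-id vectors covering every pen
#'   in the file.
#' @param schedule optional [obs_schedule]; with `check_schedule = TRUE`
#'   events outside its blocks are errors.
#' @param check_schedule validate event times against `schedule`.
#' @return `read_event_log()` returns an [event_log];
#'   `write_event_log()` invisibly returns `file`.  Writing then re-reading
#'   reproduces the log exactly.
#' @export
read_event_log <- function(file, roster, schedule = NULL,
                           check_schedule = !is.null(schedule)) {
  raw <- utils::read.csv(file, colClasses = "character", check.names = TRUE)
  cols <- c("pen_id", "initiator", "receiver", "winner", "loser",
            "day", "clock_time", "duration_s")
  if (!all(cols %in% names(raw)))
    stop("event-log file is missing column(s): ",
         paste(setdiff(cols, names(raw)), collapse = ", "))
  raw <- raw[cols]
  line <- seq_len(nrow(raw)) + 1L  # header is line 1

  unclear <- rep(FALSE, nrow(raw))
  for (col in c("initiator", "receiver", "winner", "loser"))
    unclear <- unclear | is.na(raw[[col]]) | trimws(raw[[col]]) == ""
  n_dropped <- sum(unclear)
  if (n_dropped > 0) {
    message("read_event_log: dropped ", n_dropped,
            " row(s) without a clear initiator/receiver and winner/loser")
    raw <- raw[!unclear, , drop = FALSE]
    line <- line[!unclear]
  }

  day <- suppressWarnings(as.integer(raw$day))
  if (anyNA(day) && nrow(raw))
    stop("line ", line[which(is.na(day))[1L]], ": unparseable day value")
  dur <- suppressWarnings(as.numeric(raw$duration_s))
  if (anyNA(dur) && nrow(raw))
    stop("line ", line[which(is.na(dur))[1L]], ": unparseable duration_s value")
  events <- data.frame(pen_id = raw$pen_id, initiator = raw$initiator,
                       receiver = raw$receiver, winner = raw$winner,
                       loser = raw$loser, day = day,
                       clock_time = parse_clock(raw$clock_time),
                       duration_s = dur)
  roster <- lapply(as.list(roster), as.character)
  validate_events(events, roster, schedule, check_schedule, line = line)
  log <- event_log(events, roster, schedule, check_schedule = FALSE)
  attr(log, "n_dropped") <- n_dropped
  log
}

#' @rdname read_event_log
#' @param log an [event_log].
#' @export
write_event_log <- function(log, file) {
  stopifnot(inherits(log, "event_log"))
  out <- log$events
  out$clock_time <- format_clock(out$clock_time)
  utils::write.csv(out, file, row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' Read / write pen rosters
#'
#' Rosters are stored as a two-column CSV (`pen_id`, `animal_id`), one row
#' per animal.
#'
#' @param file path to a CSV file.
#' @return `read_roster()` returns a named list of character vectors.
#' @export
read_roster <- function(file) {
  raw <- utils::read.csv(file, colClasses = "character")
  if (!all(c("pen_id", "animal_id") %in% names(raw)))
    stop("roster file must have columns pen_id, animal_id")
  split(raw$animal_id, raw$pen_id)
}

#' @rdname read_roster
#' @param roster named list of per-pen animal-id vectors.
#' @export
write_roster <- function(roster, file) {
  df <- data.frame(pen_id = rep(names(roster), lengths(roster)),
                   animal_id = unlist(roster, use.names = FALSE))
  utils::write.csv(df, file, row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' Restrict an event log to an expanding time window
#'
#' Keeps the events whose cumulative observed time since mixing is at most
#' `window_hours` (the windows of the temporal analysis are closed on the
#' right: an event starting exactly at the boundary hour is included).  A
#' fight belongs to the window containing its start time.  The roster is
#' never reduced — animals without events in the window become isolated
#' nodes downstream, not missing ones.
#'
#' @param log an [event_log].
#' @param window_hours positive number of observed hours since mixing.
#' @param schedule an [obs_schedule]; defaults to the log's own.
#' @return An [event_log] with the filtered events and the full roster.
#' @export
slice_by_window <- function(log, window_hours, schedule = log$schedule) {
  stopifnot(inherits(log, "event_log"))
  if (is.null(schedule)) stop("no schedule available for windowing")
  if (!is.numeric(window_hours) || length(window_hours) != 1L || window_hours <= 0)
    stop("window_hours must be a single positive number")
  t <- cumulative_observed_hours(schedule, log$events$day, log$events$clock_time)
  keep <- t <= window_hours + 1e-9
  out <- log
  out$events <- log$events[keep, , drop = FALSE]
  rownames(out$events) <- NULL
  attr(out, "n_dropped") <- NULL
  out
}
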