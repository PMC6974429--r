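#' Observation schedules
#'
#' Video observation of freshly mixed pens runs in daytime blocks; the night
#' pause is not observed and does not count towards observed time.  A schedule
#' is an ordered set of non-overlapping blocks, each `(day, start, end)` in
#' whole-or-fractional clock hours, with `day >= 1` and `end > start`.
#'
#' Two presets reflect the usual designs: `"piglets_28h"` observes weaned
#' piglets for 28 h (day 1: 12:00-18:00, days 2-3: 07:00-18:00) and
#' `"fatteners_17h"` observes fattening pigs or gilts for 17 h
#' (day 1: 12:00-18:00, day 2: 07:00-18:00).  Mixing happens at the start of
#' the first block (12:00 on day 1).
#'
#' @param day integer vector of observation days (1-based).
#' @param start,end numeric vectors of clock hours, `0 <= start < end <= 24`.
#' @return An object of class `obs_schedule`: a data frame with columns
#'   `day`, `start`, `end` (hours).
#' @examples
#' sch <- obs_schedule(day = c(1, 2), start = c(12, 7), end = c(18, 18))
#' total_hours(sch)  # 17
#' @export
obs_schedule <- function(day, start, end) {
  if (length(day) == 0L) stop("schedule needs at least one block")
  if (length(start) != length(day) || length(end) != length(day))
    stop("day, start and end must have equal length")
  day <- as.integer(day)
  if (anyNA(day) || anyNA(start) || anyNA(end)) stop("schedule blocks must not contain NA")
  if (any(day < 1L)) stop("block days must be >= 1")
  if (any(end <= start)) stop("each block must have end > start")
  if (any(start < 0) || any(end > 24)) stop("clock hours must lie in [0, 24]")
  sch <- data.frame(day = day, start = start, end = end)
  sch <- sch[order(sch$day, sch$start), , drop = FALSE]
  rownames(sch) <- NULL
  # blocks on the same day must not overlap
  same <- which(diff(sch$day) == 0L)
  if (any(sch$start[same + 1L] < sch$end[same]))
    stop("schedule blocks overlap")
  class(sch) <- c("obs_schedule", "data.frame")
  sch
}

#' @rdname obs_schedule
#' @param name preset name, `"piglets_28h"` or `"fatteners_17h"`.
#' @export
schedule_preset <- function(name = c("piglets_28h", "fatteners_17h")) {
  name <- match.arg(name)
  switch(name,
    piglets_28h   = obs_schedule(day = c(1, 2, 3), start = c(12, 7, 7), end = c(18, 18, 18)),
    fatteners_17h = obs_schedule(day = c(1, 2),    start = c(12, 7),    end = c(18, 18))
  )
}

#' @rdname obs_schedule
#' @param schedule an `obs_schedule`.
#' @export
total_hours <- function(schedule) {
  stopifnot(inherits(schedule, "obs_schedule"))
  sum(schedule$end - schedule$start)
}

#' Observed hours elapsed since mixing
#'
#' Converts a clock time into cumulative observed hours since the start of the
#' first block, skipping unobserved pauses.  The mapping is piecewise linear
#' and non-decreasing: times inside a block accrue linearly, times in a pause
#' sit at the total of all completed blocks.
#'
#' @param schedule an [obs_schedule].
#' @param day integer vector, observation day of each time point.
#' @param clock_time numeric vector, minutes after midnight within `day`.
#' @return Numeric vector of fractional observed hours (0 at mixing).
#' @examples
#' sch <- schedule_preset("piglets_28h")
#' cumulative_observed_hours(sch, 1, 13 * 60)  # 1
#' cumulative_observed_hours(sch, 3, 18 * 60)  # 28
#' cumulative_observed_hours(sch, 2, 7 * 60)   # 6: the night pause is skipped
#' @export
cumulative_observed_hours <- function(schedule, day, clock_time) {
  stopifnot(inherits(schedule, "obs_schedule"))
  if (length(day) != length(clock_time))
    stop("day and clock_time must have equal length")
  day <- as.integer(day)
  t_h <- clock_time / 60
  first <- schedule[1L, ]
  before <- day < first$day | (day == first$day & t_h < first$start)
  if (any(before, na.rm = TRUE))
    stop("time point precedes the start of observation (day ", first$day,
         ", ", sprintf("%02d:%02d", floor(first$start), round(first$start %% 1 * 60)), ")")
  cum <- numeric(length(day))
  for (i in seq_len(nrow(schedule))) {
    b <- schedule[i, ]
    len <- b$end - b$start
    contrib <- ifelse(day > b$day, len,
               ifelse(day == b$day, pmin(pmax(t_h - b$start, 0), len), 0))
    cum <- cum + contrib
  }
  cum
}

# Inverse of cumulative_observed_hours: map observed hours since mixing back to
# (day, clock minutes).  t = 0 is the first block start; a block's right
# boundary maps into that block (day, end).
hours_to_clock <- function(schedule, t) {
  stopifnot(inherits(schedule, "obs_schedule"))
  if (any(t < 0) || any(t > total_hours(schedule) + 1e-9))
    stop("observed hours outside the schedule")
  lens <- schedule$end - schedule$start
  cum_end <- cumsum(lens)
  cum_start <- cum_end - lens
  idx <- findInterval(t, cum_start, rightmost.closed = FALSE)  # block with cum_start <= t
  idx <- pmin(pmax(idx, 1L), nrow(schedule))
  # t exactly at a block's cumulative start belongs to that block except t at
  # the very end, which findInterval already assigns to the last block
  day <- schedule$day[idx]
  minutes <- (schedule$start[idx] + (t - cum_start[idx])) * 60
  data.frame(day = day, clock_time = minutes)
}

# TRUE where (day, clock minutes) lies inside a block (closed at both ends).
in_schedule <- function(schedule, day, clock_time) {
  t_h <- clock_time / 60
  ok <- rep(FALSE, length(day))
  for (i in seq_len(nrow(schedule))) {
    b <- schedule[i, ]
    ok <- ok | (day == b$day & t_h >= b$start - 1e-9 & t_h <= b$end + 1e-9)
  }
  ok
}

#' @export
print.obs_schedule <- function(x, ...) {
  cat("Observation schedule:", total_hours(x), "observed h in", nrow(x), "block(s)\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  day %d: %05.2f-%05.2f h\n", x$day[i], x$start[i], x$end[i]))
  invisible(x)
}
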