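#' Expanding time-window grid
#'
#' The temporal analysis evaluates every parameter on windows of 1, 2, ...,
#' T observed hours, all anchored at mixing (the start of the first
#' observation block), so later windows contain earlier ones.
#'
#' @param schedule an [obs_schedule].
#' @param by window increment in observed hours (default 1, the usual
#'   design).
#' @return Numeric vector of window lengths, `attr(,"schedule")` set.
#' @export
window_grid <- function(schedule, by = 1) {
  stopifnot(inherits(schedule, "obs_schedule"))
  if (by <= 0) stop("window increment must be positive")
  w <- seq(by, total_hours(schedule), by = by)
  attr(w, "schedule") <- schedule
  w
}

#' Network parameters over expanding time windows
#'
#' The core temporal pipeline: for every pen, window length and data-set
#' rule it slices the events observed up to that window, classifies the
#' dyads ([classify_dyads()]), keeps the significant ones
#' ([filter_events()]; `ALL` keeps everything), builds the directed network
#' ([build_network()]) and computes all parameters ([metrics_table()]).
#' Empty windows yield valid edge-less networks, not errors.
#'
#' By default significance labels are recomputed within each window from
#' that window's events (`labels = "per_window"`); `labels = "final"`
#' instead classifies once on the full observation period and applies those
#' labels to every window.
#'
#' @param log an [event_log] covering one cohort.
#' @param schedule an [obs_schedule]; defaults to the log's own.
#' @param windows window lengths in observed hours (default
#'   [window_grid()] of the schedule).
#' @param methods subset of `c("ALL", "PEN", "DYAD")`.
#' @param conf,alpha,interpolate,sides passed to [classify_dyads()].
#' @param labels `"per_window"` or `"final"`.
#' @return An object of class `agonet_windows`: list with long-format data
#'   frames `metrics` (pen x window x method) and `centrality`
#'   (x animal).
#' @export
run_expanding_windows <- function(log, schedule = log$schedule,
                                  windows = window_grid(schedule),
                                  methods = c("ALL", "PEN", "DYAD"),
                                  conf = 0.95, alpha = 0.05,
                                  interpolate = TRUE, sides = c("two", "one"),
                                  labels = c("per_window", "final")) {
  stopifnot(inherits(log, "event_log"))
  if (is.null(schedule)) stop("no schedule available")
  labels <- match.arg(labels)
  sides <- match.arg(sides)
  methods <- match.arg(methods, c("ALL", "PEN", "DYAD"), several.ok = TRUE)
  if (any(windows <= 0)) stop("window lengths must be positive")
  if (max(windows) > total_hours(schedule) + 1e-9)
    stop("window exceeds the schedule's total observed hours")
  windows <- sort(windows)
  pens <- names(log$roster)

  final_labels <- NULL
  if (labels == "final") {
    full_tab <- aggregate_dyads(log)
    final_labels <- lapply(stats::setNames(methods, methods), function(m)
      classify_dyads(full_tab, m, conf = conf, alpha = alpha,
                     interpolate = interpolate, sides = sides))
  }

  metrics_rows <- list()
  centrality_rows <- list()
  for (w in windows) {
    slw <- slice_by_window(log, w, schedule)
    tab_w <- aggregate_dyads(slw)
    for (m in methods) {
      lab <- if (labels == "final") final_labels[[m]]
             else classify_dyads(tab_w, m, conf = conf, alpha = alpha,
                                 interpolate = interpolate, sides = sides)
      ev <- if (m == "ALL") slw else filter_events(slw, lab)
      for (pen in pens) {
        mt <- metrics_table(build_network(ev, pen), dataset = m, window_hours = w)
        metrics_rows[[length(metrics_rows) + 1L]] <- mt$metrics
        centrality_rows[[length(centrality_rows) + 1L]] <- mt$centrality
      }
    }
  }
  out <- list(metrics = do.call(rbind, metrics_rows),
              centrality = do.call(rbind, centrality_rows),
              windows = windows, methods = methods, labels = labels)
  rownames(out$metrics) <- NULL
  rownames(out$centrality) <- NULL
  class(out) <- "agonet_windows"
  out
}

#' @export
print.agonet_windows <- function(x, ...) {
  cat("Expanding-window network analysis:\n",
      "  windows: ", length(x$windows), " (", min(x$windows), "-", max(x$windows),
      " h), methods: ", paste(x$methods, collapse = "/"),
      ", labels: ", x$labels, "\n",
      "  ", nrow(x$metrics), " network rows, ", nrow(x$centrality),
      " centrality rows\n", sep = "")
  invisible(x)
}
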