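#' End-to-end analysis pipeline on a simulated cohort
#'
#' Convenience wrapper chaining the whole analysis: simulate a cohort
#' ([simulate_cohort()]), classify dyads at the final window
#' ([classify_dyads()] for each method), run the expanding-window network
#' analysis ([run_expanding_windows()]) and correlate the data sets
#' ([compare_datasets()]).  With a fixed `seed` the result — including the
#' CSV files written by [write_pipeline_csv()] — is byte-identical across
#' runs.
#'
#' @param age_group,n_pens,seed,kappa,beta,gamma passed to
#'   [simulate_cohort()].
#' @param methods data-set rules to evaluate.
#' @param conf,alpha passed to [classify_dyads()].
#' @param windows window lengths; defaults to the full 1 h grid.
#' @return List with `log`, `dyads` (final-window `dyad_table`), `labels`
#'   (per method), `pen_limits`, `windows` (`agonet_windows`),
#'   `correlations` and `centrality_correlations`.
#' @export
run_pipeline <- function(age_group = "piglets", n_pens = 10L, seed = NULL,
                         methods = c("ALL", "PEN", "DYAD"),
                         conf = 0.95, alpha = 0.05,
                         kappa = 0.15, beta = 2, gamma = 0.8,
                         windows = NULL) {
  log <- simulate_cohort(age_group, n_pens = n_pens, seed = seed,
                         kappa = kappa, beta = beta, gamma = gamma)
  if (is.null(windows)) windows <- window_grid(log$schedule)
  dyads <- aggregate_dyads(log)
  labels <- lapply(stats::setNames(methods, methods), function(m)
    classify_dyads(dyads, m, conf = conf, alpha = alpha))
  limits <- if ("PEN" %in% methods) attr(labels[["PEN"]], "pen_limits") else NULL
  win <- run_expanding_windows(log, windows = windows, methods = methods,
                               conf = conf, alpha = alpha)
  list(log = log, dyads = dyads, labels = labels, pen_limits = limits,
       windows = win,
       correlations = compare_datasets(win, "metrics"),
       centrality_correlations = compare_datasets(win, "centrality"))
}

#' @rdname run_pipeline
#' @param result a list returned by `run_pipeline()`.
#' @param dir output directory (created if missing).
#' @return `write_pipeline_csv()` invisibly returns the written file paths.
#' @export
write_pipeline_csv <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = TRUE)
    paths[[length(paths) + 1L]] <<- p
  }
  write_event_log(result$log, file.path(dir, "events.csv"))
  paths <- c(paths, file.path(dir, "events.csv"))
  write_roster(result$log$roster, file.path(dir, "roster.csv"))
  paths <- c(paths, file.path(dir, "roster.csv"))
  lab <- do.call(rbind, lapply(result$labels, function(l) {
    d <- as.data.frame(l)
    d$flag <- as.character(d$flag)
    d
  }))
  rownames(lab) <- NULL
  wr(lab, "dyad_labels.csv")
  if (!is.null(result$pen_limits)) wr(result$pen_limits, "pen_limits.csv")
  wr(result$windows$metrics, "network_metrics.csv")
  wr(result$windows$centrality, "centrality.csv")
  wr(result$correlations, "correlations_metrics.csv")
  wr(result$centrality_correlations, "correlations_centrality.csv")
  invisible(paths)
}
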