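#' Aggregate events into dyadic win/loss records
#'
#' A dyad is an unordered pair of pen mates.  For every pair of roster
#' animals — including pairs that never interacted — the table records how
#' many fights each side won against the other.  Pair members are stored in
#' canonical (lexicographic) order, so each dyad appears exactly once and
#' the representation is invariant under relabelling the two animals.
#'
#' @param log an [event_log].
#' @param pens pens to aggregate; defaults to every pen in the roster.
#' @return A `dyad_table`: data frame with columns `pen_id`, `animal_a`,
#'   `animal_b` (`animal_a < animal_b`), `wins_a`, `wins_b`, `total` and
#'   `difference` (`|wins_a - wins_b|`), with `choose(N, 2)` rows per pen.
#' @export
aggregate_dyads <- function(log, pens = names(log$roster)) {
  stopifnot(inherits(log, "event_log"))
  unknown <- setdiff(pens, names(log$roster))
  if (length(unknown)) stop("unknown pen(s): ", paste(unknown, collapse = ", "))
  out <- lapply(pens, function(pen) {
    animals <- sort(log$roster[[pen]])
    if (length(animals) < 2L)
      stop("pen ", pen, " has fewer than 2 animals")
    pairs <- t(utils::combn(animals, 2L))
    tab <- data.frame(pen_id = pen, animal_a = pairs[, 1L], animal_b = pairs[, 2L],
                      wins_a = 0L, wins_b = 0L)
    ev <- log$events[log$events$pen_id == pen, , drop = FALSE]
    if (nrow(ev)) {
      a <- pmin(ev$winner, ev$loser)
      b <- pmax(ev$winner, ev$loser)
      key <- paste(a, b, sep = "\r")
      tab_key <- paste(tab$animal_a, tab$animal_b, sep = "\r")
      wa <- table(factor(key[ev$winner == a], levels = tab_key))
      wb <- table(factor(key[ev$winner == b], levels = tab_key))
      tab$wins_a <- as.integer(wa)
      tab$wins_b <- as.integer(wb)
    }
    tab
  })
  out <- do.call(rbind, out)
  out$total <- out$wins_a + out$wins_b
  out$difference <- abs(out$wins_a - out$wins_b)
  rownames(out) <- NULL
  class(out) <- c("dyad_table", "data.frame")
  out
}

#' Dyad-level significance of an asymmetric outcome
#'
#' Exact one-sided sign test for a single dyad: under the null that both
#' animals are equally likely to win each fight, the number of wins of the
#' more successful animal is Binomial(n, 1/2).  The dyad is significant when
#' the upper tail probability `P(X >= max(wins))` falls below `alpha`.  At
#' `alpha = 0.05` the smallest significant ratios are 5:0, 6:0, 7:0, 7:1,
#' 8:1, ... — at least five strictly unidirectional fights are needed.
#'
#' @param wins_x,wins_y non-negative win counts of the two animals
#'   (vectorised; order irrelevant).
#' @param alpha significance level in (0, 1).
#' @return Logical vector: `TRUE` where the asymmetry is significant.
#' @examples
#' dyad_limit_significant(5, 0)  # TRUE
#' dyad_limit_significant(4, 0)  # FALSE: P = 0.5^4 = 0.0625
#' @export
dyad_limit_significant <- function(wins_x, wins_y, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  if (any(wins_x < 0) || any(wins_y < 0)) stop("win counts must be >= 0")
  n <- wins_x + wins_y
  m <- pmax(wins_x, wins_y)
  p <- stats::pbinom(m - 1, n, 0.5, lower.tail = FALSE)
  p < alpha & n > 0
}

#' Order-statistic confidence interval for a median (sign test)
#'
#' Distribution-free confidence bounds for the median based on the sign
#' test: the interval between the k-th smallest and k-th largest
#' observations has exact coverage `1 - 2 * pbinom(k - 1, n, 0.5)`
#' (two-sided).  Because only finitely many coverage levels are achievable,
#' the requested level is reached by linear interpolation between the
#' bracketing achievable intervals (the standard sign-test CI interpolation);
#' with `interpolate = FALSE` the conservative exact interval is returned
#' and its achieved confidence reported.
#'
#' With `sides = "one"` each bound is a one-sided bound at level `conf`
#' (tail probability `1 - conf` per side instead of `(1 - conf)/2`).
#'
#' For very small samples no pair of order statistics reaches the requested
#' level; the full sample range is then returned with its (lower) achieved
#' confidence.
#'
#' @param x numeric sample (non-empty, no NA).
#' @param conf requested confidence level in (0, 1).
#' @param interpolate interpolate between achievable levels (default `TRUE`).
#' @param sides `"two"` (default) or `"one"`.
#' @return List with elements `lower`, `upper`, `achieved_confidence`, `n`.
#' @export
sign_test_ci_median <- function(x, conf = 0.95, interpolate = TRUE,
                                sides = c("two", "one")) {
  sides <- match.arg(sides)
  if (length(x) == 0L) stop("empty sample")
  if (anyNA(x)) stop("sample must not contain NA")
  if (!is.numeric(conf) || length(conf) != 1L || conf <= 0 || conf >= 1)
    stop("conf must lie strictly between 0 and 1")
  n <- length(x)
  s <- sort(x)
  tail_target <- if (sides == "two") (1 - conf) / 2 else (1 - conf)
  coverage <- function(k) {
    tail <- stats::pbinom(k - 1, n, 0.5)
    if (sides == "two") 1 - 2 * tail else 1 - tail
  }
  ks <- seq_len(max(1L, floor(n / 2)))
  ok <- stats::pbinom(ks - 1, n, 0.5) <= tail_target + 1e-12
  if (!any(ok)) {
    # even the sample range cannot reach the requested level
    return(list(lower = s[1L], upper = s[n],
                achieved_confidence = coverage(1L), n = n))
  }
  k <- max(ks[ok])
  lower <- s[k]; upper <- s[n + 1L - k]
  achieved <- coverage(k)
  inner_exists <- (k + 1L) <= (n - k)
  if (interpolate && achieved > conf + 1e-12 && inner_exists) {
    achieved_in <- coverage(k + 1L)
    t <- (achieved - conf) / (achieved - achieved_in)
    lower <- (1 - t) * s[k] + t * s[k + 1L]
    upper <- (1 - t) * s[n + 1L - k] + t * s[n - k]
    achieved <- conf
  }
  list(lower = lower, upper = upper, achieved_confidence = achieved, n = n)
}

#' Pen-level limits for a significant win/loss difference
#'
#' The pen limit takes the overall level of fighting in a pen into account:
#' over all dyads with at least one interaction (zero differences retained),
#' it computes the sign-test confidence interval of the median absolute
#' win/loss difference.  A dyad whose difference exceeds the upper limit is
#' more asymmetric than is compatible with the pen's typical dyad.
#'
#' @param table a [aggregate_dyads()] `dyad_table`.
#' @param conf confidence level for the median CI (default 0.95).
#' @param interpolate,sides passed to [sign_test_ci_median()].
#' @return Data frame with one row per pen: `pen_id`, `n_dyads` (interacting
#'   dyads used), `lower`, `upper`, `achieved_confidence`.
#' @export
pen_limit <- function(table, conf = 0.95, interpolate = TRUE,
                      sides = c("two", "one")) {
  sides <- match.arg(sides)
  stopifnot(inherits(table, "dyad_table") || is.data.frame(table))
  out <- lapply(unique(table$pen_id), function(pen) {
    d <- table[table$pen_id == pen & table$total >= 1L, "difference"]
    if (length(d) == 0L)
      stop("pen ", pen, " has no interacting dyads; no pen limit can be computed")
    ci <- sign_test_ci_median(d, conf = conf, interpolate = interpolate, sides = sides)
    data.frame(pen_id = pen, n_dyads = length(d), lower = ci$lower,
               upper = ci$upper, achieved_confidence = ci$achieved_confidence)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Classify dyads as significant under a data-set rule
#'
#' Produces the per-dyad labels behind the three data sets: `ALL` keeps
#' every interacting dyad; `PEN` keeps dyads whose win/loss difference
#' strictly exceeds the pen-level upper limit ([pen_limit()]); `DYAD` keeps
#' dyads individually significant under the exact sign test
#' ([dyad_limit_significant()]).  Dyads without any interaction are labelled
#' `unknown` under every method.
#'
#' @param table a `dyad_table` from [aggregate_dyads()].
#' @param method `"ALL"`, `"PEN"` or `"DYAD"`.
#' @param conf confidence level for the pen limit (PEN).
#' @param alpha significance level for the dyad-level sign test (DYAD).
#' @param interpolate,sides passed to [pen_limit()].
#' @return A `dyad_labels` data frame: the input columns plus `method` and
#'   `flag` (factor `significant` / `not_significant` / `unknown`).
#'   Attributes: `frac_significant` (per-pen fraction of significant dyads
#'   among interacting dyads) and, for PEN, `pen_limits`.
#' @export
classify_dyads <- function(table, method = c("ALL", "PEN", "DYAD"),
                           conf = 0.95, alpha = 0.05, interpolate = TRUE,
                           sides = c("two", "one")) {
  method <- match.arg(method)
  sides <- match.arg(sides)
  out <- as.data.frame(table)
  sig <- rep(FALSE, nrow(out))
  limits <- NULL
  if (method == "ALL") {
    sig <- out$total >= 1L
  } else if (method == "DYAD") {
    sig <- dyad_limit_significant(out$wins_a, out$wins_b, alpha = alpha)
  } else {
    interacting_pens <- unique(out$pen_id[out$total >= 1L])
    if (length(interacting_pens)) {
      limits <- pen_limit(out[out$pen_id %in% interacting_pens, , drop = FALSE],
                          conf = conf, interpolate = interpolate, sides = sides)
      upper <- limits$upper[match(out$pen_id, limits$pen_id)]
      sig <- !is.na(upper) & out$total >= 1L & out$difference > upper
    }
  }
  out$method <- method
  out$flag <- factor(ifelse(out$total == 0L, "unknown",
                     ifelse(sig, "significant", "not_significant")),
                     levels = c("significant", "not_significant", "unknown"))
  frac <- vapply(split(out, out$pen_id), function(d) {
    inter <- d$total >= 1L
    if (!any(inter)) NA_real_ else mean(d$flag[inter] == "significant")
  }, numeric(1))
  class(out) <- c("dyad_labels", "data.frame")
  attr(out, "frac_significant") <- frac
  attr(out, "pen_limits") <- limits
  out
}

#' Keep only events of significant dyads
#'
#' Restricts an event log to the fights of dyads flagged significant —
#' both directions of a significant dyad are kept, including reversals.
#' The roster is unchanged, so excluded animals become isolated nodes in
#' the downstream network rather than disappearing.
#'
#' @param log an [event_log].
#' @param labels a `dyad_labels` object from [classify_dyads()] computed on
#'   the same pens.
#' @return An [event_log] with the filtered events.
#' @export
filter_events <- function(log, labels) {
  stopifnot(inherits(log, "event_log"))
  if (!inherits(labels, "dyad_labels")) stop("labels must come from classify_dyads()")
  log_pens <- unique(log$events$pen_id)
  if (!all(log_pens %in% unique(labels$pen_id)))
    stop("mismatched pen ids: labels do not cover pen(s) ",
         paste(setdiff(log_pens, unique(labels$pen_id)), collapse = ", "))
  sig <- labels[labels$flag == "significant", , drop = FALSE]
  keep_key <- paste(sig$pen_id, sig$animal_a, sig$animal_b, sep = "\r")
  ev <- log$events
  key <- paste(ev$pen_id, pmin(ev$initiator, ev$receiver),
               pmax(ev$initiator, ev$receiver), sep = "\r")
  out <- log
  out$events <- ev[key %in% keep_key, , drop = FALSE]
  rownames(out$events) <- NULL
  attr(out, "n_dropped") <- NULL
  out
}
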