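#' Spearman rank correlation with midranks and exact small-sample p
#'
#' `r_s` is the Pearson correlation of the average ranks (midranks under
#' ties).  The p-value uses the t approximation
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` df; for `n <= exact_max`
#' (default 8) an exact two-sided permutation p is computed by full
#' enumeration of the `n!` orderings instead.  A constant input has no
#' defined rank correlation: the result is `NA` with a warning, never a
#' silent `NaN`.
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @param exact_max largest `n` for which the permutation p is used.
#' @return List with `r_s`, `p`, `n` and `method` (`"exact"` or
#'   `"t-approximation"`).
#' @export
spearman_rs <- function(x, y, exact_max = 8L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(r_s = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  r <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- perm_matrix(n)
    rperm <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rperm) >= abs(r) - 1e-12)
    method <- "exact"
  } else {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- min(p, 1)
    method <- "t-approximation"
  }
  list(r_s = r, p = p, n = n, method = method)
}

# All permutations of 1..n as an (n! x n) matrix, n small.
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_matrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# Tie-corrected Kruskal-Wallis H for a pooled sample and group labels.
kw_statistic <- function(values, g) {
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  ng <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(ng * (rbar - (N + 1) / 2)^2)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr <= 0) return(0)  # all observations identical
  H / corr
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p on `k - 1` df
#' (delegated to [stats::kruskal.test()]).  For small designs an exact
#' permutation p is available (`exact = TRUE`, total `n <= 10` recommended):
#' the tie-corrected statistic is recomputed over every distinct assignment
#' of the pooled observations to the group sizes.  When all observations
#' are identical, `H = 0` and `p = 1`.
#'
#' @param groups list of >= 2 numeric samples (total n >= 3).
#' @param exact compute the permutation p by full enumeration.
#' @return List with `H`, `df`, `p`, `n` and, when `exact = TRUE`,
#'   `p_exact`.
#' @export
kruskal_wallis <- function(groups, exact = FALSE) {
  if (!is.list(groups) || length(groups) < 2L) stop("need a list of at least 2 groups")
  if (any(lengths(groups) < 1L)) stop("every group needs at least one observation")
  values <- unlist(groups, use.names = FALSE)
  if (anyNA(values)) stop("observations must not contain NA")
  N <- length(values)
  if (N < 3L) stop("need at least 3 observations in total")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1L) {
    out <- list(H = 0, df = length(groups) - 1L, p = 1, n = N)
  } else {
    kt <- stats::kruskal.test(values, g)
    out <- list(H = unname(kt$statistic), df = unname(kt$parameter),
                p = kt$p.value, n = N)
  }
  if (exact) {
    H_obs <- kw_statistic(values, g)
    perms <- group_assignments(N, lengths(groups))
    Hs <- apply(perms, 1L, function(lab) kw_statistic(values, lab))
    out$p_exact <- mean(Hs >= H_obs - 1e-12)
  }
  out
}

# All distinct assignments of N items to groups with the given sizes, as a
# matrix of group labels (rows = assignments).
group_assignments <- function(N, sizes) {
  assign_rec <- function(avail, gi) {
    if (gi > length(sizes)) return(list(list()))
    picks <- utils::combn(avail, sizes[gi], simplify = FALSE)
    out <- list()
    for (p in picks) {
      for (rest in assign_rec(setdiff(avail, p), gi + 1L))
        out[[length(out) + 1L]] <- c(list(p), rest)
    }
    out
  }
  combos <- assign_rec(seq_len(N), 1L)
  labs <- matrix(0L, length(combos), N)
  for (i in seq_along(combos)) {
    parts <- combos[[i]]
    for (gi in seq_along(parts)) labs[i, parts[[gi]]] <- gi
  }
  labs
}

#' Dunn's post hoc pairwise comparisons on ranks
#'
#' After a Kruskal-Wallis test, Dunn's z statistics compare mean pooled
#' midranks of each group pair, with the usual tie correction in the
#' standard error; two-sided normal p-values, Bonferroni-adjusted across
#' the `k(k-1)/2` comparisons by default.
#'
#' @param groups list of >= 2 numeric samples.
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return Data frame with one row per pair: `group_i`, `group_j`, `z`,
#'   `p`, `p_adjusted`.  `z(i, j) = -z(j, i)` by construction.
#' @export
dunn_posthoc <- function(groups, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  if (!is.list(groups) || length(groups) < 2L) stop("need a list of at least 2 groups")
  values <- unlist(groups, use.names = FALSE)
  if (anyNA(values)) stop("observations must not contain NA")
  k <- length(groups)
  N <- length(values)
  g <- rep(seq_len(k), lengths(groups))
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  ng <- lengths(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(k, 2L)
  nm <- if (!is.null(names(groups))) names(groups) else as.character(seq_len(k))
  out <- data.frame(group_i = nm[pairs[1L, ]], group_j = nm[pairs[2L, ]],
                    z = NA_real_, p = NA_real_, p_adjusted = NA_real_)
  for (c_i in seq_len(ncol(pairs))) {
    i <- pairs[1L, c_i]; j <- pairs[2L, c_i]
    se2 <- (N * (N + 1) / 12 - tie_term) * (1 / ng[i] + 1 / ng[j])
    z <- if (se2 <= 0) 0 else (rbar[i] - rbar[j]) / sqrt(se2)
    out$z[c_i] <- z
    out$p[c_i] <- 2 * stats::pnorm(-abs(z))
  }
  m <- nrow(out)
  out$p_adjusted <- if (adjust == "bonferroni") pmin(out$p * m, 1) else out$p
  out
}

#' Spearman correlations between data sets across windows
#'
#' Quantifies how much restricting the network to significant dyads changes
#' each parameter: for every window length, parameter and data-set pair it
#' pairs observations (by pen for general network parameters, by pen and
#' animal for centralities — isolates with zero centrality included) and
#' computes [spearman_rs()].
#'
#' @param windows_result an `agonet_windows` from [run_expanding_windows()].
#' @param what `"metrics"` (general network parameters) or `"centrality"`.
#' @param pairs 2-row character matrix of data-set pairs to compare;
#'   defaults to every pair among the computed methods.
#' @param parameters parameter columns to correlate; defaults to all.
#' @return Data frame with columns `window_hours`, `parameter`, `pair`,
#'   `r_s`, `p`, `n`.
#' @export
compare_datasets <- function(windows_result, what = c("metrics", "centrality"),
                             pairs = NULL, parameters = NULL) {
  what <- match.arg(what)
  stopifnot(inherits(windows_result, "agonet_windows"))
  df <- windows_result[[what]]
  methods <- unique(df$dataset)
  if (length(methods) < 2L) stop("need at least 2 data sets to compare")
  if (is.null(pairs)) pairs <- utils::combn(methods, 2L)
  key_cols <- if (what == "metrics") "pen_id" else c("pen_id", "animal")
  if (is.null(parameters))
    parameters <- setdiff(names(df), c("pen_id", "dataset", "window_hours", "animal"))
  out <- list()
  for (w in unique(df$window_hours)) {
    dw <- df[df$window_hours == w, , drop = FALSE]
    for (ci in seq_len(ncol(pairs))) {
      d1 <- dw[dw$dataset == pairs[1L, ci], , drop = FALSE]
      d2 <- dw[dw$dataset == pairs[2L, ci], , drop = FALSE]
      k1 <- do.call(paste, c(d1[key_cols], sep = "\r"))
      k2 <- do.call(paste, c(d2[key_cols], sep = "\r"))
      common <- intersect(k1, k2)
      if (length(common) == 0L)
        stop("data sets ", pairs[1L, ci], " and ", pairs[2L, ci],
             " share no observation keys")
      i1 <- match(common, k1); i2 <- match(common, k2)
      for (par in parameters) {
        x <- d1[[par]][i1]; y <- d2[[par]][i2]
        ok <- !(is.na(x) | is.na(y))
        cell <- if (sum(ok) >= 3L && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0)
          spearman_rs(x[ok], y[ok])
        else list(r_s = NA_real_, p = NA_real_, n = sum(ok))
        out[[length(out) + 1L]] <- data.frame(
          window_hours = w, parameter = par,
          pair = paste(pairs[1L, ci], pairs[2L, ci], sep = "_vs_"),
          r_s = cell$r_s, p = cell$p, n = cell$n)
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
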