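# Independent brute-force oracles used across the suite.  Everything here is
# deliberately written from first principles (enumeration, closure matrices,
# all-pairs shortest paths) so it shares no code path with the package.

# Exact upper-tail probability of the one-sided sign test by direct
# enumeration of binomial coefficients.
oracle_sign_tail <- function(wins, losses) {
  n <- wins + losses
  m <- max(wins, losses)
  if (n == 0) return(1)
  sum(choose(n, m:n)) / 2^n
}

# Order-statistic CI of the median with interpolation, via explicit
# enumeration of interval coverages sum_{i=k}^{n-k} C(n,i)/2^n.
oracle_sign_ci <- function(x, conf = 0.95, interpolate = TRUE) {
  n <- length(x)
  s <- sort(x)
  cov_k <- function(k) {
    if (k > n - k) return(0)
    sum(choose(n, k:(n - k))) / 2^n
  }
  ks <- seq_len(max(1, floor(n / 2)))
  covs <- vapply(ks, cov_k, numeric(1))
  ok <- covs >= conf - 1e-12
  if (!any(ok))
    return(list(lower = s[1], upper = s[n], achieved_confidence = covs[1]))
  k <- max(ks[ok])
  lower <- s[k]; upper <- s[n + 1 - k]
  achieved <- covs[k]
  if (interpolate && achieved > conf + 1e-12 && (k + 1) <= (n - k)) {
    ach_in <- cov_k(k + 1)
    t <- (achieved - conf) / (achieved - ach_in)
    lower <- (1 - t) * s[k] + t * s[k + 1]
    upper <- (1 - t) * s[n + 1 - k] + t * s[n - k]
    achieved <- conf
  }
  list(lower = lower, upper = upper, achieved_confidence = achieved)
}

# --- graph oracles on a logical adjacency matrix A (no self loops) ---------

# Reachability closure (excluding the trivial self path) by repeated boolean
# matrix products.
oracle_reach <- function(A) {
  n <- nrow(A)
  R <- A
  for (k in seq_len(n)) {
    R_new <- R | (R %*% A > 0)
    if (identical(R_new, R)) break
    R <- R_new
  }
  R
}

# All-pairs shortest directed path lengths, Floyd-Warshall.
oracle_dist <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  d[A] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  d
}

# Weak / strong component membership from closure matrices.
oracle_components <- function(A, mode) {
  n <- nrow(A)
  if (mode == "weak") {
    R <- oracle_reach(A | t(A)); diag(R) <- TRUE
  } else {
    C <- oracle_reach(A); diag(C) <- TRUE
    R <- C & t(C)
  }
  comp <- integer(n); cid <- 0
  for (v in seq_len(n)) {
    if (comp[v] > 0) next
    cid <- cid + 1
    comp[R[v, ]] <- cid
  }
  comp
}

oracle_fragmentation <- function(A) {
  n <- nrow(A)
  sizes <- tabulate(oracle_components(A, "weak"))
  1 - sum(sizes * (sizes - 1)) / (n * (n - 1))
}

# Component-corrected closeness from the Floyd-Warshall distance matrix.
oracle_closeness <- function(A, mode) {
  n <- nrow(A)
  d <- oracle_dist(A)
  vapply(seq_len(n), function(v) {
    dv <- if (mode == "out") d[v, -v] else d[-v, v]
    r <- sum(is.finite(dv))
    if (r == 0) 0 else (r / (n - 1)) * (r / sum(dv[is.finite(dv)]))
  }, numeric(1))
}

# Betweenness by geodesic counting: sigma[s, t] = number of shortest s->t
# paths, built up over nodes in order of distance; pair-dependency summed
# explicitly for every (s, v, t) triple.
oracle_betweenness <- function(A) {
  n <- nrow(A)
  d <- oracle_dist(A)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(d[s, ])
    for (t in ord) {
      if (t == s || !is.finite(d[s, t])) next
      preds <- which(A[, t] & d[s, ] + 1 == d[s, t])
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      if (s == v) next
      for (t in seq_len(n)) {
        if (t == s || t == v) next
        if (is.finite(d[s, t]) && sigma[s, t] > 0 &&
            is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t])
          bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  bc / ((n - 1) * (n - 2))
}

# --- fixture builders ------------------------------------------------------

# Network object straight from an edge specification.
net_from_edges <- function(nodes, from = character(), to = character(),
                           weight = rep(1L, length(from)), pen_id = "p") {
  edges <- data.frame(from = as.character(from), to = as.character(to),
                      weight = as.integer(weight))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(pen_id = pen_id, nodes = sort(as.character(nodes)), edges = edges),
            class = "agonet_network")
}

# Random digraph as an agonet_network plus its adjacency matrix.
rand_digraph <- function(n, p = NULL) {
  if (is.null(p)) p <- runif(1, 0.05, 0.6)
  A <- matrix(runif(n * n) < p, n, n)
  diag(A) <- FALSE
  nodes <- sprintf("n%02d", seq_len(n))
  idx <- which(A, arr.ind = TRUE)
  net <- net_from_edges(nodes, nodes[idx[, 1]], nodes[idx[, 2]])
  dimnames(A) <- list(nodes, nodes)
  list(net = net, A = A)
}

# Compact event-log fixture: winner always the initiator unless stated.
make_log <- function(initiator, receiver, roster,
                     winner = initiator, loser = receiver,
                     day = 1L, clock_time = 12 * 60 + seq_along(initiator),
                     pen_id = "p", schedule = schedule_preset("piglets_28h")) {
  n <- length(initiator)
  ev <- data.frame(pen_id = rep_len(pen_id, n), initiator = initiator,
                   receiver = receiver, winner = winner, loser = loser,
                   day = rep_len(day, n), clock_time = rep_len(clock_time, n),
                   duration_s = rep_len(10, n))
  event_log(ev, roster, schedule = schedule)
}
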