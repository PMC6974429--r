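#' General network parameters of a directed agonistic network
#'
#' All metrics operate on the unweighted directed topology and keep
#' isolated animals in the node set, so denominators are always the full
#' pen size.
#'
#' * `net_density()`: fraction of the `N(N-1)` possible directed edges that
#'   are present.
#' * `graph_components()`: partition of the nodes into weakly connected
#'   components (connectivity ignoring edge direction) or strongly
#'   connected components (mutual directed reachability, Kosaraju's
#'   two-pass algorithm).
#' * `fragmentation()`: fraction of unordered node pairs not joined by any
#'   semipath, `1 - sum(n_k (n_k - 1)) / (N (N - 1))` over weak-component
#'   sizes `n_k`; 0 for a spanning weak component, 1 when all nodes are
#'   isolated.
#' * `component_pcts()`: percentages of pen size in the largest weak and
#'   strong components and the percentage of isolated nodes (no ingoing
#'   and no outgoing edge).
#'
#' @param net an `agonet_network` from [build_network()].
#' @param mode `"weak"` or `"strong"` component definition.
#' @return `net_density()` and `fragmentation()` return a single fraction in
#'   \[0, 1\]; `graph_components()` an integer membership vector named by
#'   node; `component_pcts()` a named vector
#'   `c(largest_wcc_pct, largest_scc_pct, isolated_pct)` in \[0, 100\].
#' @export
net_density <- function(net) {
  n <- n_nodes(net)
  if (n < 2L) stop("density needs at least 2 nodes")
  nrow(net$edges) / (n * (n - 1))
}

#' @rdname net_density
#' @export
graph_components <- function(net, mode = c("weak", "strong")) {
  mode <- match.arg(mode)
  A <- adjacency_matrix(net)
  n <- nrow(A)
  if (n == 0L) return(integer(0))
  if (mode == "weak") {
    U <- A | t(A)
    comp <- integer(n)
    cid <- 0L
    for (s in seq_len(n)) {
      if (comp[s] > 0L) next
      cid <- cid + 1L
      queue <- s
      comp[s] <- cid
      while (length(queue)) {
        v <- queue[[1L]]; queue <- queue[-1L]
        nb <- which(U[v, ] & comp == 0L)
        comp[nb] <- cid
        queue <- c(queue, nb)
      }
    }
  } else {
    comp <- kosaraju_scc(A)
  }
  names(comp) <- net$nodes
  comp
}

# Kosaraju: iterative DFS finishing order on A, then DFS on t(A) in reverse
# finishing order; each second-pass tree is one SCC.
kosaraju_scc <- function(A) {
  n <- nrow(A)
  nbr <- lapply(seq_len(n), function(v) which(A[v, ]))
  rnbr <- lapply(seq_len(n), function(v) which(A[, v]))
  visited <- rep(FALSE, n)
  order_out <- integer(0)
  for (s in seq_len(n)) {
    if (visited[s]) next
    stack <- list(c(s, 0L))  # (node, next-neighbour index)
    visited[s] <- TRUE
    while (length(stack)) {
      top <- stack[[length(stack)]]
      v <- top[1L]; i <- top[2L] + 1L
      nb <- nbr[[v]]
      advanced <- FALSE
      while (i <= length(nb)) {
        w <- nb[i]
        if (!visited[w]) {
          stack[[length(stack)]] <- c(v, i)
          stack[[length(stack) + 1L]] <- c(w, 0L)
          visited[w] <- TRUE
          advanced <- TRUE
          break
        }
        i <- i + 1L
      }
      if (!advanced) {
        order_out <- c(order_out, v)
        stack[[length(stack)]] <- NULL
      }
    }
  }
  comp <- integer(n)
  cid <- 0L
  for (s in rev(order_out)) {
    if (comp[s] > 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- rnbr[[v]][comp[rnbr[[v]]] == 0L]
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

#' @rdname net_density
#' @export
fragmentation <- function(net) {
  n <- n_nodes(net)
  if (n < 2L) stop("fragmentation needs at least 2 nodes")
  sizes <- tabulate(graph_components(net, "weak"))
  1 - sum(sizes * (sizes - 1)) / (n * (n - 1))
}

#' @rdname net_density
#' @export
component_pcts <- function(net) {
  n <- n_nodes(net)
  if (n < 1L) stop("empty node set")
  A <- adjacency_matrix(net)
  wcc <- max(tabulate(graph_components(net, "weak")))
  scc <- max(tabulate(graph_components(net, "strong")))
  isolated <- sum(rowSums(A) + colSums(A) == 0)
  c(largest_wcc_pct = 100 * wcc / n,
    largest_scc_pct = 100 * scc / n,
    isolated_pct = 100 * isolated / n)
}

#' Centrality parameters for directed networks with isolates
#'
#' Standardised to \[0, 1\] with the full pen in the denominator; isolated
#' animals score 0 on every centrality.
#'
#' * `degree_centrality()`: number of distinct in- or out-neighbours over
#'   `N - 1`.
#' * `closeness_centrality()`: component-corrected closeness.  For node `v`
#'   let `r` be the number of other nodes that reach `v` (`mode = "in"`) or
#'   are reached from `v` (`mode = "out"`) along directed paths and `S` the
#'   sum of those shortest-path lengths; then
#'   `C(v) = (r / (N - 1)) * (r / S)`, and 0 when `r = 0`.  The first
#'   factor discounts nodes that can only reach a small component, so the
#'   measure is finite and comparable on disconnected networks.
#' * `betweenness_centrality()`: directed shortest-path betweenness
#'   (Brandes' dependency accumulation; all geodesics count equally),
#'   normalised by `(N - 1)(N - 2)`.  Pairs without a connecting path
#'   contribute nothing.
#'
#' @param net an `agonet_network`.
#' @param mode `"in"` (being attacked / reached) or `"out"` (attacking /
#'   reaching).
#' @return Named numeric vector over all nodes, values in \[0, 1\].
#' @export
degree_centrality <- function(net, mode = c("in", "out")) {
  mode <- match.arg(mode)
  n <- n_nodes(net)
  if (n < 2L) stop("degree centrality needs at least 2 nodes")
  A <- adjacency_matrix(net)
  deg <- if (mode == "in") colSums(A) else rowSums(A)
  deg / (n - 1)
}

# BFS distances from source v along the given neighbour list; Inf where
# unreachable.
bfs_dist <- function(nbr, v, n) {
  d <- rep(Inf, n)
  d[v] <- 0
  queue <- v
  while (length(queue)) {
    u <- queue[[1L]]; queue <- queue[-1L]
    nb <- nbr[[u]][is.infinite(d[nbr[[u]]])]
    d[nb] <- d[u] + 1
    queue <- c(queue, nb)
  }
  d
}

#' @rdname degree_centrality
#' @export
closeness_centrality <- function(net, mode = c("in", "out")) {
  mode <- match.arg(mode)
  n <- n_nodes(net)
  if (n < 2L) stop("closeness centrality needs at least 2 nodes")
  A <- adjacency_matrix(net)
  # "out": distances from v along edges; "in": along reversed edges
  B <- if (mode == "out") A else t(A)
  nbr <- lapply(seq_len(n), function(v) which(B[v, ]))
  out <- vapply(seq_len(n), function(v) {
    d <- bfs_dist(nbr, v, n)[-v]
    reached <- is.finite(d)
    r <- sum(reached)
    if (r == 0L) return(0)
    (r / (n - 1)) * (r / sum(d[reached]))
  }, numeric(1))
  names(out) <- net$nodes
  out
}

#' @rdname degree_centrality
#' @export
betweenness_centrality <- function(net) {
  n <- n_nodes(net)
  if (n < 3L) stop("betweenness centrality needs at least 3 nodes")
  A <- adjacency_matrix(net)
  nbr <- lapply(seq_len(n), function(v) which(A[v, ]))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    S <- integer(0)
    P <- vector("list", n)
    sigma <- numeric(n); sigma[s] <- 1
    d <- rep(-1, n); d[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      S <- c(S, v)
      for (w in nbr[[v]]) {
        if (d[w] < 0) {
          d[w] <- d[v] + 1
          queue <- c(queue, w)
        }
        if (d[w] == d[v] + 1) {
          sigma[w] <- sigma[w] + sigma[v]
          P[[w]] <- c(P[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(S)) {
      for (v in P[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  names(bc) <- net$nodes
  bc / ((n - 1) * (n - 2))
}

#' Assemble all network and centrality parameters for one network
#'
#' Deterministic one-stop assembly of the general network parameters
#' (density, fragmentation, largest weak/strong component, isolated nodes)
#' and the five per-animal centralities.  Betweenness is `NA` for pens of
#' fewer than 3 animals.
#'
#' @param net an `agonet_network`.
#' @param dataset label for the data set the network was built from
#'   (e.g. `"ALL"`).
#' @param window_hours label for the time window.
#' @return List with `metrics` (one-row data frame: `pen_id`, `dataset`,
#'   `window_hours`, `density`, `fragmentation`, `largest_wcc_pct`,
#'   `largest_scc_pct`, `isolated_pct`) and `centrality` (one row per
#'   animal: `in_degree`, `out_degree`, `in_closeness`, `out_closeness`,
#'   `betweenness`).
#' @export
metrics_table <- function(net, dataset = NA_character_, window_hours = NA_real_) {
  stopifnot(inherits(net, "agonet_network"))
  n <- n_nodes(net)
  pcts <- component_pcts(net)
  metrics <- data.frame(
    pen_id = net$pen_id, dataset = dataset, window_hours = window_hours,
    density = net_density(net), fragmentation = fragmentation(net),
    largest_wcc_pct = unname(pcts["largest_wcc_pct"]),
    largest_scc_pct = unname(pcts["largest_scc_pct"]),
    isolated_pct = unname(pcts["isolated_pct"]))
  centrality <- data.frame(
    pen_id = net$pen_id, dataset = dataset, window_hours = window_hours,
    animal = net$nodes,
    in_degree = unname(degree_centrality(net, "in")),
    out_degree = unname(degree_centrality(net, "out")),
    in_closeness = unname(closeness_centrality(net, "in")),
    out_closeness = unname(closeness_centrality(net, "out")),
    betweenness = if (n >= 3L) unname(betweenness_centrality(net)) else NA_real_)
  list(metrics = metrics, centrality = centrality)
}
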