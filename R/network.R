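#' Build a directed agonistic network for one pen
#'
#' Nodes are the full pen roster; a directed edge points from the initiator
#' to the receiver of an attack, weighted by the number of fights between
#' that ordered pair.  Animals without any fight remain in the node set as
#' isolates.  All repeated fights between the same ordered pair collapse to
#' one weighted edge; the network metrics operate on the unweighted
#' topology, weights are kept for export and visualisation.
#'
#' @param log an [event_log].
#' @param pen_id pen to build the network for.
#' @return An object of class `agonet_network`: list with `pen_id`, `nodes`
#'   (sorted roster) and `edges` (data frame `from`, `to`, `weight`).
#' @export
build_network <- function(log, pen_id) {
  stopifnot(inherits(log, "event_log"))
  if (length(pen_id) != 1L || !pen_id %in% names(log$roster))
    stop("unknown pen: ", pen_id)
  nodes <- sort(log$roster[[pen_id]])
  ev <- log$events[log$events$pen_id == pen_id, , drop = FALSE]
  if (nrow(ev)) {
    agg <- stats::aggregate(list(weight = rep(1L, nrow(ev))),
                            by = list(from = ev$initiator, to = ev$receiver),
                            FUN = sum)
    agg <- agg[order(agg$from, agg$to), , drop = FALSE]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(from = character(), to = character(), weight = integer())
  }
  structure(list(pen_id = pen_id, nodes = nodes, edges = agg),
            class = "agonet_network")
}

#' @export
print.agonet_network <- function(x, ...) {
  cat("Directed agonistic network (pen ", x$pen_id, "): ",
      length(x$nodes), " nodes, ", nrow(x$edges), " edges, ",
      sum(x$edges$weight), " fights\n", sep = "")
  invisible(x)
}

n_nodes <- function(net) length(net$nodes)

# Logical adjacency matrix (distinct directed edges), nodes in roster order.
adjacency_matrix <- function(net) {
  n <- n_nodes(net)
  A <- matrix(FALSE, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges))
    A[cbind(match(net$edges$from, net$nodes), match(net$edges$to, net$nodes))] <- TRUE
  A
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

#' Export / import directed networks
#'
#' Lossless export of nodes (including isolates), edge directions and
#' weights.  Two formats: a plain edge-list CSV (`from`, `to`, `weight`,
#' with an accompanying node column convention: isolates are carried as
#' rows with an empty `to` and weight 0) and GraphML (nodes listed
#' explicitly, `weight` as an edge attribute), suitable for network
#' visualisation software.
#'
#' @param net an `agonet_network` from [build_network()].
#' @param file output path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `export_network()` invisibly returns `file`;
#'   `import_network_edgelist()` returns an `agonet_network`.
#' @export
export_network <- function(net, file, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "agonet_network"))
  if (format == "edgelist") {
    df <- net$edges
    # carry isolates (and any edge-less nodes) so the node set survives
    seen <- unique(c(df$from, df$to))
    lone <- setdiff(net$nodes, seen)
    if (length(lone))
      df <- rbind(df, data.frame(from = lone, to = "", weight = 0L))
    utils::write.csv(df, file, row.names = FALSE, quote = TRUE)
  } else {
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="w" for="edge" attr.name="weight" attr.type="double"/>',
      sprintf('  <graph id="%s" edgedefault="directed">', xml_escape(net$pen_id)),
      sprintf('    <node id="%s"/>', xml_escape(net$nodes)),
      if (nrow(net$edges)) sprintf(
        '    <edge source="%s" target="%s"><data key="w">%s</data></edge>',
        xml_escape(net$edges$from), xml_escape(net$edges$to),
        format(net$edges$weight)),
      '  </graph>',
      '</graphml>')
    writeLines(lines, file, useBytes = FALSE)
  }
  invisible(file)
}

#' @rdname export_network
#' @param pen_id pen id to assign to the imported network.
#' @export
import_network_edgelist <- function(file, pen_id = NA_character_) {
  df <- utils::read.csv(file, colClasses = c(from = "character", to = "character"))
  lone <- df$to == "" | is.na(df$to)
  nodes <- sort(unique(c(df$from, df$to[!lone])))
  edges <- df[!lone, , drop = FALSE]
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  edges$weight <- as.integer(edges$weight)
  rownames(edges) <- NULL
  structure(list(pen_id = pen_id, nodes = nodes, edges = edges),
            class = "agonet_network")
}
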