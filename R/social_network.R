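# Weighted social-network metrics of a pen's affinity network: density,
# diameter, degree and betweenness, plus top-partner lists and the
# top-percentile subgraph used for plotting.

network_igraph <- function(network, distance = c("weight", "inverse")) {
  distance <- match.arg(distance)
  edges <- network_edges(network)
  g <- igraph::graph_from_data_frame(
    edges[, .(cow_a, cow_b, weight = score)], directed = FALSE,
    vertices = data.frame(name = network$cows))
  if (distance == "inverse")
    igraph::E(g)$weight <- 1 / igraph::E(g)$weight
  g
}

#' Network metrics of an affinity network
#'
#' Computes the size, density, weighted diameter, degree distribution and
#' betweenness of a pen's affinity network.  Edges are the strictly positive
#' pair scores.  Density is `2E / (N (N - 1))`; degree is the count of
#' incident nonzero edges per cow.  For the path-based metrics (diameter,
#' betweenness) edge weights are treated as distances, the convention of the
#' graph software behind the reference analysis; note that under it a higher
#' affinity score means a longer edge.  Set `distance = "inverse"` to use
#' reciprocal scores as distances instead.  On a disconnected network the
#' diameter is the maximum over connected node pairs, and `connected` is
#' `FALSE`.
#'
#' @param network an `affinity_network`.
#' @param distance `"weight"` (scores as distances) or `"inverse"`.
#' @return a `network_metrics` list: `pen_id`, `n_nodes`, `n_edges`,
#'   `density`, `diameter`, `connected`, `degree` (named vector),
#'   `degree_max/min/mean`, `n_at_max_degree`, `betweenness` (named vector,
#'   normalised by the number of node pairs excluding the vertex).
#' @export
compute_metrics <- function(network, distance = c("weight", "inverse")) {
  distance <- match.arg(distance)
  n <- length(network$cows)
  if (n < 2L) stop("network metrics need at least 2 cows", call. = FALSE)
  g <- network_igraph(network, distance)
  n_edges <- igraph::ecount(g)
  density <- 2 * n_edges / (n * (n - 1))
  degree <- igraph::degree(g)
  connected <- igraph::is_connected(g)
  diameter <- if (n_edges == 0L) NA_real_ else
    igraph::diameter(g, weights = igraph::E(g)$weight, unconnected = TRUE)
  btw <- if (n_edges == 0L) stats::setNames(rep(0, n), network$cows) else
    igraph::betweenness(g, weights = igraph::E(g)$weight, normalized = TRUE)
  structure(list(
    pen_id = network$pen_id, n_nodes = n, n_edges = n_edges,
    density = density, diameter = diameter, connected = connected,
    degree = degree, degree_max = max(degree), degree_min = min(degree),
    degree_mean = mean(degree),
    n_at_max_degree = sum(degree == max(degree)),
    betweenness = btw), class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<network_metrics> pen %s: %d nodes, %d edges, density %.2f,\n",
    "  diameter %.3g%s, degree max/min/mean %d/%d/%.1f, %d at max\n"),
    x$pen_id, x$n_nodes, x$n_edges, x$density, x$diameter,
    if (x$connected) "" else " (disconnected)",
    x$degree_max, x$degree_min, x$degree_mean, x$n_at_max_degree))
  invisible(x)
}

#' One-row summary table of network metrics
#'
#' @param metrics a `network_metrics` object or list of them.
#' @return `data.table` with one row per pen.
#' @export
metrics_table <- function(metrics) {
  if (inherits(metrics, "network_metrics")) metrics <- list(metrics)
  rbindlist(lapply(metrics, function(m)
    data.table(pen_id = m$pen_id, n_nodes = m$n_nodes, n_edges = m$n_edges,
               diameter = m$diameter, density = m$density,
               degree_max = m$degree_max, degree_min = m$degree_min,
               degree_mean = m$degree_mean,
               n_at_max_degree = m$n_at_max_degree,
               connected = m$connected)))
}

#' Top scored partners of a cow
#'
#' @param network an `affinity_network`.
#' @param cow cow id present in the network.
#' @param k maximum number of partners returned.
#' @return `data.table` of partners with nonzero score, sorted by descending
#'   score, ties broken by ascending cow id.
#' @export
top_relationships <- function(network, cow, k = 5L) {
  if (!cow %in% network$cows)
    stop("cow ", cow, " not in network", call. = FALSE)
  s <- network$weights[cow, ]
  s <- s[names(s) != cow & s > 0]
  if (!length(s))
    return(data.table(partner = character(), score = numeric()))
  ord <- order(-s, names(s), method = "radix")
  out <- data.table(partner = names(s)[ord], score = unname(s[ord]))
  head(out, k)
}

#' Strongest-edge subgraph
#'
#' Keeps the top fraction of nonzero edge weights (the convention used to
#' draw the pen networks without oversaturating them): edges with weight at
#' least the `ceiling(top_fraction * E)`-th largest are retained, so weight
#' ties may keep a few more.  The node set is unchanged.
#'
#' @param network an `affinity_network`.
#' @param top_fraction fraction of edges to keep, in (0, 1].
#' @return the thresholded `affinity_network`.
#' @export
edge_percentile_subgraph <- function(network, top_fraction = 0.10) {
  stopifnot_scalar(top_fraction, "top_fraction", min = 1e-12, max = 1)
  w <- network$weights
  nz <- w[upper.tri(w)]
  nz <- nz[nz > 0]
  if (!length(nz)) stop("network has no edges", call. = FALSE)
  m <- ceiling(top_fraction * length(nz))
  thr <- sort(nz, decreasing = TRUE)[m]
  w[w < thr] <- 0
  network$weights <- w
  network
}
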