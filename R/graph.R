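#' Build a weighted functional network from a connectivity matrix
#'
#' Nodes are electrodes; edge weights are PLI values (affinities) and edge
#' distances are their reciprocals `1/PLI`, so stronger phase coupling means
#' shorter distance. Zero-PLI pairs are capped at distance `1/eps` (default
#' 1e6) to keep the graph formally connected; such edges never win a
#' shortest path.
#'
#' @param cm A `pli_matrix`, or a symmetric numeric matrix with labels.
#' @param node_set Optional electrode subset to induce a subnetwork (for
#'   example [frontotemporal_set()]); `NULL` keeps all nodes.
#' @param tag Name recorded for the node set ("whole", "frontotemporal", ...).
#' @param eps Weight floor used when inverting to distances.
#' @return A `pli_graph`: `W` (weights), `L` (distances), `labels`,
#'   `node_set`, `band`.
#' @export
build_graph <- function(cm, node_set = NULL, tag = NULL, eps = 1e-6) {
  if (inherits(cm, "pli_matrix")) {
    W <- cm$pli
    labels <- cm$labels
    band <- cm$band
  } else {
    W <- as.matrix(cm)
    labels <- rownames(W) %||% paste0("n", seq_len(nrow(W)))
    band <- NA_character_
  }
  dimnames(W) <- list(labels, labels)
  if (is.null(node_set)) {
    node_set <- labels
    tag <- tag %||% "whole"
  } else {
    bad <- setdiff(node_set, labels)
    if (length(bad) > 0) {
      pg_stop(sprintf("node set label(s) not in matrix: %s",
                      paste(bad, collapse = ", ")), "pg_graph_error")
    }
    W <- W[node_set, node_set, drop = FALSE]
    labels <- node_set
    tag <- tag %||% "custom"
  }
  diag(W) <- 0
  L <- 1 / pmax(W, eps)
  diag(L) <- 0
  structure(list(W = W, L = L, labels = labels, node_set = tag,
                 band = band, eps = eps),
            class = "pli_graph")
}

#' @export
print.pli_graph <- function(x, ...) {
  cat(sprintf("<pli_graph> %d nodes (%s), band %s, mean PLI %.3f\n",
              length(x$labels), x$node_set, x$band, mean_pli(x)))
  invisible(x)
}

#' Mean PLI of a network
#'
#' Arithmetic mean of the upper-triangle edge weights: the global level of
#' phase coupling.
#'
#' @param g A `pli_graph`.
#' @return Mean PLI in `[0, 1]`.
#' @export
mean_pli <- function(g) {
  if (length(g$labels) < 2) pg_stop("mean PLI needs >= 2 nodes", "pg_graph_error")
  mean(g$W[upper.tri(g$W)])
}

#' Weighted clustering coefficient
#'
#' Per-node weighted clustering by the geometric-mean triangle formula
#' (Onnela): `cc_i = sum_jh (w_ij w_ih w_jh)^(1/3) / (k_i (k_i - 1))` on
#' weights scaled to `[0, 1]`; the network CC is the node average. CC
#' measures local segregation: how strongly a node's neighbours couple to
#' each other.
#'
#' Because PLI is already bounded in `[0, 1]`, the default ceiling for the
#' weight scaling is 1 (`normalization = "unit"`), which keeps CC comparable
#' across subjects and monotone in coupling strength. `"max"` rescales by
#' the graph's maximum weight instead (classical Onnela normalization, CC of
#' a homogeneous complete graph = 1).
#'
#' @param g A `pli_graph`.
#' @param normalization `"unit"` (default) or `"max"`.
#' @return Network clustering coefficient in `[0, 1]`.
#' @export
clustering_coefficient <- function(g, normalization = c("unit", "max")) {
  normalization <- match.arg(normalization)
  n <- length(g$labels)
  if (n < 3) pg_stop("clustering needs >= 3 nodes", "pg_graph_error")
  W <- g$W
  w_max <- if (normalization == "max") max(W) else 1
  if (w_max == 0) return(0)
  S <- (W / w_max)^(1 / 3)
  num <- diag(S %*% S %*% S)
  k <- rowSums(W > 0)
  cc <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  mean(cc)
}

#' Characteristic path length
#'
#' Mean over all ordered node pairs of the shortest-path distance on the
#' `1/PLI` distance matrix (Dijkstra). PL indexes global integration; a
#' lower PL means a more integrated network.
#'
#' @param g A `pli_graph`.
#' @return Characteristic path length (> 0 on a connected graph).
#' @export
characteristic_path_length <- function(g) {
  n <- length(g$labels)
  if (n < 2) pg_stop("path length needs >= 2 nodes", "pg_graph_error")
  D <- shortest_distances(g)
  if (any(!is.finite(D))) {
    pg_stop("graph is disconnected: infinite pairwise distance", "pg_graph_error")
  }
  mean(D[upper.tri(D)])
}

# All-pairs shortest-path distances on the 1/PLI distance matrix.
shortest_distances <- function(g) {
  ig <- igraph_from_distances(g$L, g$labels)
  igraph::distances(ig, algorithm = "dijkstra")
}

igraph_from_distances <- function(L, labels) {
  dimnames(L) <- list(labels, labels)
  igraph::graph_from_adjacency_matrix(L, mode = "undirected", weighted = TRUE,
                                      diag = FALSE)
}

igraph_from_weights <- function(g) {
  W <- g$W
  dimnames(W) <- list(g$labels, g$labels)
  igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE,
                                      diag = FALSE)
}

#' Weighted-network summary row
#'
#' @param g A `pli_graph`.
#' @param subject_id Optional subject identifier for the row.
#' @param normalization Passed to [clustering_coefficient()].
#' @return One-row data.frame: `subject_id`, `band`, `node_set`,
#'   `mean_pli`, `cc`, `pl`.
#' @export
network_metrics <- function(g, subject_id = NA_character_,
                            normalization = "unit") {
  data.frame(
    subject_id = subject_id, band = g$band, node_set = g$node_set,
    mean_pli = mean_pli(g),
    cc = clustering_coefficient(g, normalization),
    pl = characteristic_path_length(g),
    stringsAsFactors = FALSE
  )
}
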