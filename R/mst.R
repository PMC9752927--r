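#' Minimum spanning tree by Kruskal's algorithm
#'
#' Extracts the backbone of the weighted network: the acyclic subgraph
#' connecting all nodes with minimal total `1/PLI` distance, which avoids
#' any connectivity threshold choice. Edges are sorted by (distance, then
#' lexicographic label pair) so ties resolve identically across runs and
#' platforms.
#'
#' @param g A `pli_graph`.
#' @return A `pli_mst`: `labels`, `edges` (data.frame `from`, `to`,
#'   `distance`), named `degree` vector, node count `n`.
#' @export
kruskal_mst <- function(g) {
  n <- length(g$labels)
  if (n < 2) pg_stop("MST needs >= 2 nodes", "pg_mst_error")
  idx <- which(upper.tri(g$L), arr.ind = TRUE)
  from <- g$labels[idx[, 1]]
  to <- g$labels[idx[, 2]]
  # canonical orientation for deterministic tie-breaking
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  d <- g$L[idx]
  ord <- order(d, from, to)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  keep <- integer(0)
  lab_idx <- stats::setNames(seq_len(n), g$labels)
  for (e in ord) {
    ri <- find(lab_idx[[from[e]]])
    rj <- find(lab_idx[[to[e]]])
    if (ri != rj) {
      parent[ri] <- rj
      keep <- c(keep, e)
      if (length(keep) == n - 1L) break
    }
  }
  if (length(keep) != n - 1L) {
    pg_stop("input graph is disconnected; no spanning tree exists", "pg_mst_error")
  }
  edges <- data.frame(from = from[keep], to = to[keep], distance = d[keep],
                      stringsAsFactors = FALSE)
  degree <- table(factor(c(edges$from, edges$to), levels = g$labels))
  structure(list(labels = g$labels, edges = edges,
                 degree = stats::setNames(as.integer(degree), g$labels),
                 n = n, band = g$band, node_set = g$node_set),
            class = "pli_mst")
}

#' @export
print.pli_mst <- function(x, ...) {
  cat(sprintf("<pli_mst> %d nodes, total distance %.3f, %d leaves\n",
              x$n, sum(x$edges$distance), sum(x$degree == 1)))
  invisible(x)
}

# Adjacency list of a tree (indices).
tree_adjacency <- function(t) {
  lab_idx <- stats::setNames(seq_len(t$n), t$labels)
  adj <- vector("list", t$n)
  for (e in seq_len(nrow(t$edges))) {
    i <- lab_idx[[t$edges$from[e]]]
    j <- lab_idx[[t$edges$to[e]]]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# BFS hop distances from a root over an adjacency list.
bfs_hops <- function(adj, root) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  dist[root] <- 0L
  queue <- root
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    for (u in adj[[v]]) {
      if (is.na(dist[u])) {
        dist[u] <- dist[v] + 1L
        queue <- c(queue, u)
      }
    }
  }
  dist
}

#' Tree diameter
#'
#' Largest hop distance between any two nodes of the tree (double-BFS). A
#' smaller diameter reflects a more star-like, integrated backbone. The
#' normalized variant `diameter / (n - 1)` is reported alongside in
#' [mst_metrics()].
#'
#' @param t A `pli_mst`.
#' @return Diameter in hops.
#' @export
tree_diameter <- function(t) {
  adj <- tree_adjacency(t)
  d1 <- bfs_hops(adj, 1L)
  far <- which.max(d1)
  max(bfs_hops(adj, far))
}

#' Leaf number and leaf fraction
#'
#' Leaves are tree nodes of degree 1; the leaf fraction `LF = LN / n`.
#' Higher LF means a more star-like tree.
#'
#' @param t A `pli_mst`.
#' @return List with `leaf_number`, `leaf_fraction`.
#' @export
leaf_metrics <- function(t) {
  ln <- sum(t$degree == 1L)
  list(leaf_number = ln, leaf_fraction = ln / t$n)
}

#' Betweenness centrality on a tree
#'
#' `BC(v) = sum over pairs s != t != v of sigma_st(v) / sigma_st`; on a tree
#' every pair has exactly one path, so BC(v) counts the pairs whose path
#' crosses v. Computed by removing v and counting pairs split across the
#' resulting components. Both the raw count and the value normalized by
#' `(n-1)(n-2)/2` (so the maximum over star centres is 1) are returned.
#'
#' @param t A `pli_mst`.
#' @return List with named vectors `bc_raw`, `bc` (normalized), and
#'   `bc_max` (max normalized value).
#' @export
tree_betweenness <- function(t) {
  adj <- tree_adjacency(t)
  n <- t$n
  bc_raw <- numeric(n)
  for (v in seq_len(n)) {
    # component sizes of the forest after deleting v
    seen <- rep(FALSE, n)
    seen[v] <- TRUE
    sizes <- integer(0)
    for (u in adj[[v]]) {
      if (!seen[u]) {
        comp <- 0L
        queue <- u
        seen[u] <- TRUE
        while (length(queue) > 0) {
          w <- queue[1]
          queue <- queue[-1]
          comp <- comp + 1L
          for (z in adj[[w]]) {
            if (!seen[z]) {
              seen[z] <- TRUE
              queue <- c(queue, z)
            }
          }
        }
        sizes <- c(sizes, comp)
      }
    }
    bc_raw[v] <- ((n - 1)^2 - sum(sizes^2)) / 2
  }
  norm <- (n - 1) * (n - 2) / 2
  bc <- if (norm > 0) bc_raw / norm else rep(0, n)
  names(bc_raw) <- names(bc) <- t$labels
  list(bc_raw = bc_raw, bc = bc, bc_max = max(bc))
}

#' Tree hierarchy
#'
#' `TH = LN / (2 m BC_max)` with `m = n - 1` edges and `BC_max` the largest
#' normalized betweenness centrality: the trade-off between integration
#' (few hubs) and hub overload. A star of any size has TH = 0.5 exactly
#' under this normalization; a long path tends to 0 as it grows.
#'
#' @param t A `pli_mst`.
#' @return Tree hierarchy (dimensionless, > 0 for n >= 3).
#' @export
tree_hierarchy <- function(t) {
  if (t$n < 3) pg_stop("tree hierarchy needs >= 3 nodes", "pg_mst_error")
  bc_max <- tree_betweenness(t)$bc_max
  if (!(bc_max > 0)) pg_stop("BC_max is zero", "pg_mst_error")
  ln <- leaf_metrics(t)$leaf_number
  m <- t$n - 1
  ln / (2 * m * bc_max)
}

#' Kappa: broadness of the degree distribution
#'
#' `kappa = <k^2> / <k>` over the tree node degrees. Equals k for a
#' degree-regular graph and grows with degree heterogeneity (hubs).
#'
#' @param t A `pli_mst`.
#' @return Kappa (dimensionless, >= mean degree).
#' @export
degree_kappa <- function(t) {
  k <- t$degree
  mean(k^2) / mean(k)
}

#' Minimum-spanning-tree summary row
#'
#' @param t A `pli_mst`.
#' @param subject_id Optional subject identifier for the row.
#' @return One-row data.frame: `subject_id`, `band`, `node_set`,
#'   `diameter`, `diameter_norm`, `leaf_number`, `leaf_fraction`,
#'   `bc_max`, `tree_hierarchy`, `kappa`.
#' @export
mst_metrics <- function(t, subject_id = NA_character_) {
  lm <- leaf_metrics(t)
  d <- tree_diameter(t)
  data.frame(
    subject_id = subject_id, band = t$band, node_set = t$node_set,
    diameter = d, diameter_norm = d / (t$n - 1),
    leaf_number = lm$leaf_number, leaf_fraction = lm$leaf_fraction,
    bc_max = tree_betweenness(t)$bc_max,
    tree_hierarchy = tree_hierarchy(t),
    kappa = degree_kappa(t),
    stringsAsFactors = FALSE
  )
}
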