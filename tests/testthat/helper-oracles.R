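# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (literal loops, exhaustive enumeration,
# igraph cross-checks) so the implementation is never compared to itself.

# Literal sign-mean double loop over channel pairs.
oracle_pli <- function(phases) {
  n <- nrow(phases)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- phases[i, ] - phases[j, ]
      d <- d - 2 * pi * floor((d + pi) / (2 * pi))  # [-pi, pi)
      d[d == -pi] <- pi                             # (-pi, pi]
      P[i, j] <- abs(mean(sign(d)))
    }
  }
  P
}

# Random symmetric weight matrix with zero diagonal.
rand_weights <- function(n, lo = 0.05, hi = 0.95) {
  W <- matrix(stats::runif(n * n, lo, hi), n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  rownames(W) <- colnames(W) <- sprintf("n%02d", seq_len(n))
  W
}

# Floyd-Warshall all-pairs shortest distances.
oracle_floyd_warshall <- function(L) {
  n <- nrow(L)
  D <- L
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
  }
  D
}

# O(n^3) triangle-enumeration weighted clustering (Onnela).
oracle_cc <- function(W, w_max = 1) {
  n <- nrow(W)
  Wn <- W / w_max
  cc <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j == i || h == i || j == h) next
        s <- s + (Wn[i, j] * Wn[i, h] * Wn[j, h])^(1 / 3)
      }
    }
    cc[i] <- s / (k * (k - 1))
  }
  mean(cc)
}

# ---- spanning-tree machinery (Pruefer sequences) -------------------------

# Decode a Pruefer sequence into the edge list of a labelled tree on 1..n.
prufer_decode <- function(seq, n) {
  degree <- rep(1L, n)
  for (v in seq) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  ptr <- 0L
  for (v in seq) {
    leaf <- which(degree == 1L)[1]
    ptr <- ptr + 1L
    edges[ptr, ] <- c(leaf, v)
    degree[leaf] <- degree[leaf] - 1L
    degree[v] <- degree[v] - 1L
  }
  last <- which(degree == 1L)
  edges[n - 1L, ] <- last
  edges
}

# All n^(n-2) spanning trees of the complete graph on n nodes (n <= 7).
all_spanning_trees <- function(n) {
  if (n == 2) return(list(matrix(c(1L, 2L), 1)))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  lapply(seq_len(nrow(seqs)), function(r) prufer_decode(seqs[r, ], n))
}

# Total distance of an edge list under a distance matrix.
tree_total_distance <- function(edges, L) {
  sum(L[edges])
}

# Random labelled tree on n nodes as a pli_mst-shaped object.
random_tree <- function(n, labels = sprintf("n%02d", seq_len(n))) {
  edges_idx <- if (n == 2) matrix(c(1L, 2L), 1) else {
    prufer_decode(sample.int(n, n - 2L, replace = TRUE), n)
  }
  from <- labels[pmin(edges_idx[, 1], edges_idx[, 2])]
  to <- labels[pmax(edges_idx[, 1], edges_idx[, 2])]
  degree <- table(factor(c(from, to), levels = labels))
  structure(list(labels = labels,
                 edges = data.frame(from = from, to = to, distance = 1,
                                    stringsAsFactors = FALSE),
                 degree = stats::setNames(as.integer(degree), labels),
                 n = n, band = NA_character_, node_set = "test"),
            class = "pli_mst")
}

# Star and path trees for closed-form cases.
star_tree <- function(n) {
  labels <- sprintf("n%02d", seq_len(n))
  edges <- data.frame(from = labels[1], to = labels[-1], distance = 1,
                      stringsAsFactors = FALSE)
  degree <- stats::setNames(c(n - 1L, rep(1L, n - 1L)), labels)
  structure(list(labels = labels, edges = edges, degree = degree, n = n,
                 band = NA_character_, node_set = "test"), class = "pli_mst")
}

path_tree <- function(n) {
  labels <- sprintf("n%02d", seq_len(n))
  edges <- data.frame(from = labels[-n], to = labels[-1], distance = 1,
                      stringsAsFactors = FALSE)
  degree <- stats::setNames(c(1L, rep(2L, n - 2L), 1L), labels)
  structure(list(labels = labels, edges = edges, degree = degree, n = n,
                 band = NA_character_, node_set = "test"), class = "pli_mst")
}

# Brute-force tree statistics by explicit path enumeration: hop-distance
# matrix and, for every unordered pair, the set of interior nodes crossed.
oracle_tree_stats <- function(t) {
  n <- t$n
  idx <- stats::setNames(seq_len(n), t$labels)
  adj <- vector("list", n)
  for (e in seq_len(nrow(t$edges))) {
    i <- idx[[t$edges$from[e]]]
    j <- idx[[t$edges$to[e]]]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  # BFS parents from every source, then walk each path
  D <- matrix(0L, n, n)
  crossings <- numeric(n)
  for (s in seq_len(n)) {
    parent <- rep(NA_integer_, n)
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (u in adj[[v]]) {
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + 1L
          parent[u] <- v
          queue <- c(queue, u)
        }
      }
    }
    D[s, ] <- dist
    for (tt in seq_len(n)) {
      if (tt <= s) next
      v <- tt
      while (!is.na(parent[v])) {
        v <- parent[v]
        if (v != s && v != tt) crossings[v] <- crossings[v] + 1
      }
    }
  }
  list(diameter = max(D),
       leaf_number = sum(vapply(adj, length, integer(1)) == 1L),
       bc_raw = crossings,
       dist = D)
}

# Hop distances from node 1 of a pli_mst (finite everywhere iff connected).
bfs_reachable <- function(t) {
  idx <- stats::setNames(seq_len(t$n), t$labels)
  adj <- vector("list", t$n)
  for (e in seq_len(nrow(t$edges))) {
    i <- idx[[t$edges$from[e]]]; j <- idx[[t$edges$to[e]]]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  d <- rep(Inf, t$n); d[1] <- 0; q <- 1
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    for (u in adj[[v]]) if (!is.finite(d[u])) { d[u] <- d[v] + 1; q <- c(q, u) }
  }
  d
}

# ---- partitions ----------------------------------------------------------

# Independent set-partition enumeration: iterative restricted-growth-string
# successor algorithm (distinct from the package's recursive generator).
oracle_partitions <- function(n) {
  a <- rep(1L, n)
  out <- list(a)
  repeat {
    i <- n
    while (i > 1L) {
      cap <- max(a[1:(i - 1L)]) + 1L
      if (a[i] < cap) break
      i <- i - 1L
    }
    if (i == 1L) break
    a[i] <- a[i] + 1L
    if (i < n) a[(i + 1L):n] <- 1L
    out[[length(out) + 1L]] <- a
  }
  out
}

# Modularity via igraph (independent of the package formula code).
oracle_modularity <- function(W, membership) {
  ig <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  igraph::modularity(ig, membership, weights = igraph::E(ig)$weight)
}

# ---- signal battery ------------------------------------------------------

# Adversarial pairs of signals for PLI bound checks: independent noise,
# identical signals, constant-lag narrowband tones, antiphase, mixtures.
signal_pair_battery <- function(n_pairs, fs = 250, dur = 2, seed = 1) {
  set.seed(seed)
  n <- fs * dur
  t_ax <- seq_len(n) / fs
  lapply(seq_len(n_pairs), function(i) {
    kind <- i %% 5L
    if (kind == 0L) {
      x <- stats::rnorm(n); y <- stats::rnorm(n)            # independent
    } else if (kind == 1L) {
      x <- stats::rnorm(n); y <- x                           # identical
    } else if (kind == 2L) {
      f <- stats::runif(1, 2, 40)
      lag <- stats::runif(1, 0.05, pi - 0.05)
      x <- sin(2 * pi * f * t_ax)
      y <- sin(2 * pi * f * t_ax - lag)                      # constant lag
    } else if (kind == 3L) {
      x <- sin(2 * pi * 10 * t_ax); y <- -x                  # antiphase
    } else {
      f <- stats::runif(1, 2, 40)
      x <- sin(2 * pi * f * t_ax) + 0.5 * stats::rnorm(n)
      y <- sin(2 * pi * f * t_ax - 1) + 0.5 * stats::rnorm(n)
    }
    rbind(x, y)
  })
}
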