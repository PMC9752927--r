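test_that("node-set selection induces the expected subgraphs", {
  set.seed(1)
  W <- rand_weights(25)
  rownames(W) <- colnames(W) <- ifcn_montage()
  g_all <- build_graph(W)
  expect_equal(length(g_all$labels), 25)
  expect_equal(unname(g_all$W), unname(W))
  g_ft <- build_graph(W, node_set = frontotemporal_set(), tag = "frontotemporal")
  expect_equal(length(g_ft$labels), 16)
  expect_equal(g_ft$W, W[frontotemporal_set(), frontotemporal_set()])
  expect_error(build_graph(W, node_set = c("Fp1", "XX")),
               class = "pligraph_error")
  # zero-PLI pair is capped at finite distance 1/eps
  W0 <- W
  W0["Fp1", "Fp2"] <- W0["Fp2", "Fp1"] <- 0
  g0 <- build_graph(W0, eps = 1e-6)
  expect_equal(g0$L["Fp1", "Fp2"], 1e6)
})

test_that("mean PLI is the upper-triangle average", {
  W <- matrix(0.5, 4, 4)
  diag(W) <- 0
  expect_equal(mean_pli(build_graph(W)), 0.5)
  W3 <- matrix(0, 3, 3)
  W3[1, 2] <- W3[2, 1] <- 0.2
  W3[1, 3] <- W3[3, 1] <- 0.4
  W3[2, 3] <- W3[3, 2] <- 0.6
  expect_equal(mean_pli(build_graph(W3)), 0.4)
  set.seed(2)
  W6 <- rand_weights(6)
  acc <- 0; cnt <- 0
  for (i in 1:5) for (j in (i + 1):6) { acc <- acc + W6[i, j]; cnt <- cnt + 1 }
  expect_equal(mean_pli(build_graph(W6)), acc / cnt)
})

test_that("weighted clustering matches the triangle-enumeration oracle", {
  set.seed(3)
  for (rep in 1:5) {
    W <- rand_weights(6)
    g <- build_graph(W)
    expect_equal(clustering_coefficient(g, "unit"), oracle_cc(W, 1),
                 tolerance = 1e-12)
    expect_equal(clustering_coefficient(g, "max"), oracle_cc(W, max(W)),
                 tolerance = 1e-12)
  }
  # homogeneous complete graph: CC = w under unit ceiling, 1 under max
  Wh <- matrix(0.6, 5, 5); diag(Wh) <- 0
  expect_equal(clustering_coefficient(build_graph(Wh), "unit"), 0.6)
  expect_equal(clustering_coefficient(build_graph(Wh), "max"), 1)
  # star topology: no triangles
  Ws <- matrix(0, 5, 5)
  Ws[1, 2:5] <- Ws[2:5, 1] <- 0.8
  expect_equal(clustering_coefficient(build_graph(Ws)), 0)
  expect_error(clustering_coefficient(build_graph(matrix(0, 2, 2))),
               class = "pligraph_error")
})

test_that("characteristic path length matches Floyd-Warshall", {
  set.seed(4)
  for (rep in 1:5) {
    W <- rand_weights(7)
    g <- build_graph(W)
    D <- oracle_floyd_warshall(g$L)
    expect_equal(characteristic_path_length(g), mean(D[upper.tri(D)]),
                 tolerance = 1e-12)
  }
  # complete homogeneous graph: direct edges are optimal, PL = 1/w
  Wh <- matrix(0.5, 6, 6); diag(Wh) <- 0
  expect_equal(characteristic_path_length(build_graph(Wh)), 2)
  expect_equal(characteristic_path_length(build_graph(2 * Wh)), 1)
})

test_that("metrics respond monotonically to uniformly stronger coupling", {
  set.seed(5)
  W <- rand_weights(8, lo = 0.1, hi = 0.4)
  W2 <- pmin(W * 1.8, 0.95); diag(W2) <- 0
  g1 <- build_graph(W); g2 <- build_graph(W2)
  expect_gt(mean_pli(g2), mean_pli(g1))
  expect_lt(characteristic_path_length(g2), characteristic_path_length(g1))
  expect_gt(clustering_coefficient(g2), clustering_coefficient(g1))
})

test_that("subnetwork metrics equal whole-graph metrics after restriction", {
  set.seed(6)
  W <- rand_weights(25)
  rownames(W) <- colnames(W) <- ifcn_montage()
  direct <- build_graph(W, node_set = frontotemporal_set())
  whole <- build_graph(W)
  restricted <- build_graph(whole$W, node_set = frontotemporal_set())
  expect_equal(mean_pli(direct), mean_pli(restricted))
  expect_equal(clustering_coefficient(direct),
               clustering_coefficient(restricted))
  expect_equal(characteristic_path_length(direct),
               characteristic_path_length(restricted))
})

test_that("simulated frontotemporal coupling moves CC, PL and PLI as expected", {
  a <- ft_left_frontal(); b <- ft_left_temporal()
  metrics_at <- function(s) {
    cps <- if (s > 0) list(sim_coupling(a, b, strength = s)) else list()
    rec <- simulate_recording(30, 500, couplings = cps, seed = 21)
    ep <- make_epochs(rec, bands = eeg_bands()[2, ], epoch_length_s = 10,
                      total_s = 30)
    g <- build_graph(pli_connectivity(ep)$theta,
                     node_set = frontotemporal_set())
    c(pli = mean_pli(g), cc = clustering_coefficient(g),
      pl = characteristic_path_length(g))
  }
  lo <- metrics_at(0.15)
  hi <- metrics_at(0.85)
  expect_gt(hi["pli"], lo["pli"])
  expect_gt(hi["cc"], lo["cc"])
  expect_lt(hi["pl"], lo["pl"])
})
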