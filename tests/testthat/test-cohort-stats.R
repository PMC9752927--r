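test_that("group comparison reproduces a textbook one-way ANOVA", {
  d <- data.frame(
    value = c(6, 8, 4, 5, 3, 4, 8, 12, 9, 11, 8, 7, 13, 9, 11, 8, 12, 13),
    group = rep(c("a", "b", "c"), each = 6)
  )
  res <- group_compare(d, "value", "group")
  fit <- stats::oneway.test(value ~ group, d, var.equal = TRUE)
  expect_equal(res$f, unname(fit$statistic), tolerance = 1e-10)
  expect_equal(res$p, fit$p.value, tolerance = 1e-10)
  expect_equal(nrow(res$pairwise), 3)
  expect_error(group_compare(data.frame(value = 1:3, group = c("a", "a", "b")),
                             "value"),
               class = "pligraph_error")
  expect_error(group_compare(data.frame(value = rep(1, 6),
                                        group = rep(c("a", "b"), 3)), "value"),
               class = "pligraph_error")
})

test_that("ANOVA type-I error is calibrated near the nominal level", {
  set.seed(10)
  n_sim <- 400
  rejections <- 0
  for (s in seq_len(n_sim)) {
    d <- data.frame(value = rnorm(60), group = rep(c("a", "b", "c"), each = 20))
    if (group_compare(d, "value")$p < 0.05) rejections <- rejections + 1
  }
  expect_gt(rejections / n_sim, 0.02)
  expect_lt(rejections / n_sim, 0.08)
})

test_that("a planted one-SD group shift is detected with high power", {
  set.seed(11)
  n_sim <- 100
  hits <- 0
  for (s in seq_len(n_sim)) {
    d <- data.frame(value = c(rnorm(30), rnorm(30) + 1, rnorm(30)),
                    group = rep(c("a", "b", "c"), each = 30))
    if (group_compare(d, "value")$p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / n_sim, 0.9)
})

test_that("Spearman correlation is rank-exact, tie-safe and null-centered", {
  # monotone transform of the severity score has r = 1
  d <- data.frame(va2 = c(5, 40, 12, 300, 80, 1), metric = NA_real_)
  d$metric <- log(d$va2)
  res <- severity_correlation(d, "metric")
  expect_equal(res$r, 1)
  # tied-rank toy table matches the rank-formula computed by hand
  d2 <- data.frame(va2 = c(1, 2, 2, 4, 5, 6), metric = c(2, 1, 4, 3, 6, 6))
  res2 <- severity_correlation(d2, "metric")
  r_hand <- stats::cor(rank(d2$va2), rank(d2$metric))
  expect_equal(res2$r, r_hand, tolerance = 1e-12)
  # null calibration: independent metric over repeated draws
  set.seed(12)
  rs <- replicate(300, severity_correlation(
    data.frame(va2 = rexp(40), metric = rnorm(40)), "metric")$r)
  expect_lt(abs(mean(rs)), 0.05)
  expect_error(severity_correlation(data.frame(va2 = 1:3, metric = 1:3),
                                    "metric"),
               class = "pligraph_error")
})

test_that("stepwise regression selects planted signal and stays quiet on noise", {
  set.seed(13)
  n <- 200
  make_table <- function(slope) {
    d <- as.data.frame(matrix(rnorm(n * 11), n))
    names(d) <- c("x1", paste0("z", 1:10))
    d$va2 <- slope * d$x1 + rnorm(n)
    d
  }
  # power: planted predictor with slope 0.5 SD selected
  hits <- 0
  n_sim <- 50
  for (s in seq_len(n_sim)) {
    res <- stepwise_regression(make_table(0.5), "va2",
                               c("x1", paste0("z", 1:10)))
    if ("x1" %in% res$terms$term) hits <- hits + 1
  }
  expect_gt(hits / n_sim, 0.9)
  # null: zero-signal response yields an empty model most of the time
  empties <- 0
  for (s in seq_len(n_sim)) {
    res <- stepwise_regression(make_table(0), "va2",
                               c("x1", paste0("z", 1:10)))
    if (nrow(res$terms) == 0) empties <- empties + 1
  }
  expect_gt(empties / n_sim, 0.5)
  # determinism given the table
  tab <- make_table(0.5)
  r1 <- stepwise_regression(tab, "va2", c("x1", paste0("z", 1:10)))
  r2 <- stepwise_regression(tab, "va2", c("x1", paste0("z", 1:10)))
  expect_identical(r1$terms, r2$terms)
  # standardized betas: slope 0.5 with unit noise -> beta ~ 0.45
  expect_equal(r1$terms$beta[r1$terms$term == "x1"], 0.45, tolerance = 0.15)
})

test_that("collinear and degenerate candidates are handled", {
  set.seed(14)
  n <- 80
  d <- data.frame(x1 = rnorm(n))
  d$x2 <- d$x1                    # exact duplicate
  d$x3 <- rep(1, n)               # zero variance
  d$va2 <- 0.8 * d$x1 + rnorm(n)
  expect_warning(res <- stepwise_regression(d, "va2", c("x1", "x2", "x3")),
                 regexp = "zero-variance")
  expect_true(all(res$terms$term %in% c("x1", "x2")))
  expect_equal(nrow(res$terms), 1)  # the duplicate cannot enter twice
})
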