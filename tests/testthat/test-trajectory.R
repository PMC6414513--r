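test_that("knn_graph on collinear points with k=1 is a path", {
  m <- cbind(c(0, 1, 2), 0)
  g <- knn_graph(m, k = 1)
  # 1-2 and 2-3 (plus the bridge that keeps it connected)
  expect_true(igraph::is_connected(g))
  expect_equal(igraph::ecount(g), 2L)
  expect_equal(igraph::degree(g, 2), 2)
})

test_that("knn_graph bridges far blobs with a warning", {
  m <- two_blobs(20, gap = 100, seed = 3)
  expect_warning(g <- knn_graph(m, k = 5), "components")
  expect_true(igraph::is_connected(g))
})

test_that("knn_graph on a dense manifold is connected with mean degree >= k", {
  set.seed(31)
  t <- runif(2000)
  m <- cbind(t + rnorm(2000, 0, 0.01), sin(t * 3) + rnorm(2000, 0, 0.01))
  expect_silent(g <- knn_graph(m, k = 10))
  expect_true(igraph::is_connected(g))
  expect_gte(mean(igraph::degree(g)), 10)
})

test_that("pseudotime orders a noiseless arc perfectly", {
  n <- 200
  m <- cbind(seq(0, 10, length.out = n), 0)
  params <- trajectory_params("x", k = 10, l = 5, n_graphs = 5,
                              n_waypoints = 30, start_rule = 1L, seed = 1)
  pt <- pseudotime(m, params)
  expect_equal(pt$pseudotime[pt$start], 0)
  expect_true(all(pt$pseudotime >= 0 & pt$pseudotime <= 1))
  expect_equal(cor(pt$pseudotime, seq_len(n), method = "spearman"), 1)
})

test_that("pseudotime is deterministic given the seed", {
  set.seed(32)
  m <- cbind(runif(300), runif(300, 0, 0.1))
  params <- trajectory_params("x", k = 15, l = 8, n_graphs = 4,
                              n_waypoints = 40, start_rule = 5L, seed = 9)
  p1 <- pseudotime(m, params)
  p2 <- pseudotime(m, params)
  expect_identical(p1$pseudotime, p2$pseudotime)
})

test_that("pseudotime validates the start rule", {
  m <- matrix(runif(100), 50)
  params <- trajectory_params("x", k = 5, l = 3, n_graphs = 2,
                              n_waypoints = 10, start_rule = 99L)
  expect_error(pseudotime(m, params), "start_rule")
  params$start_rule <- function(mm) integer(0)
  expect_error(pseudotime(m, params), "start_rule")
})

test_that("trajectory_params validates l <= k and n_waypoints", {
  expect_error(trajectory_params("x", k = 5, l = 10), "at most k")
  expect_error(trajectory_params("x", n_waypoints = 1), "at least 2")
})

test_that("channel_trends: constant channel gives a flat trend", {
  pt <- seq(0, 1, length.out = 500)
  vals <- matrix(7, 500, 1, dimnames = list(NULL, "A"))
  tr <- channel_trends(vals, pt, "A", n_points = 20)
  expect_true(all(tr$A == 7))
  expect_equal(nrow(tr), 20L)
})

test_that("channel_trends with window 100% is the global median", {
  set.seed(33)
  vals <- matrix(rnorm(400), 400, 1, dimnames = list(NULL, "A"))
  pt <- runif(400)
  tr <- channel_trends(vals, pt, "A", window = 1, n_points = 5)
  expect_true(all(abs(tr$A - median(vals)) < 1e-12))
})

test_that("channel_trends is invariant to monotone relabeling of pseudotime", {
  set.seed(34)
  vals <- matrix(rnorm(300), 300, 1, dimnames = list(NULL, "A"))
  pt <- runif(300)
  t1 <- channel_trends(vals, pt, "A")
  t2 <- channel_trends(vals, pt^3, "A")  # same ordering
  expect_equal(t1$A, t2$A)
})

test_that("trend_half_rise finds the sigmoid midpoint", {
  x <- seq(0, 1, length.out = 100)
  tr <- data.frame(pseudotime = x, S = plogis((x - 0.6) / 0.05))
  expect_equal(trend_half_rise(tr, "S"), 0.6, tolerance = 0.02)
})
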