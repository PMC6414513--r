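test_that("closed-form E_R and Var_R match exhaustive enumeration", {
  # paths, stars, and random Euclidean MSTs, several (n1, n2) splits
  path_edges <- function(n) cbind(1:(n - 1), 2:n)
  star_edges <- function(n) cbind(rep(1, n - 1), 2:n)
  for (n in c(6, 8, 10)) {
    for (n1 in c(2, n %/% 2)) {
      n2 <- n - n1
      for (edges in list(path_edges(n), star_edges(n))) {
        exact <- fr_exact_null(edges, n1, n2)
        expect_equal(exact$mean, 2 * n1 * n2 / n, tolerance = 1e-9)
        deg <- tabulate(c(edges), n)
        C <- sum(deg * (deg - 1)) / 2
        expect_equal(exact$var_pop, trisyn:::fr_variance(n1, n2, C),
                     tolerance = 1e-9)
      }
    }
  }
  set.seed(13)
  for (i in 1:3) {
    m <- matrix(rnorm(10 * 2), 10)
    edges <- trisyn:::prim_mst(as.matrix(dist(m)))[, 1:2]
    exact <- fr_exact_null(edges, 5, 5)
    deg <- tabulate(c(edges), 10)
    C <- sum(deg * (deg - 1)) / 2
    expect_equal(exact$mean, 5, tolerance = 1e-9)
    expect_equal(exact$var_pop, trisyn:::fr_variance(5, 5, C),
                 tolerance = 1e-9)
  }
})

test_that("the worked instance gives R=1, E_R=3, exact p=0.10", {
  a <- matrix(c(0, 1, 2), ncol = 1)
  b <- matrix(c(10, 11, 12), ncol = 1)
  st <- fr_statistic(a, b)
  expect_equal(st$R_cross, 1)
  expect_equal(st$E_R, 3)
  # pooled MST is the path 1-2-3-4-5-6: exact lower tail at R=1 is 2/20
  exact <- fr_exact_null(cbind(1:5, 2:6), 3, 3)
  expect_equal(exact$p_leq(1), 0.10, tolerance = 1e-12)
  expect_equal(st$Var_R, exact$var_pop, tolerance = 1e-12)
})

test_that("fr_statistic validates input and warns on duplicates", {
  expect_error(fr_statistic(matrix(1), matrix(2)), "at least 2")
  expect_warning(fr_statistic(matrix(c(1, 1), 2), matrix(c(5, 6), 2)),
                 "duplicate")
})

test_that("fr_test is deterministic and summarizes the median p", {
  set.seed(20)
  a <- matrix(rnorm(300 * 2), 300)
  b <- matrix(rnorm(300 * 2, 2), 300)
  p <- fr_params(S = 40, N = 9, seed = 3)
  r1 <- fr_test(a, b, p)
  r2 <- fr_test(a, b, p)
  expect_identical(r1$iterations, r2$iterations)
  expect_equal(r1$p_summary, median(r1$iterations$p))
  expect_equal(nrow(r1$iterations), 9L)
  expect_lt(r1$p_summary, 0.05)  # separated by construction
})

test_that("fr_test lowers S with a warning for small populations", {
  set.seed(21)
  a <- matrix(rnorm(30 * 2), 30)
  b <- matrix(rnorm(500 * 2), 500)
  expect_warning(r <- fr_test(a, b, fr_params(S = 200, N = 5, seed = 1)),
                 "lowering S")
  expect_equal(r$S_used, 60L)
})

test_that("identical populations give large p, different small", {
  set.seed(22)
  base <- matrix(rnorm(400 * 2), 400)
  same <- fr_test(base, base, fr_params(S = 100, N = 15, seed = 2))
  diff <- fr_test(base, base + 3, fr_params(S = 100, N = 15, seed = 2))
  expect_gt(same$p_summary, diff$p_summary)
  expect_lt(diff$p_summary, 1e-4)
})

test_that("fr_matrix puts the largest p on the self-comparison", {
  set.seed(23)
  pops <- list(ref = matrix(rnorm(200 * 2), 200),
               near = matrix(rnorm(200 * 2, 0.3), 200),
               far = matrix(rnorm(200 * 2, 4), 200))
  tab <- fr_matrix(pops, "ref", params = fr_params(S = 80, N = 11, seed = 4))
  expect_equal(tab$population, c("ref", "near", "far"))
  expect_equal(which.max(tab$p_summary), 1L)
  expect_lt(tab$p_summary[3], tab$p_summary[2])
  expect_equal(tab$stars, star_bins(tab$p_summary))
  # empty others -> empty table
  empty <- fr_matrix(pops, "ref", others = character(0),
                     params = fr_params(S = 80, N = 3))
  expect_equal(nrow(empty), 0L)
})

test_that("fr_exact_null validates its inputs", {
  expect_error(fr_exact_null(cbind(1:9, 2:10), 8, 8), "n <= 14")
  expect_error(fr_exact_null(cbind(1:3, 2:4), 3, 3), "edges")
  out <- fr_exact_null(cbind(1:5, 2:6), 3, 3)
  expect_equal(sum(out$pmf), 1)
  expect_equal(out$cdf[length(out$cdf)], 1)
})
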