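test_that("transformed medians commute with the monotone transform", {
  set.seed(1)
  v <- sample(seq(1, 5000), 501)  # odd length, no ties
  expect_equal(transformed_median(v, 5), asinh(median(v) / 5),
               tolerance = 1e-12)
})

test_that("median_shift is zero on identity and antisymmetric", {
  set.seed(2)
  a <- rpois(501, 50)
  b <- rpois(501, 200)
  expect_equal(median_shift(a, a), 0)
  expect_equal(median_shift(a, b), -median_shift(b, a), tolerance = 1e-12)
  expect_gt(median_shift(b, a), 0)
})

test_that("bootstrap_median is deterministic and collapses on constants", {
  set.seed(3)
  v <- rnorm(200)
  p <- stat_params(bootstrap_R = 500, seed = 11)
  b1 <- bootstrap_median(v, p)
  b2 <- bootstrap_median(v, p)
  expect_identical(b1, b2)
  expect_lte(b1$ci_low, b1$point_estimate)
  expect_gte(b1$ci_high, b1$point_estimate)
  const <- bootstrap_median(rep(4, 50), p)
  expect_equal(const$ci_low, 4)
  expect_equal(const$ci_high, 4)
  expect_error(bootstrap_median(numeric(0), p), "empty")
})

test_that("bootstrap percentile CI agrees with the boot package", {
  skip_if_not_installed("boot")
  set.seed(4)
  v <- rlnorm(300)
  p <- stat_params(bootstrap_R = 4000, seed = 5)
  ours <- bootstrap_median(v, p)
  set.seed(5)
  ref <- boot::boot(v, function(d, i) median(d[i]), R = 4000)
  ci <- boot::boot.ci(ref, type = "perc")$percent[4:5]
  # different resampling streams, same estimand: intervals agree closely
  expect_equal(ours$ci_low, ci[1], tolerance = 0.05)
  expect_equal(ours$ci_high, ci[2], tolerance = 0.05)
})

test_that("CI width shrinks with sample size", {
  set.seed(6)
  p <- stat_params(bootstrap_R = 1000, seed = 1)
  w <- vapply(c(50, 500, 5000), function(n) {
    b <- bootstrap_median(rnorm(n), p)
    b$ci_high - b$ci_low
  }, numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("the 4% IdU reporting rule fires strictly above the boundary", {
  p <- panel(channel_def("IdU", "I127", "biosynthesis"))
  mk <- function(n_pos, n) {
    event_table(matrix(c(rep(100, n_pos), rep(0, n - n_pos)), n, 1), p)
  }
  params <- stat_params()
  at_boundary <- idu_fraction_report(mk(4, 100), params)   # exactly 0.04
  expect_equal(at_boundary$fraction, 0.04)
  expect_null(at_boundary$split)
  below <- idu_fraction_report(mk(3, 100), params)         # 0.03
  expect_null(below$split)
  above <- idu_fraction_report(mk(5, 100), params)         # 0.05
  expect_false(is.null(above$split))
  expect_equal(length(above$split$idu_pos) + length(above$split$idu_neg), 100L)
  expect_length(above$split$idu_pos, 5L)
})

test_that("erythroid-style fixture recovers the designed S fraction", {
  p <- panel(channel_def("IdU", "I127", "biosynthesis"))
  spec <- population_spec("ery", 1, idu_positive_fraction = 0.35)
  d <- experiment_design(p, populations = list(spec), n_events = 10000,
                         seed = 12)
  x <- simulate_events(d)
  rep <- idu_fraction_report(x, stat_params())
  expect_equal(rep$fraction, 0.35, tolerance = 0.02)
  expect_false(is.null(rep$split))
})

test_that("shift_table reports control zeros and missing populations as NA", {
  p <- tiny_panel()
  set.seed(7)
  v <- matrix(rpois(600 * 3, 50), 600, 3)
  x <- event_table(v, p)
  popn <- rep(c("p1", "p2"), 300)
  cond <- rep(c("ctrl", "stim"), each = 300)
  popn[cond == "stim" & popn == "p2"] <- "p1"  # p2 absent under stim
  tab <- shift_table(x, popn, cond, channels = c("A", "C"), control = "ctrl")
  ctrl_rows <- tab[tab$condition == "ctrl" & tab$n > 0, ]
  expect_true(all(ctrl_rows$shift == 0))
  missing <- tab[tab$population == "p2" & tab$condition == "stim", ]
  expect_true(all(is.na(missing$shift)))
  expect_true(all(missing$n == 0))
  expect_error(shift_table(x, popn, cond, "A", control = "nope"),
               "control")
  xt <- arcsinh_transform(x)
  expect_error(shift_table(xt, popn, cond, "A", control = "ctrl"),
               "raw counts")
})

test_that("single condition equal to control yields an all-zero table", {
  p <- tiny_panel()
  x <- event_table(matrix(rpois(300, 20), 100, 3), p)
  tab <- shift_table(x, rep("p", 100), rep("ctrl", 100),
                     channels = c("A", "B"), control = "ctrl")
  expect_true(all(tab$shift == 0))
})

test_that("star_bins follows the display legend bins", {
  expect_equal(star_bins(0.5), "")
  expect_equal(star_bins(1e-8), "*")       # 1e-7 > p > 1e-14 gives *
  expect_equal(star_bins(1e-10), "*")
  expect_equal(star_bins(1e-16), "**")
  expect_equal(star_bins(1e-24), "***")
  expect_equal(star_bins(1e-30), "****")
  # boundary values belong to the less significant bin (strict inequalities)
  expect_equal(star_bins(c(1e-7, 1e-14, 1e-21, 1e-28)),
               c("", "*", "**", "***"))
  expect_error(star_bins(2))
})
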