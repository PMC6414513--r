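test_that("arcsinh transform and inverse are exact", {
  x <- tiny_table(matrix(c(0, 10, 100, 3, 7, 2), 2, 3))
  t1 <- arcsinh_transform(x, 5)
  expect_equal(unname(t1$values[1, 1]), 0)  # arcsinh(0) = 0
  expect_equal(unname(t1$values[1, 2]), asinh(100 / 5))
  expect_true(all(t1$transformed))
  back <- inverse_arcsinh(t1, 5)
  expect_equal(back$values, x$values, tolerance = 1e-12)
  expect_error(arcsinh_transform(t1, 5), "already")
  expect_error(inverse_arcsinh(x, 5), "not transformed")
  expect_error(arcsinh_transform(x, 0), "positive")
})

test_that("per-channel transform state is honored", {
  x <- tiny_table(matrix(1:6, 2, 3))
  t1 <- arcsinh_transform(x, 5, channels = "B")
  expect_equal(unname(t1$transformed), c(FALSE, TRUE, FALSE))
  expect_equal(t1$values[, "A"], x$values[, "A"])
  expect_error(arcsinh_transform(t1, 5, channels = c("A", "B")), "already")
})

test_that("otsu_threshold separates two clear modes", {
  set.seed(2)
  v <- c(rnorm(500, 0, 0.3), rnorm(500, 5, 0.3))
  thr <- otsu_threshold(v)
  expect_gt(thr, 1.5)
  expect_lt(thr, 3.5)
  expect_equal(otsu_threshold(rep(3, 10)), 3)
  expect_error(otsu_threshold(numeric(0)), "no finite")
})

test_that("empty gate list is the identity", {
  x <- tiny_table(matrix(1:6, 2, 3))
  g <- apply_gates(x, list())
  expect_true(all(g$mask))
  expect_equal(nrow(g$report), 0L)
})

test_that("keep gate on all-passing events is the identity mask", {
  x <- tiny_table(matrix(100, 5, 3))
  g <- apply_gates(x, list(gate_rule("A", "ge", 1, scale = "raw",
                                     action = "keep")))
  expect_true(all(g$mask))
  expect_equal(g$report$n_out, 5L)
})

test_that("viability gate removes the designed dead fraction", {
  d <- make_scenario("cellcycle", seed = 21, n_events = 20000)
  d$dead_fraction <- 0.10
  d$apoptotic_fraction <- 0
  d$bead_fraction <- 0
  x <- simulate_events(d)
  g <- apply_gates(x, list(gate_rule("cisplatin", "gt", NA,
                                     scale = "transformed", action = "drop")))
  removed <- !g$mask
  expect_equal(mean(removed), 0.10, tolerance = 0.05)
  expect_gt(mean(x$labels$viability[removed] == "dead"), 0.95)
})

test_that("gates on missing channels error", {
  x <- tiny_table(matrix(1, 2, 3))
  expect_error(apply_gates(x, list(gate_rule("nope", "gt", 1))),
               "unknown channel")
})

test_that("idu_positive applies the >10 raw counts rule", {
  p <- panel(channel_def("IdU", "I127", "biosynthesis"))
  x <- event_table(matrix(c(0, 5, 11, 20), 4, 1), p)
  expect_equal(idu_positive(x), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(mean(idu_positive(x)), 0.5)
  z <- event_table(matrix(0, 4, 1), p)
  expect_equal(mean(idu_positive(z)), 0)
  xt <- arcsinh_transform(x)
  expect_error(idu_positive(xt), "raw counts")
})

test_that("bead normalization is the identity under constant sensitivity", {
  d <- make_scenario("cellcycle", seed = 31, n_events = 6000)
  x <- simulate_events(d)
  bn <- bead_normalize(x)
  expect_equal(mean(bn$is_bead), 0.01, tolerance = 0.05)
  expect_true(all(abs(bn$report$scale - 1) < 0.05))
  non_bead_ch <- x$channels$name[x$channels$kind != "bead"]
  ci <- match(non_bead_ch, channel_names(x))
  expect_equal(bn$table$values[, ci], x$values[, ci], tolerance = 0.06)
})

test_that("bead normalization recovers a linear sensitivity drift", {
  d <- make_scenario("cellcycle", seed = 33, n_events = 30000)
  d$noise$sensitivity <- c(1, 0.6)
  x <- simulate_events(d)
  bn <- bead_normalize(x)
  # post-normalization per-window bead median CV < 5% on each bead channel
  norm_cols <- grep("^norm_median_", names(bn$report), value = TRUE)
  for (cc in norm_cols) {
    v <- bn$report[[cc]]
    expect_lt(sd(v) / mean(v), 0.05)
  }
  # raw windows, by contrast, drift by design
  raw_cols <- grep("^median_", names(bn$report), value = TRUE)
  drift <- vapply(raw_cols, function(cc)
    max(bn$report[[cc]]) / min(bn$report[[cc]]), numeric(1L))
  expect_gt(max(drift), 1.3)
})

test_that("bead normalization errors without beads", {
  x <- tiny_table(matrix(1, 10, 3))
  expect_error(bead_normalize(x), "no bead channels")
  p <- rbind(tiny_panel(), channel_def("bead1", "Ce140", "bead"))
  y <- event_table(matrix(1, 10, 4), p)
  expect_error(bead_normalize(y), "no bead events")
})

test_that("debarcode assigns clean keys and flags summed doublets", {
  bc <- paste0("bc", 1:6)
  p <- do.call(panel, lapply(bc, function(nm)
    channel_def(nm, paste0("Pd", nm), "barcode")))
  scheme <- barcode_scheme(bc, k = 3)
  # build noiseless events for keys 1 and 7
  mk <- function(key) {
    v <- rep(0.1, 6)
    v[scheme$keys[[key]]] <- 200
    v
  }
  v <- rbind(mk(1), mk(7), mk(1) + mk(7))  # third is a summed doublet
  x <- event_table(v, p)
  db <- debarcode(x, scheme)
  expect_equal(db$sample_id[1:2], c(1L, 7L))
  expect_true(is.na(db$sample_id[3]))
  expect_true(db$doublet_flag[3])
  expect_false(any(db$doublet_flag[1:2]))
})

test_that("debarcode separation criterion uses min_separation", {
  bc <- paste0("bc", 1:6)
  p <- do.call(panel, lapply(bc, function(nm)
    channel_def(nm, paste0("Pd", nm), "barcode")))
  scheme <- barcode_scheme(bc, k = 3)
  v <- matrix(c(200, 200, 200, 150, 0.1, 0.1), 1)  # 4th channel nearly high
  x <- event_table(v, p)
  strict <- debarcode(x, scheme, min_separation = 0.5)
  loose <- debarcode(x, scheme, min_separation = 0.1)
  expect_true(is.na(strict$sample_id))
  expect_equal(loose$sample_id, 1L)
})
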