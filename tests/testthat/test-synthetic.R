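test_that("population_spec validates fractions and phase profiles", {
  expect_error(population_spec("x", 1.5), "fraction")
  expect_error(population_spec("x", 0.5, channel_medians = c(A = -1)),
               "nonnegative")
  expect_error(population_spec("x", 1, phase_profile = list(
    fractions = c(G0G1 = 0.5, S = 0.4))), "sum to 1")
  expect_error(population_spec("x", 1, phase_profile = list(
    fractions = c(G0G1 = 0.5, Weird = 0.5))), "unknown phase")
})

test_that("experiment_design checks population frequencies", {
  p <- tiny_panel()
  pops <- list(population_spec("a", 0.6), population_spec("b", 0.3))
  expect_error(experiment_design(p, pops), "sum to 1")
})

test_that("apply_inhibitor follows the Hill curve", {
  m <- inhibitor_model("BRU", ic50 = 1)
  expect_equal(apply_inhibitor(c(BRU = 100), m, dose = 0)[["BRU"]], 100)
  expect_equal(apply_inhibitor(c(BRU = 100), m, dose = 1)[["BRU"]], 50)
  # monotone nonincreasing in dose
  doses <- c(0, 0.5, 1, 2, 10, 100)
  vals <- vapply(doses, function(d)
    apply_inhibitor(c(BRU = 100), m, d)[["BRU"]], numeric(1L))
  expect_true(all(diff(vals) <= 0))
  # floor respected at saturating dose
  mf <- inhibitor_model("BRU", ic50 = 1, floor = 0.2)
  expect_equal(apply_inhibitor(c(BRU = 100), mf, dose = 1e9)[["BRU"]], 20,
               tolerance = 1e-6)
  expect_error(apply_inhibitor(c(BRU = 1), m, dose = -1), "nonnegative")
  # untargeted channels untouched
  expect_equal(apply_inhibitor(c(Puromycin = 7), m, 5)[["Puromycin"]], 7)
})

test_that("simulate_events is deterministic and produces valid counts", {
  d <- make_scenario("cellcycle", seed = 3, n_events = 800)
  x <- simulate_events(d)
  y <- simulate_events(d)
  expect_identical(x$values, y$values)
  expect_identical(x$labels, y$labels)
  expect_true(all(x$values >= 0))
  expect_true(all(x$values == round(x$values)))  # raw ion counts are integers
  expect_false(any(x$transformed))
  expect_setequal(unique(x$labels$viability), c("live", "dead", "apoptotic"))
})

test_that("designed fractions are recovered in the truth labels", {
  d <- make_scenario("cellcycle", seed = 9, n_events = 20000)
  x <- simulate_events(d)
  lab <- x$labels
  cells <- lab[!lab$bead, ]
  expect_equal(mean(cells$viability == "dead"), 0.03, tolerance = 0.01)
  expect_equal(mean(cells$phase == "S"), 0.30, tolerance = 0.02)
  expect_equal(mean(lab$bead), 0.01, tolerance = 0.05)
})

test_that("barcode_keys enumerates 3-of-6 into 20 distinct keys", {
  keys <- barcode_keys(6, 3)
  expect_length(keys, 20L)
  expect_equal(anyDuplicated(vapply(keys, paste, "", collapse = ",")), 0L)
  expect_error(barcode_keys(3, 3), "k < m")
})

test_that("pool_with_barcodes labels samples, keys and doublets", {
  p <- rbind(tiny_panel(), barcode_channel_defs_for_test())
  mk <- function(n, val) event_table(matrix(val, n, nrow(p),
                                            dimnames = list(NULL, p$name)), p)
  set.seed(4)
  scheme <- barcode_scheme(p$name[4:9], k = 3, doublet_rate = 0.1)
  pooled <- pool_with_barcodes(list(mk(300, 5), mk(300, 9)), scheme)
  expect_equal(n_events(pooled), 600L)
  expect_equal(pooled$labels$barcode_key, rep(1:2, each = 300))
  expect_gt(sum(pooled$labels$doublet), 20)
  # high channels of the assigned key dominate for singlets
  sing <- which(!pooled$labels$doublet & pooled$labels$barcode_key == 1L)[1:50]
  bc <- pooled$values[sing, 4:9, drop = FALSE]
  top3 <- t(apply(bc, 1, order, decreasing = TRUE))[, 1:3]
  expect_true(all(apply(top3, 1, function(r) setequal(r, scheme$keys[[1L]]))))
  expect_error(pool_with_barcodes(rep(list(mk(2, 1)), 25), scheme),
               "more samples")
})

test_that("inject_spillover adds Poisson counts to the destination only", {
  set.seed(1)
  x <- tiny_table(matrix(rpois(3000, 100), 1000, 3))
  y <- inject_spillover(x, list(list(src = "A", dst = "C", fraction = 0.1)))
  expect_identical(y$values[, "A"], x$values[, "A"])
  expect_identical(y$values[, "B"], x$values[, "B"])
  added <- y$values[, "C"] - x$values[, "C"]
  expect_true(all(added >= 0))
  expect_equal(mean(added), 10, tolerance = 1)
  expect_error(inject_spillover(x, list(list(src = "A", dst = "C",
                                             fraction = 1))), "fraction")
})

test_that("sensitivity drift thins counts monotonically", {
  d <- make_scenario("cellcycle", seed = 5, n_events = 2000)
  d$noise$sensitivity <- c(1, 0.5)
  d$bead_fraction <- 0
  x <- simulate_events(d)
  d$noise$sensitivity <- c(1, 1)
  x0 <- simulate_events(d)
  # mean total counts drop under the drift
  expect_lt(mean(rowSums(x$values)), mean(rowSums(x0$values)))
})

test_that("simulate_cell_cycle encodes the designed phase structure", {
  x <- simulate_cell_cycle(cellcycle_spec(), 8000, seed = 2)
  ph <- x$labels$phase
  med <- function(ch, p) median(channel_values(x, ch)[ph == p])
  expect_gt(med("IdU", "S"), 100)
  expect_lt(med("IdU", "G2"), 10)
  expect_gt(med("CyclinB1", "G2"), med("CyclinB1", "G0G1"))
  expect_gt(med("pHH3", "M_early"), med("pHH3", "G2"))
  expect_lt(med("BRU", "M_early"), med("BRU", "G2"))      # mitotic RNA shutdown
  expect_lt(med("Puromycin", "M_late"), med("Puromycin", "M_early"))
})

test_that("latent continuum drives the designed marker programs", {
  spec <- b_continuum_spec(1)
  p <- scenario_panel("marrow_hierarchy")
  d <- experiment_design(p, populations = list(spec), n_events = 6000,
                         seed = 8)
  x <- simulate_events(d)
  lab <- x$labels
  tau <- lab$tau[!lab$bead]
  expect_true(all(tau >= 0 & tau <= 1, na.rm = TRUE))
  v <- x$values[!lab$bead, ]
  early <- tau < 0.2
  late <- tau > 0.8
  expect_gt(median(v[early, "CD34"]), median(v[late, "CD34"]))
  expect_gt(median(v[late, "IgM"]), median(v[early, "IgM"]))
})

barcode_channel_defs_for_test <- function() {
  panel(channel_def("bcA", "PdA", "barcode"),
        channel_def("bcB", "PdB", "barcode"),
        channel_def("bcC", "PdC", "barcode"),
        channel_def("bcD", "PdD", "barcode"),
        channel_def("bcE", "PdE", "barcode"),
        channel_def("bcF", "PdF", "barcode"))
}
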