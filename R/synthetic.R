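#' Population specification for the event simulator
#'
#' Describes one cell population of a simulated experiment: its frequency,
#' per-channel median raw ion counts, per-channel dispersions (log scale),
#' the fraction of the population in S phase (which receives the elevated IdU
#' median), and optionally either a full cell-cycle phase profile or a latent
#' continuum (per-channel median functions of a pseudotime coordinate).
#'
#' Counts are generated per channel as zero-inflated log-normal-Poisson: a
#' latent intensity `lambda = exp(Normal(log median, spread))` is drawn per
#' event, the observed count is `Poisson(lambda)`, and an extra point mass at
#' zero is applied per channel kind. This reproduces the zero mode plus
#' right-skewed positive mode characteristic of ion-count cytometry channels.
#'
#' @param name Population name.
#' @param frequency Fraction of events belonging to this population.
#' @param channel_medians Named numeric vector of median raw counts; channels
#'   not named default to 0 (background).
#' @param channel_spreads Optional named numeric vector of log-scale standard
#'   deviations overriding the design default for specific channels.
#' @param idu_positive_fraction Fraction of the population in S phase.
#' @param idu_s_median,idu_background IdU median raw counts for S-phase and
#'   non-S-phase events (defaults 200 and 1; the `>10 counts` positivity rule
#'   then separates the phases cleanly).
#' @param phase_profile Optional list with `fractions` (named over phases
#'   `G0G1`, `S`, `G2`, `M_early`, `M_late`, summing to 1) and `medians`
#'   (named list of per-phase channel-median overrides).
#' @param latent Optional list describing a developmental continuum:
#'   `channels` is a named list of functions `f(tau)` returning median counts
#'   for `tau` in \[0, 1\], `idu_fraction` an optional function `f(tau)`.
#' @return A `population_spec` list.
#' @export
population_spec <- function(name, frequency, channel_medians = numeric(0),
                            channel_spreads = NULL,
                            idu_positive_fraction = 0,
                            idu_s_median = 200, idu_background = 1,
                            phase_profile = NULL, latent = NULL) {
  check_fraction(frequency, "frequency")
  check_fraction(idu_positive_fraction, "idu_positive_fraction")
  if (any(channel_medians < 0)) stop("channel medians must be nonnegative")
  if (!is.null(phase_profile)) {
    fr <- phase_profile$fractions
    if (abs(sum(fr) - 1) > 1e-9)
      stop("phase fractions must sum to 1 (got ", sum(fr), ")")
    bad <- setdiff(names(fr), cell_cycle_phases())
    if (length(bad)) stop("unknown phase(s): ", paste(bad, collapse = ", "))
  }
  structure(list(name = name, frequency = frequency,
                 channel_medians = channel_medians,
                 channel_spreads = channel_spreads,
                 idu_positive_fraction = idu_positive_fraction,
                 idu_s_median = idu_s_median,
                 idu_background = idu_background,
                 phase_profile = phase_profile, latent = latent),
            class = "population_spec")
}

#' @rdname population_spec
#' @export
cell_cycle_phases <- function() c("G0G1", "S", "G2", "M_early", "M_late")

#' Inhibitor dose-response model
#'
#' Four-parameter Hill curve acting on channel medians: at dose `d` the median
#' becomes `baseline * (floor + (1 - floor) / (1 + (d / ic50)^hill))`, a
#' monotone nonincreasing function of dose that approaches `floor * baseline`
#' at saturation. Secondary targets (e.g. the depression of nascent RNA and
#' DNA labeling under a translation inhibitor) carry their own parameters.
#'
#' @param target_channel Primary channel whose median is suppressed.
#' @param ic50 Dose at half-maximal effect (> 0).
#' @param hill Hill slope.
#' @param floor Residual fraction of the baseline median at saturating dose,
#'   in \[0, 1\].
#' @param secondary_targets Named list, channel -> `list(ic50, hill, floor)`.
#' @return An `inhibitor_model` list.
#' @export
inhibitor_model <- function(target_channel, ic50, hill = 1, floor = 0,
                            secondary_targets = list()) {
  if (!is.numeric(ic50) || ic50 <= 0) stop("ic50 must be positive")
  check_fraction(floor, "floor")
  for (s in secondary_targets) {
    if (s$ic50 <= 0) stop("secondary ic50 must be positive")
    check_fraction(s$floor %||% 0, "secondary floor")
  }
  structure(list(target_channel = target_channel, ic50 = ic50, hill = hill,
                 floor = floor, secondary_targets = secondary_targets),
            class = "inhibitor_model")
}

#' Apply an inhibitor model to channel medians
#'
#' @param medians Named numeric vector of baseline channel medians.
#' @param model An [inhibitor_model()].
#' @param dose Nonnegative dose (same units as `ic50`).
#' @return Adjusted named median vector.
#' @examples
#' m <- inhibitor_model("BRU", ic50 = 1)
#' apply_inhibitor(c(BRU = 100), m, dose = 1)  # exactly half
#' @export
apply_inhibitor <- function(medians, model, dose) {
  stopifnot(inherits(model, "inhibitor_model"))
  if (!is.numeric(dose) || length(dose) != 1L || dose < 0)
    stop("dose must be a nonnegative number")
  hill_scale <- function(ic50, hill, floor) {
    floor + (1 - floor) / (1 + (dose / ic50)^hill)
  }
  adjust <- function(ch, ic50, hill, floor) {
    if (ch %in% names(medians))
      medians[[ch]] <<- medians[[ch]] * hill_scale(ic50, hill, floor)
  }
  adjust(model$target_channel, model$ic50, model$hill, model$floor)
  for (ch in names(model$secondary_targets)) {
    s <- model$secondary_targets[[ch]]
    adjust(ch, s$ic50, s$hill %||% 1, s$floor %||% 0)
  }
  medians
}

#' Experiment design for the event simulator
#'
#' A fully parameterized description of a simulated acquisition: either a
#' single condition (`populations`) or several barcoded conditions
#' (`samples`, each a list with `name` and `populations`, all sharing the
#' panel). Nuisance structure -- non-viable and apoptotic cells, calibration
#' bead events, palladium sample barcodes with doublets, +1-mass isotope
#' spillover, and a linear acquisition sensitivity drift -- is part of the
#' design so the preprocessing stages have something real to remove.
#'
#' @param panel Panel `data.frame` (see [channel_def()]).
#' @param populations List of [population_spec()] (single-condition designs).
#' @param samples List of `list(name=, populations=, inhibitor=)` for
#'   multi-condition designs; `n_events` is then per sample.
#' @param n_events Number of cell events (per sample).
#' @param dead_fraction,apoptotic_fraction Fractions of cell events drawn as
#'   cisplatin-positive dead or cleaved-Caspase3-positive apoptotic.
#' @param bead_fraction Fraction of bead events appended to the pooled data.
#' @param barcode_scheme Optional scheme from [barcode_scheme()].
#' @param spillover List of `list(src=, dst=, fraction=)` spillover rules.
#' @param inhibitor Optional `list(model = inhibitor_model, dose =)` applied
#'   to every population's medians.
#' @param noise List: `spread` (default log-sd 0.3), `zero_inflation` (named
#'   by channel kind), `sensitivity` (length-2, linear drift of instrument
#'   sensitivity over acquisition, default `c(1, 1)`).
#' @param dead_channel,apoptotic_channel Viability channel names.
#' @param seed Simulation seed.
#' @return An `experiment_design` list.
#' @export
experiment_design <- function(panel, populations = NULL, samples = NULL,
                              n_events = 10000L,
                              dead_fraction = 0, apoptotic_fraction = 0,
                              bead_fraction = 0, barcode_scheme = NULL,
                              spillover = NULL, inhibitor = NULL,
                              noise = list(),
                              dead_channel = "cisplatin",
                              apoptotic_channel = "cCaspase3",
                              seed = 0L) {
  validate_panel(panel)
  if (is.null(samples)) {
    stopifnot(!is.null(populations))
    samples <- list(list(name = "sample1", populations = populations))
  }
  for (s in samples) {
    freqs <- vapply(s$populations, `[[`, numeric(1L), "frequency")
    if (abs(sum(freqs) - 1) > 1e-9)
      stop("population frequencies must sum to 1 in sample '",
           s$name, "' (got ", sum(freqs), ")")
  }
  check_fraction(dead_fraction, "dead_fraction")
  check_fraction(apoptotic_fraction, "apoptotic_fraction")
  check_fraction(bead_fraction, "bead_fraction")
  for (r in spillover %||% list())
    if (r$fraction < 0 || r$fraction >= 1)
      stop("spillover fraction must be in [0, 1)")
  noise <- utils::modifyList(list(
    spread = 0.3,
    zero_inflation = c(phenotype = 0.02, biosynthesis = 0.02, barcode = 0,
                       bead = 0, viability = 0.02, dna_content = 0,
                       signaling = 0.05),
    sensitivity = c(1, 1),
    bead_median = 500, bead_background = 0.2,
    positive_viability_median = 300), noise)
  structure(list(panel = panel, samples = samples,
                 n_events = as.integer(n_events),
                 dead_fraction = dead_fraction,
                 apoptotic_fraction = apoptotic_fraction,
                 bead_fraction = bead_fraction,
                 barcode_scheme = barcode_scheme, spillover = spillover,
                 inhibitor = inhibitor, noise = noise,
                 dead_channel = dead_channel,
                 apoptotic_channel = apoptotic_channel,
                 seed = as.integer(seed)),
            class = "experiment_design")
}

#' Combinatorial barcode keys and schemes
#'
#' `barcode_keys(m, k)` enumerates all k-high-of-m channel combinations in
#' lexicographic order (the default 3-of-6 palladium scheme yields 20 keys).
#' `barcode_scheme()` bundles the keys with the barcode channel names and the
#' doublet rate used when pooling.
#'
#' @param m Number of barcode channels.
#' @param k Number of "high" channels per key (`k < m`).
#' @return `barcode_keys`: list of integer vectors (indices into the barcode
#'   channels); `barcode_scheme`: a `barcode_scheme` list.
#' @export
barcode_keys <- function(m, k) {
  if (k >= m) stop("barcode scheme requires k < m")
  unname(as.list(as.data.frame(utils::combn(m, k))))
}

#' @rdname barcode_keys
#' @param channels Barcode channel names (length `m`).
#' @param keys Key list (default all [barcode_keys()] combinations).
#' @param high_median,low_median Median raw counts of high and low barcode
#'   channels (defaults 200 and 0.1).
#' @param doublet_rate Fraction of pooled events turned into doublets by
#'   summing in a second random event.
#' @export
barcode_scheme <- function(channels, k = 3L, keys = NULL,
                           high_median = 200, low_median = 0.1,
                           doublet_rate = 0) {
  m <- length(channels)
  keys <- keys %||% barcode_keys(m, k)
  if (anyDuplicated(vapply(keys, paste, character(1L), collapse = ",")))
    stop("barcode keys must be distinct")
  check_fraction(doublet_rate, "doublet_rate")
  structure(list(channels = channels, m = m, k = as.integer(k), keys = keys,
                 high_median = high_median, low_median = low_median,
                 doublet_rate = doublet_rate),
            class = "barcode_scheme")
}

# Per-event median matrix and labels for one population.
population_medians <- function(spec, n, panel, idu_channel = "IdU") {
  p <- nrow(panel)
  med <- matrix(0, n, p, dimnames = list(NULL, panel$name))
  base <- spec$channel_medians
  med[, intersect(names(base), panel$name)] <-
    rep(base[intersect(names(base), panel$name)], each = n)
  phase <- rep("G0G1", n)
  tau <- rep(NA_real_, n)
  if (!is.null(spec$latent)) {
    tau <- runif(n)
    for (ch in names(spec$latent$channels)) {
      if (ch %in% panel$name)
        med[, ch] <- pmax(spec$latent$channels[[ch]](tau), 0)
    }
    idu_f <- spec$latent$idu_fraction
    frac <- if (is.null(idu_f)) rep(spec$idu_positive_fraction, n)
            else idu_f(tau)
    phase <- ifelse(runif(n) < frac, "S", "G0G1")
  } else if (!is.null(spec$phase_profile)) {
    fr <- spec$phase_profile$fractions
    phase <- sample(names(fr), n, replace = TRUE, prob = fr)
    for (ph in names(spec$phase_profile$medians)) {
      ov <- spec$phase_profile$medians[[ph]]
      idx <- phase == ph
      for (ch in intersect(names(ov), panel$name))
        med[idx, ch] <- ov[[ch]]
    }
  } else if (spec$idu_positive_fraction > 0) {
    phase <- ifelse(runif(n) < spec$idu_positive_fraction, "S", "G0G1")
  }
  if (idu_channel %in% panel$name && is.null(spec$phase_profile)) {
    med[, idu_channel] <- ifelse(phase == "S", spec$idu_s_median,
                                 spec$idu_background)
  }
  list(medians = med, phase = phase, tau = tau)
}

# Zero-inflated log-normal-Poisson draw given a per-event median matrix.
draw_counts <- function(med, spreads, zero_inflation) {
  n <- nrow(med)
  p <- ncol(med)
  counts <- matrix(0, n, p, dimnames = dimnames(med))
  pos <- med > 0
  if (any(pos)) {
    sd_mat <- if (is.matrix(spreads)) spreads
              else matrix(spreads, n, p, byrow = TRUE)
    lam <- exp(rnorm(sum(pos), mean = log(med[pos]), sd = sd_mat[pos]))
    counts[pos] <- rpois(sum(pos), lam)
  }
  zi <- matrix(runif(n * p), n, p) <
    matrix(zero_inflation, n, p, byrow = TRUE)
  counts[zi] <- 0
  counts
}

# One sample (condition) of a design: cell events only, raw counts, truth
# labels; barcodes/beads/drift/spillover are layered on by simulate_events.
simulate_sample <- function(design, sample) {
  panel <- design$panel
  n <- design$n_events
  specs <- sample$populations
  freqs <- vapply(specs, `[[`, numeric(1L), "frequency")
  pop_idx <- sample.int(length(specs), n, replace = TRUE, prob = freqs)
  ord <- order(pop_idx)  # generate per population, then restore order
  med <- matrix(0, n, nrow(panel), dimnames = list(NULL, panel$name))
  phase <- character(n)
  tau <- rep(NA_real_, n)
  pop <- character(n)
  inh <- sample$inhibitor %||% design$inhibitor
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    idx <- which(pop_idx == i)
    if (!length(idx)) next
    if (!is.null(inh))
      spec$channel_medians <- apply_inhibitor(spec$channel_medians,
                                              inh$model, inh$dose)
    pm <- population_medians(spec, length(idx), panel)
    med[idx, ] <- pm$medians
    phase[idx] <- pm$phase
    tau[idx] <- pm$tau
    pop[idx] <- spec$name
  }
  viability <- rep("live", n)
  nd <- round(design$dead_fraction * n)
  na <- round(design$apoptotic_fraction * n)
  status_idx <- sample.int(n, min(n, nd + na))
  viability[status_idx[seq_len(min(nd, length(status_idx)))]] <- "dead"
  if (na > 0 && length(status_idx) > nd)
    viability[status_idx[(nd + 1L):length(status_idx)]] <- "apoptotic"
  posv <- design$noise$positive_viability_median
  if (design$dead_channel %in% panel$name)
    med[, design$dead_channel] <- ifelse(viability == "dead", posv, 1)
  if (design$apoptotic_channel %in% panel$name)
    med[, design$apoptotic_channel] <- ifelse(viability == "apoptotic", posv, 1)
  spreads <- matrix(design$noise$spread, n, nrow(panel),
                    dimnames = list(NULL, panel$name))
  for (i in seq_along(specs)) {
    ov <- specs[[i]]$channel_spreads
    if (!is.null(ov)) {
      idx <- pop_idx == i
      for (ch in intersect(names(ov), panel$name))
        spreads[idx, ch] <- ov[[ch]]
    }
  }
  zi <- design$noise$zero_inflation[panel$kind]
  zi[is.na(zi)] <- 0
  counts <- draw_counts(med, spreads, zi)
  event_table(counts, panel,
              labels = data.frame(sample = sample$name, population = pop,
                                  phase = phase, tau = tau,
                                  viability = viability, bead = FALSE,
                                  doublet = FALSE,
                                  stringsAsFactors = FALSE))
}

#' Simulate a full mass-cytometry acquisition
#'
#' Generates the raw-count event table of an [experiment_design()], with
#' per-event ground-truth labels (`sample`, `population`, `phase`, `tau`,
#' `viability`, `bead`, `doublet`, `barcode_key`). Conditions are generated
#' independently, pooled through [pool_with_barcodes()] when a barcode scheme
#' is present, bead events are appended, the event order is shuffled (as in
#' an acquisition of a pooled tube), the sensitivity drift is applied by
#' binomial thinning, and spillover is injected last. Deterministic given
#' `design$seed`.
#'
#' @param design An [experiment_design()].
#' @return An [event_table()] of raw counts with truth labels.
#' @export
simulate_events <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  set.seed(design$seed)
  tables <- lapply(design$samples, function(s) simulate_sample(design, s))
  if (!is.null(design$barcode_scheme)) {
    pooled <- pool_with_barcodes(tables, design$barcode_scheme)
  } else {
    pooled <- bind_events(tables)
    pooled$labels$barcode_key <- NA_integer_
  }
  nb <- round(design$bead_fraction * n_events(pooled))
  if (nb > 0) {
    panel <- design$panel
    bead_ch <- panel$name[panel$kind == "bead"]
    if (!length(bead_ch)) stop("bead_fraction > 0 but panel has no bead channels")
    med <- matrix(design$noise$bead_background, nb, nrow(panel),
                  dimnames = list(NULL, panel$name))
    med[, bead_ch] <- design$noise$bead_median
    counts <- draw_counts(med, rep(0.1, nrow(panel)),
                          rep(0, nrow(panel)))
    beads <- event_table(counts, panel,
                         labels = data.frame(sample = rep("beads", nb),
                                             population = "bead", phase = "",
                                             tau = NA_real_,
                                             viability = "live", bead = TRUE,
                                             doublet = FALSE,
                                             barcode_key = NA_integer_,
                                             stringsAsFactors = FALSE))
    pooled <- bind_events(list(pooled, beads))
  }
  pooled <- subset_events(pooled, sample.int(n_events(pooled)))
  sens <- design$noise$sensitivity
  if (any(sens != 1)) {
    s <- seq(sens[1L], sens[2L], length.out = n_events(pooled))
    if (any(s < 0 | s > 1)) stop("sensitivity drift must stay within (0, 1]")
    v <- pooled$values
    for (j in seq_len(ncol(v))) v[, j] <- rbinom(nrow(v), v[, j], s)
    pooled$values <- v
  }
  if (!is.null(design$spillover))
    pooled <- inject_spillover(pooled, design$spillover)
  pooled
}

#' Simulate one cell-cycle-structured population
#'
#' Draws `n` events from a [population_spec()] carrying a `phase_profile`,
#' enforcing the phase truth model: IdU elevated only in S, CyclinB1
#' low/mid/high across G0G1/S/G2, p-HH3 high only in mitosis, nascent-RNA
#' (BRU) median suppressed in mitosis relative to G2, puromycin reduced only
#' in late mitosis, p-4EBP1 maximal in early mitosis. The phase structure is
#' entirely encoded in the spec's per-phase median overrides; this function
#' draws phases and counts.
#'
#' @param spec [population_spec()] with a `phase_profile`.
#' @param n Number of events.
#' @param seed Seed.
#' @param panel Panel; defaults to the cell-cycle scenario panel.
#' @param spread Log-scale dispersion.
#' @return An [event_table()] with `phase` truth labels.
#' @export
simulate_cell_cycle <- function(spec, n, seed = 0L,
                                panel = scenario_panel("cellcycle"),
                                spread = 0.3) {
  stopifnot(inherits(spec, "population_spec"), !is.null(spec$phase_profile))
  set.seed(seed)
  pm <- population_medians(spec, n, panel)
  counts <- draw_counts(pm$medians, rep(spread, nrow(panel)),
                        rep(0, nrow(panel)))
  event_table(counts, panel,
              labels = data.frame(population = spec$name, phase = pm$phase,
                                  stringsAsFactors = FALSE))
}

#' Pool barcoded samples, generating doublets
#'
#' Each sample's events receive its k-of-m barcode key: the key's "high"
#' palladium channels are drawn at the scheme's high median, the remaining
#' barcode channels near zero. After pooling, each event independently becomes
#' a doublet with probability `doublet_rate` by summing in the channel values
#' of a second random event from any sample; truth labels record sample of
#' origin, key index and doublet status. Event order within and across
#' samples is preserved (samples are concatenated in order).
#'
#' @param tables List of [event_table()]s sharing a panel that contains the
#'   scheme's barcode channels.
#' @param scheme A [barcode_scheme()].
#' @return Pooled [event_table()].
#' @export
pool_with_barcodes <- function(tables, scheme) {
  stopifnot(inherits(scheme, "barcode_scheme"))
  if (length(tables) > length(scheme$keys))
    stop("more samples (", length(tables), ") than barcode keys (",
         length(scheme$keys), ")")
  out <- vector("list", length(tables))
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    ci <- match_channel(t, scheme$channels)
    key <- scheme$keys[[i]]
    n <- n_events(t)
    med <- matrix(scheme$low_median, n, length(ci))
    med[, key] <- scheme$high_median
    t$values[, ci] <- matrix(rpois(n * length(ci), med), n)
    if (is.null(t$labels)) t <- set_labels(t, sample = rep(paste0("sample", i), n))
    t$labels$barcode_key <- i
    if (is.null(t$labels$doublet)) t$labels$doublet <- FALSE
    out[[i]] <- t
  }
  pooled <- bind_events(out)
  n <- n_events(pooled)
  if (scheme$doublet_rate > 0 && n > 1L) {
    is_dbl <- runif(n) < scheme$doublet_rate
    idx <- which(is_dbl)
    if (length(idx)) {
      partner <- sample.int(n, length(idx), replace = TRUE)
      pooled$values[idx, ] <- pooled$values[idx, , drop = FALSE] +
        pooled$values[partner, , drop = FALSE]
      pooled$labels$doublet[idx] <- TRUE
    }
  }
  pooled
}

#' Inject +1-mass isotope spillover
#'
#' For each rule, the destination channel receives an extra
#' `Poisson(fraction * source count)` contribution per event (e.g. the
#' CD4-Gd157 into Puromycin-Gd158 contamination); the source is unchanged.
#'
#' @param x Raw-count [event_table()].
#' @param rules List of `list(src=, dst=, fraction=)`.
#' @return The event table with spillover added.
#' @export
inject_spillover <- function(x, rules) {
  for (r in rules) {
    if (r$fraction < 0 || r$fraction >= 1) stop("spillover fraction must be in [0, 1)")
    if (r$fraction == 0) next
    src <- channel_values(x, r$src)
    j <- match_channel(x, r$dst)
    x$values[, j] <- x$values[, j] + rpois(length(src), r$fraction * src)
  }
  x
}
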