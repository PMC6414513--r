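#' Statistics parameters
#'
#' @param bootstrap_R Bootstrap replicates (default 1000).
#' @param ci_level Confidence level (default 0.95).
#' @param idu_threshold IdU positivity threshold in raw counts (default 10).
#' @param idu_report_min Minimum IdU-positive fraction of a parent population
#'   for its IdU-positive/negative split to be reported (default 0.04).
#' @param seed Seed for the bootstrap draws.
#' @return A `stat_params` list.
#' @export
stat_params <- function(bootstrap_R = 1000L, ci_level = 0.95,
                        idu_threshold = 10, idu_report_min = 0.04,
                        seed = 0L) {
  if (bootstrap_R < 1L) stop("bootstrap_R must be at least 1")
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must be in (0, 1)")
  structure(list(bootstrap_R = as.integer(bootstrap_R), ci_level = ci_level,
                 idu_threshold = idu_threshold,
                 idu_report_min = idu_report_min, seed = as.integer(seed)),
            class = "stat_params")
}

#' Median on the arcsinh scale
#'
#' `transformed_median(x)` is the median of `asinh(x / cofactor)`; because
#' the transform is strictly monotone this equals the transform of the raw
#' median for odd sample sizes without ties.
#'
#' @param values Raw ion counts.
#' @param cofactor Arcsinh cofactor (default 5).
#' @return The transformed median.
#' @export
transformed_median <- function(values, cofactor = 5) {
  median(asinh(values / cofactor))
}

#' Median shift relative to a control population
#'
#' The difference of arcsinh-transformed medians,
#' `transformed_median(pop) - transformed_median(control)` -- a log-fold-
#' change analog for ion counts, zero when the populations are identical and
#' antisymmetric under swapping them.
#'
#' @param pop_values,control_values Raw counts of the two populations.
#' @param cofactor Arcsinh cofactor.
#' @return The shift (transformed units).
#' @export
median_shift <- function(pop_values, control_values, cofactor = 5) {
  transformed_median(pop_values, cofactor) -
    transformed_median(control_values, cofactor)
}

#' Ordinary nonparametric bootstrap of the median
#'
#' `R` resamples with replacement of size `n`, percentile confidence interval
#' at `ci_level`. Deterministic given `params$seed`.
#'
#' @param values Numeric vector (n > 0).
#' @param params [stat_params()].
#' @return A `bootstrap_summary` list: `point_estimate`, `boot_median`,
#'   `ci_low`, `ci_high`, `R`.
#' @export
bootstrap_median <- function(values, params = stat_params()) {
  n <- length(values)
  if (n == 0L) stop("cannot bootstrap an empty sample")
  set.seed(params$seed)
  R <- params$bootstrap_R
  reps <- matrixStats::rowMedians(
    matrix(values[sample.int(n, n * R, replace = TRUE)], nrow = R))
  alpha <- (1 - params$ci_level) / 2
  ci <- unname(quantile(reps, c(alpha, 1 - alpha)))
  structure(list(point_estimate = median(values),
                 boot_median = median(reps),
                 ci_low = ci[1L], ci_high = ci[2L], R = R),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("median %.4g (bootstrap %.4g, CI [%.4g, %.4g], R = %d)\n",
              x$point_estimate, x$boot_median, x$ci_low, x$ci_high, x$R))
  invisible(x)
}

#' IdU-positive fraction with the 4% reporting rule
#'
#' Computes the IdU-positive fraction of a parent population and, only when
#' it exceeds `idu_report_min` (default 4%), returns the IdU-positive and
#' IdU-negative subpopulation indices for separate reporting.
#'
#' @param x [event_table()] of the parent population (raw IdU channel).
#' @param params [stat_params()].
#' @param channel IdU channel name.
#' @return List: `fraction`, `n`, and (iff the rule fires) `split` with
#'   `idu_pos` / `idu_neg` event indices partitioning the parent.
#' @export
idu_fraction_report <- function(x, params = stat_params(), channel = "IdU") {
  pos <- idu_positive(x, threshold = params$idu_threshold, channel = channel)
  fraction <- mean(pos)
  out <- list(fraction = fraction, n = length(pos))
  if (fraction > params$idu_report_min)
    out$split <- list(idu_pos = which(pos), idu_neg = which(!pos))
  out
}

#' Shift table across conditions
#'
#' One arcsinh-median shift per (population, condition, channel) relative to
#' the same population in the control condition. Populations are matched
#' across conditions by name; events of same-named nodes are pooled. A
#' population absent at some condition yields `NA` (missing), never 0.
#'
#' @param x Raw-count [event_table()].
#' @param population Population name per event (e.g. from
#'   [event_populations()] or truth labels).
#' @param condition Condition per event (e.g. stimulation time).
#' @param channels Channels to tabulate.
#' @param control Control condition name.
#' @param cofactor Arcsinh cofactor.
#' @return Long data frame: `population`, `condition`, `channel`, `shift`,
#'   `n`; the control condition's shifts are identically 0.
#' @export
shift_table <- function(x, population, condition, channels, control,
                        cofactor = 5) {
  stopifnot(inherits(x, "event_table"),
            length(population) == n_events(x),
            length(condition) == n_events(x))
  condition <- as.character(condition)
  if (!control %in% condition)
    stop("control condition '", control, "' has no events")
  ci <- match_channel(x, channels)
  if (any(x$transformed[ci]))
    stop("shift_table expects raw counts (shifts are arcsinh differences)")
  pops <- sort(unique(population))
  conds <- unique(condition)
  out <- expand.grid(population = pops, condition = conds, channel = channels,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$shift <- NA_real_
  out$n <- 0L
  for (p in pops) {
    ctrl_idx <- which(population == p & condition == control)
    for (cd in conds) {
      idx <- which(population == p & condition == cd)
      rows <- out$population == p & out$condition == cd
      out$n[rows] <- length(idx)
      if (!length(idx) || !length(ctrl_idx)) next
      for (ch in channels) {
        v <- x$values[idx, match_channel(x, ch)]
        vc <- x$values[ctrl_idx, match_channel(x, ch)]
        out$shift[rows & out$channel == ch] <- median_shift(v, vc, cofactor)
      }
    }
  }
  out
}

#' Significance stars for population-equivalence probabilities
#'
#' Bins a p-value into the display convention used for the population-
#' equivalence tests: `""` for p >= 1e-7, `"*"` down to 1e-14, `"**"` down to
#' 1e-21, `"***"` down to 1e-28, `"****"` below 1e-28.
#'
#' @param p Probability (vectorized).
#' @return Character vector of star strings.
#' @examples
#' star_bins(c(0.5, 1e-10, 1e-30))
#' @export
star_bins <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  cut_levels <- c("****", "***", "**", "*", "")
  idx <- findInterval(p, c(1e-28, 1e-21, 1e-14, 1e-7), left.open = FALSE) + 1L
  cut_levels[idx]
}
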