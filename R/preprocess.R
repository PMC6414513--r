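#' Arcsinh transformation
#'
#' The variance-stabilizing transform standard for ion counts:
#' `y = asinh(x / cofactor)`, default cofactor 5. Applied per channel; the
#' per-channel transform state is tracked on the table and applying the
#' transform twice is an error. `inverse_arcsinh()` restores raw counts
#' exactly (`x = cofactor * sinh(y)`).
#'
#' @param x An [event_table()].
#' @param cofactor Positive cofactor (default 5).
#' @param channels Channels to transform; default all channels.
#' @return The transformed table.
#' @examples
#' \dontrun{asinh(10 / 5)  # = 1.44363..., the transformed value of 10 counts}
#' @export
arcsinh_transform <- function(x, cofactor = 5, channels = NULL) {
  stopifnot(inherits(x, "event_table"))
  if (!is.numeric(cofactor) || cofactor <= 0) stop("cofactor must be positive")
  channels <- channels %||% channel_names(x)
  ci <- match_channel(x, channels)
  if (any(x$transformed[ci]))
    stop("channel(s) already arcsinh-transformed: ",
         paste(channels[x$transformed[ci]], collapse = ", "))
  x$values[, ci] <- asinh(x$values[, ci, drop = FALSE] / cofactor)
  x$transformed[ci] <- TRUE
  attr(x, "cofactor") <- cofactor
  x
}

#' @rdname arcsinh_transform
#' @export
inverse_arcsinh <- function(x, cofactor = 5, channels = NULL) {
  stopifnot(inherits(x, "event_table"))
  channels <- channels %||% channel_names(x)
  ci <- match_channel(x, channels)
  if (any(!x$transformed[ci]))
    stop("channel(s) not transformed: ",
         paste(channels[!x$transformed[ci]], collapse = ", "))
  x$values[, ci] <- cofactor * sinh(x$values[, ci, drop = FALSE])
  x$transformed[ci] <- FALSE
  x
}

#' Otsu threshold between two modes of a channel
#'
#' Places a cutoff by maximizing the between-class variance over a histogram
#' of the values -- used for the viability/apoptosis gates, whose criteria
#' the analysis states qualitatively (positive vs negative) without numeric
#' cutoffs.
#'
#' @param v Numeric vector (typically arcsinh-transformed).
#' @param n_breaks Histogram resolution.
#' @return The threshold value.
#' @export
otsu_threshold <- function(v, n_breaks = 256L) {
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite values for Otsu thresholding")
  r <- range(v)
  if (r[1L] == r[2L]) return(r[1L])
  h <- hist(v, breaks = seq(r[1L], r[2L], length.out = n_breaks + 1L),
            plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  # with well-separated modes the criterion plateaus across the empty gap;
  # take the middle of the plateau rather than its first bin
  top <- which(sigma_b >= max(sigma_b) - 1e-12 * max(sigma_b))
  mean(mids[range(top)])
}

#' Gate rule
#'
#' A threshold filter on one channel: events satisfying `channel op threshold`
#' are kept, dropped or flagged. `threshold = NA` means "place the cutoff by
#' Otsu's method on this channel at gating time" (the default for the
#' viability and apoptosis gates).
#'
#' @param channel Channel name.
#' @param op One of `"gt"`, `"ge"`, `"lt"`, `"le"`.
#' @param threshold Numeric cutoff, or `NA` for Otsu.
#' @param scale `"raw"` or `"transformed"` -- the scale the threshold refers
#'   to; the gate transforms on the fly if the table's state differs.
#' @param action `"keep"` (drop events not satisfying the rule), `"drop"`
#'   (drop events satisfying it) or `"flag"` (report only).
#' @return A `gate_rule` list.
#' @export
gate_rule <- function(channel, op = c("gt", "ge", "lt", "le"), threshold = NA,
                      scale = c("transformed", "raw"),
                      action = c("drop", "keep", "flag")) {
  op <- match.arg(op)
  scale <- match.arg(scale)
  action <- match.arg(action)
  if (!is.na(threshold) && !is.finite(threshold))
    stop("gate threshold must be finite (or NA for Otsu)")
  structure(list(channel = channel, op = op, threshold = threshold,
                 scale = scale, action = action),
            class = "gate_rule")
}

gate_op <- function(v, op, thr) {
  switch(op, gt = v > thr, ge = v >= thr, lt = v < thr, le = v <= thr)
}

#' Apply an ordered list of gate rules
#'
#' Rules are applied in order to the events still in the gate; the result is
#' an index mask over the *original* events (event order is never changed)
#' plus a per-rule report of events in/out and the thresholds used.
#'
#' @param x An [event_table()].
#' @param rules List of [gate_rule()]s.
#' @param cofactor Cofactor used when a rule's scale differs from the
#'   channel's current state.
#' @return A list with `mask` (logical, length `n_events(x)`), `flags`
#'   (logical matrix for flag rules) and `report` (data frame: rule, channel,
#'   threshold, n_in, n_out).
#' @export
apply_gates <- function(x, rules, cofactor = 5) {
  stopifnot(inherits(x, "event_table"))
  mask <- rep(TRUE, n_events(x))
  report <- data.frame(rule = character(0L), channel = character(0L),
                       op = character(0L), threshold = numeric(0L),
                       action = character(0L), n_in = integer(0L),
                       n_out = integer(0L))
  flags <- NULL
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    ci <- match_channel(x, r$channel)
    v <- x$values[, ci]
    if (r$scale == "transformed" && !x$transformed[ci]) v <- asinh(v / cofactor)
    if (r$scale == "raw" && x$transformed[ci]) v <- cofactor * sinh(v)
    thr <- r$threshold
    if (is.na(thr)) thr <- otsu_threshold(v[mask])
    hit <- gate_op(v, r$op, thr)
    n_in <- sum(mask)
    if (r$action == "keep") {
      mask <- mask & hit
    } else if (r$action == "drop") {
      mask <- mask & !hit
    } else {
      fl <- mask & hit
      flags <- cbind(flags, stats::setNames(data.frame(fl), r$channel))
    }
    report <- rbind(report, data.frame(
      rule = i, channel = r$channel, op = r$op, threshold = thr,
      action = r$action, n_in = n_in, n_out = sum(mask)))
  }
  list(mask = mask, flags = flags, report = report)
}

#' IdU positivity (DNA-synthesis activity)
#'
#' Flags events with more than `threshold` raw counts of incorporated IdU
#' (default 10 counts). The rule is defined on raw ion counts, so the IdU
#' channel must not be arcsinh-transformed; calibrate the threshold on an
#' unlabeled control when moving to a new cell system.
#'
#' @param x An [event_table()] with a raw IdU channel.
#' @param threshold Count threshold (default 10).
#' @param channel IdU channel name.
#' @return Logical vector, one flag per event.
#' @export
idu_positive <- function(x, threshold = 10, channel = "IdU") {
  stopifnot(inherits(x, "event_table"))
  ci <- match_channel(x, channel)
  if (x$transformed[ci])
    stop("IdU positivity is defined on raw counts but channel '", channel,
         "' is arcsinh-transformed; apply inverse_arcsinh() first")
  x$values[, ci] > threshold
}

#' Bead normalization of acquisition sensitivity drift
#'
#' Identifies calibration-bead events (all bead channels above `bead_threshold`
#' raw counts), splits the acquisition into windows of `window` events,
#' computes a per-window sensitivity scale as the geometric mean over bead
#' channels of `reference median / window bead median` (reference = whole-run
#' bead median), interpolates the scale over event index, and multiplies all
#' non-bead channels by it. Bead events are flagged for downstream exclusion.
#'
#' @param x Raw [event_table()] containing bead events.
#' @param bead_channels Bead channel names (default: panel channels of kind
#'   `"bead"`).
#' @param window Events per normalization window (default 5000).
#' @param bead_threshold Raw count threshold identifying beads.
#' @return List: `table` (normalized, with a `bead` label column), `report`
#'   (per-window bead medians, scales, normalized medians), `is_bead`.
#' @export
bead_normalize <- function(x, bead_channels = NULL, window = 5000L,
                           bead_threshold = 100) {
  stopifnot(inherits(x, "event_table"))
  bead_channels <- bead_channels %||%
    x$channels$name[x$channels$kind == "bead"]
  if (!length(bead_channels)) stop("no bead channels given or found in panel")
  ci <- match_channel(x, bead_channels)
  bv <- x$values[, ci, drop = FALSE]
  is_bead <- rowSums(bv > bead_threshold) == length(ci)
  if (!any(is_bead))
    stop("no bead events found; if this run has no beads, skip normalization")
  n <- n_events(x)
  win <- pmin((seq_len(n) - 1L) %/% window + 1L, max(1L, n %/% window))
  ref <- col_medians(bv[is_bead, , drop = FALSE])
  wins <- sort(unique(win[is_bead]))
  centers <- scales <- numeric(length(wins))
  wmed <- matrix(NA_real_, length(wins), length(ci))
  for (i in seq_along(wins)) {
    sel <- is_bead & win == wins[i]
    m <- col_medians(x$values[sel, ci, drop = FALSE])
    wmed[i, ] <- m
    ratio <- ref / m
    ratio <- ratio[is.finite(ratio) & ratio > 0]
    scales[i] <- if (length(ratio)) exp(mean(log(ratio))) else 1
    centers[i] <- mean(which(win == wins[i]))
  }
  per_event <- if (length(wins) == 1L) rep(scales, n)
               else approx(centers, scales, xout = seq_len(n), rule = 2L)$y
  out_ci <- setdiff(seq_len(ncol(x$values)), ci)
  x$values[, out_ci] <- x$values[, out_ci, drop = FALSE] * per_event
  x <- set_labels(x, bead = is_bead)
  report <- data.frame(window = wins, center = centers, scale = scales,
                       bead_events = as.integer(table(factor(win[is_bead],
                                                             levels = wins))))
  report <- cbind(report,
                  stats::setNames(as.data.frame(wmed),
                                  paste0("median_", bead_channels)),
                  stats::setNames(as.data.frame(wmed * scales),
                                  paste0("norm_median_", bead_channels)))
  list(table = x, report = report, is_bead = is_bead)
}

#' Single-cell debarcoding
#'
#' Assigns each event to a k-of-m barcode key from its arcsinh-transformed
#' palladium channels: the k highest barcode channels form the candidate key;
#' the event is assigned iff the candidate matches one of the sample keys and
#' the separation -- the gap between the k-th and (k+1)-th highest
#' transformed barcode values -- is at least `min_separation`. Events with an
#' extra high barcode channel (summed doublets) fail the separation criterion
#' and are flagged.
#'
#' @param x An [event_table()] with the barcode channels (raw or transformed).
#' @param keys List of integer vectors (indices into `barcode_channels`), or
#'   a [barcode_scheme()].
#' @param min_separation Minimum transformed-scale separation (default 0.3).
#' @param barcode_channels Barcode channel names (default: kind `"barcode"`).
#' @param cofactor Arcsinh cofactor applied if the channels are raw.
#' @return A data frame with one row per event: `sample_id` (key index or
#'   `NA`), `separation`, `doublet_flag`.
#' @export
debarcode <- function(x, keys, min_separation = 0.3,
                      barcode_channels = NULL, cofactor = 5) {
  stopifnot(inherits(x, "event_table"))
  if (inherits(keys, "barcode_scheme")) {
    barcode_channels <- barcode_channels %||% keys$channels
    keys <- keys$keys
  }
  barcode_channels <- barcode_channels %||%
    x$channels$name[x$channels$kind == "barcode"]
  m <- length(barcode_channels)
  k <- length(keys[[1L]])
  if (k >= m) stop("debarcoding requires k < m barcode channels")
  if (any(vapply(keys, length, integer(1L)) != k))
    stop("all barcode keys must have the same k")
  ci <- match_channel(x, barcode_channels)
  bv <- x$values[, ci, drop = FALSE]
  raw <- !x$transformed[ci]
  if (any(raw)) bv[, raw] <- asinh(bv[, raw, drop = FALSE] / cofactor)
  n <- nrow(bv)
  key_str <- vapply(keys, function(kk) paste(sort(kk), collapse = ","),
                    character(1L))
  ord <- t(apply(bv, 1L, order, decreasing = TRUE))
  sorted <- t(apply(bv, 1L, sort, decreasing = TRUE))
  separation <- sorted[, k] - sorted[, k + 1L]
  cand <- vapply(seq_len(n), function(i)
    paste(sort(ord[i, seq_len(k)]), collapse = ","), character(1L))
  key_idx <- match(cand, key_str)
  ok <- !is.na(key_idx) & separation >= min_separation
  data.frame(sample_id = ifelse(ok, key_idx, NA_integer_),
             separation = separation,
             doublet_flag = separation < min_separation)
}
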