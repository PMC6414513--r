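#' Channel definition
#'
#' Describes one acquisition channel of a mass-cytometry panel: a short
#' human-readable name (e.g. `"IdU"`, `"BRU"`, `"Puromycin"`), the isotope
#' mass tag it is read on (e.g. `"I127"`, `"Gd158"`) and its functional kind.
#'
#' @param name Short channel label, unique within a panel.
#' @param mass_tag Isotope label string, unique within a panel.
#' @param kind One of `"phenotype"`, `"biosynthesis"`, `"barcode"`, `"bead"`,
#'   `"viability"`, `"dna_content"`, `"signaling"`.
#' @return A one-row `data.frame` with columns `name`, `mass_tag`, `kind`.
#' @examples
#' channel_def("IdU", "I127", "biosynthesis")
#' @export
channel_def <- function(name, mass_tag, kind) {
  kind <- match.arg(kind, channel_kinds())
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(mass_tag), length(mass_tag) == 1L)
  data.frame(name = name, mass_tag = mass_tag, kind = kind,
             stringsAsFactors = FALSE)
}

#' @rdname channel_def
#' @export
channel_kinds <- function() {
  c("phenotype", "biosynthesis", "barcode", "bead", "viability",
    "dna_content", "signaling")
}

#' Build a panel from channel definitions
#'
#' @param ... One-row data frames from [channel_def()], or complete
#'   data frames with `name`, `mass_tag`, `kind` columns.
#' @return A validated panel `data.frame`.
#' @export
panel <- function(...) {
  p <- do.call(rbind, list(...))
  validate_panel(p)
  p
}

validate_panel <- function(p) {
  stopifnot(is.data.frame(p), all(c("name", "mass_tag", "kind") %in% names(p)))
  if (anyDuplicated(p$name))
    stop("panel channel names must be unique: ",
         paste(unique(p$name[duplicated(p$name)]), collapse = ", "))
  if (anyDuplicated(p$mass_tag))
    stop("panel mass tags must be unique: ",
         paste(unique(p$mass_tag[duplicated(p$mass_tag)]), collapse = ", "))
  bad <- setdiff(unique(p$kind), channel_kinds())
  if (length(bad)) stop("unknown channel kind: ", paste(bad, collapse = ", "))
  invisible(p)
}

#' Single-cell event table
#'
#' The central container of the pipeline: a numeric matrix of nonnegative ion
#' counts (events in rows, channels in columns), channel metadata, optional
#' per-event labels (sample id, ground-truth population, phase, ...), and a
#' per-channel flag recording whether the values are raw counts or
#' arcsinh-transformed. Event order is meaningful and stable: filters in this
#' package return index masks rather than reordered copies.
#'
#' @param values Numeric matrix `n_events x n_channels`, nonnegative when raw.
#' @param channels Panel `data.frame` (see [channel_def()]); row order matches
#'   the columns of `values`.
#' @param labels Optional `data.frame` with one row per event.
#' @param transformed Logical scalar or vector (one per channel): `TRUE` where
#'   the channel holds arcsinh-transformed values.
#' @return An object of class `event_table`.
#' @export
event_table <- function(values, channels, labels = NULL, transformed = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  validate_panel(channels)
  if (ncol(values) != nrow(channels))
    stop("channel count mismatch: values has ", ncol(values),
         " columns but panel defines ", nrow(channels), " channels")
  colnames(values) <- channels$name
  if (length(transformed) == 1L) transformed <- rep(transformed, nrow(channels))
  stopifnot(length(transformed) == nrow(channels))
  transformed <- stats::setNames(as.logical(transformed), channels$name)
  if (!is.null(labels)) {
    labels <- as.data.frame(labels, stringsAsFactors = FALSE)
    if (nrow(labels) != nrow(values))
      stop("labels must have one row per event (", nrow(values), "), got ",
           nrow(labels))
  }
  if (nrow(values) && any(!transformed)) {
    raw <- values[, !transformed, drop = FALSE]
    if (any(raw < 0, na.rm = TRUE)) stop("raw ion counts must be nonnegative")
  }
  structure(list(values = values, channels = channels, labels = labels,
                 transformed = transformed),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat("event_table: ", n_events(x), " events x ", nrow(x$channels),
      " channels\n", sep = "")
  tr <- sum(x$transformed)
  cat("  scale: ", if (tr == 0) "raw counts"
      else if (tr == length(x$transformed)) "arcsinh-transformed"
      else paste0(tr, "/", length(x$transformed), " channels transformed"),
      "\n", sep = "")
  kinds <- table(x$channels$kind)
  cat("  channels:", paste(names(kinds), kinds, sep = ":", collapse = " "), "\n")
  if (!is.null(x$labels))
    cat("  labels:", paste(names(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname event_table
#' @param x An `event_table`.
#' @export
n_events <- function(x) nrow(x$values)

#' @rdname event_table
#' @export
channel_names <- function(x) x$channels$name

#' Extract channel values
#'
#' @param x An `event_table`.
#' @param channel Channel name.
#' @return Numeric vector of that channel's values.
#' @export
channel_values <- function(x, channel) {
  x$values[, match_channel(x, channel)]
}

match_channel <- function(x, channels) {
  i <- match(channels, x$channels$name)
  if (anyNA(i))
    stop("unknown channel(s): ", paste(channels[is.na(i)], collapse = ", "))
  i
}

#' Subset events of an event table
#'
#' Keeps the given events (logical mask or integer indices) in their original
#' order; channels and metadata are carried along.
#'
#' @param x An `event_table`.
#' @param events Logical mask (length `n_events`) or integer indices.
#' @return An `event_table` with the selected events.
#' @export
subset_events <- function(x, events) {
  if (is.logical(events)) {
    stopifnot(length(events) == n_events(x))
    events <- which(events)
  }
  event_table(x$values[events, , drop = FALSE], x$channels,
              labels = if (!is.null(x$labels)) x$labels[events, , drop = FALSE],
              transformed = x$transformed)
}

#' Combine event tables row-wise
#'
#' All tables must share an identical panel and transform state. Label columns
#' are unioned (missing values filled with `NA`).
#'
#' @param tables List of `event_table`s.
#' @return A single `event_table`.
#' @export
bind_events <- function(tables) {
  stopifnot(length(tables) >= 1L)
  ref <- tables[[1L]]
  for (t in tables[-1L]) {
    if (!identical(t$channels$name, ref$channels$name))
      stop("cannot bind event tables with different panels")
    if (!identical(unname(t$transformed), unname(ref$transformed)))
      stop("cannot bind event tables with different transform state")
  }
  values <- do.call(rbind, lapply(tables, `[[`, "values"))
  labs <- lapply(tables, `[[`, "labels")
  labels <- NULL
  if (any(!vapply(labs, is.null, logical(1L)))) {
    cols <- unique(unlist(lapply(labs, names)))
    labels <- do.call(rbind, lapply(seq_along(tables), function(i) {
      li <- labs[[i]]
      n <- n_events(tables[[i]])
      out <- as.data.frame(matrix(NA, n, length(cols),
                                  dimnames = list(NULL, cols)))
      if (!is.null(li)) for (cn in names(li)) out[[cn]] <- li[[cn]]
      out
    }))
  }
  event_table(values, ref$channels, labels = labels,
              transformed = ref$transformed)
}

#' Attach or extend per-event labels
#'
#' @param x An `event_table`.
#' @param ... Named vectors of length `n_events(x)`.
#' @return The table with the label columns added/replaced.
#' @export
set_labels <- function(x, ...) {
  new <- list(...)
  stopifnot(length(new) > 0L, !is.null(names(new)), all(nzchar(names(new))))
  labels <- x$labels
  if (is.null(labels)) labels <- data.frame(row.names = seq_len(n_events(x)))
  for (nm in names(new)) {
    v <- new[[nm]]
    stopifnot(length(v) == n_events(x))
    labels[[nm]] <- v
  }
  rownames(labels) <- NULL
  x$labels <- labels
  x
}
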