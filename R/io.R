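#' Read single-cell events from FCS or delimited text
#'
#' Reads an event table from a list-mode FCS 3.0/3.1 file or from delimited
#' text with a header row (tab- or comma-separated, chosen by extension).
#' Channel metadata (mass tag, kind, transform state) is restored from the
#' file when present: FCS files written by [write_events()] carry it in TEXT
#' keywords, delimited files in a `<path>.channels.tsv` sidecar. Per-event
#' labels are restored from a `<path>.labels.tsv` sidecar when one exists.
#' Event order is preserved.
#'
#' @param path File to read.
#' @param format `"auto"` (sniff/extension), `"fcs"` or `"delimited"`.
#' @return An [event_table()].
#' @export
read_events <- function(path, format = c("auto", "fcs", "delimited")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    magic <- tryCatch(readChar(path, 3L, useBytes = TRUE), error = function(e) "")
    format <- if (identical(magic, "FCS")) "fcs" else "delimited"
  }
  x <- if (format == "fcs") fcs_read(path) else delimited_read(path)
  lab_path <- paste0(path, ".labels.tsv")
  if (file.exists(lab_path)) {
    labels <- utils::read.delim(lab_path, stringsAsFactors = FALSE)
    labels$event_index <- NULL
    if (nrow(labels) != n_events(x))
      stop("labels sidecar row count (", nrow(labels),
           ") does not match event count (", n_events(x), ")")
    x$labels <- labels
  }
  x
}

#' Write single-cell events to FCS or delimited text
#'
#' FCS output is FCS 3.1, list mode, 32-bit float, little-endian, one dataset
#' per file. Labels, when present, are written to a `<path>.labels.tsv`
#' sidecar keyed by event index (never into the FCS TEXT segment). Delimited
#' output additionally writes a `<path>.channels.tsv` sidecar with the panel
#' metadata.
#'
#' @param x An [event_table()], nonempty.
#' @param path Output file.
#' @param format `"fcs"` or `"delimited"` (default from extension: `.fcs` for
#'   FCS, anything else delimited).
#' @return `path`, invisibly.
#' @export
write_events <- function(x, path, format = NULL) {
  stopifnot(inherits(x, "event_table"))
  if (n_events(x) < 1L) stop("refusing to write an empty event table")
  if (is.null(format))
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "delimited"
  format <- match.arg(format, c("fcs", "delimited"))
  if (format == "fcs") fcs_write(x, path) else delimited_write(x, path)
  if (!is.null(x$labels)) {
    lab <- cbind(event_index = seq_len(n_events(x)), x$labels)
    utils::write.table(lab, paste0(path, ".labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

delimited_read <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.delim(path, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!ncol(d)) stop("delimited event file has no columns: ", path)
  if (!all(vapply(d, is.numeric, logical(1L))))
    stop("non-numeric event values in ", path)
  meta_path <- paste0(path, ".channels.tsv")
  if (file.exists(meta_path)) {
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
    if (!identical(meta$name, names(d)))
      stop("channel metadata sidecar does not match data columns in ", path)
    chan <- meta[c("name", "mass_tag", "kind")]
    transformed <- as.logical(meta$transformed %||% FALSE)
  } else {
    chan <- data.frame(name = names(d), mass_tag = names(d),
                       kind = "phenotype", stringsAsFactors = FALSE)
    transformed <- FALSE
  }
  event_table(as.matrix(d), chan, transformed = transformed)
}

delimited_write <- function(x, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(as.data.frame(x$values), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  meta <- cbind(x$channels, transformed = unname(x$transformed))
  utils::write.table(meta, paste0(path, ".channels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load and validate a pipeline configuration
#'
#' Configurations are YAML documents with blocks `panel`, `cofactor`, `gates`,
#' `barcode`, `clustering`, `stats`, `fr`, `trajectory`, `comparisons`,
#' `annotation`, and `seed` (all optional except `panel` when gates or
#' statistics reference channels). Missing values receive the pipeline
#' defaults: arcsinh cofactor 5, IdU positivity threshold 10 counts, IdU
#' reporting minimum 4%, bootstrap R = 1000 with 95% intervals,
#' Friedman-Rafsky S = 200 and N = 100, SPADE downsample target 15%.
#'
#' @param path YAML file, or a list already parsed.
#' @return A validated config list of class `pipeline_config`.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  stopifnot(is.list(cfg))
  cfg <- utils::modifyList(default_config(), cfg)
  if (!is.null(cfg$panel)) {
    cfg$panel <- do.call(rbind, lapply(cfg$panel, function(ch)
      channel_def(ch$name, ch$mass_tag %||% ch$name, ch$kind %||% "phenotype")))
    validate_panel(cfg$panel)
  }
  known <- if (is.null(cfg$panel)) character(0L) else cfg$panel$name
  ref_check <- function(chs, where) {
    bad <- setdiff(unlist(chs), known)
    if (length(bad) && length(known))
      stop("config ", where, " references unknown channel(s): ",
           paste(bad, collapse = ", "))
  }
  ref_check(lapply(cfg$gates, `[[`, "channel"), "gates")
  ref_check(cfg$clustering$channels, "clustering")
  ref_check(cfg$fr$channels, "fr")
  ref_check(cfg$trajectory$channels, "trajectory")
  if (!is.numeric(cfg$seed) || cfg$seed < 0) stop("seed must be a nonnegative integer")
  if (cfg$cofactor <= 0) stop("cofactor must be positive")
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' @rdname load_config
#' @export
default_config <- function() {
  list(
    panel = NULL,
    cofactor = 5,
    gates = list(),
    barcode = list(min_separation = 0.3),
    clustering = list(downsample_target = 0.15, n_nodes = 150L,
                      density_k = 15L, channels = NULL),
    stats = list(bootstrap_R = 1000L, ci_level = 0.95, idu_threshold = 10,
                 idu_report_min = 0.04),
    fr = list(channels = NULL, S = 200L, N = 100L),
    trajectory = list(k = 30L, l = 15L, n_graphs = 20L, n_waypoints = 150L,
                      channels = NULL),
    comparisons = NULL,
    annotation = NULL,
    seed = 0L
  )
}
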