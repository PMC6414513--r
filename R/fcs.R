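# Minimal FCS support: list-mode FCS 3.0/3.1 reading (DATATYPE F, D or I with
# a uniform bit width; both byte orders) and FCS 3.1 writing (DATATYPE F,
# little-endian, one dataset per file). Channel names go to $PnN, mass tags to
# $PnS, and channel kind / transform state to custom TRSYNnKIND / TRSYNnXFORM
# keywords so a round trip through a file preserves the panel. Ground-truth or
# sample labels are never written into the TEXT segment; they travel in a
# delimited sidecar (see write_events).

fcs_read <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 58L) stop("not an FCS file (too short): ", path)
  header <- rawToChar(bytes[1:58])
  version <- substr(header, 1L, 6L)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version '", version, "' in ", path)
  off <- suppressWarnings(as.numeric(substring(header,
    seq(11L, 51L, by = 8L), seq(18L, 58L, by = 8L))))
  if (anyNA(off[1:2])) stop("unreadable FCS header offsets in ", path)
  text <- rawToChar(bytes[(off[1L] + 1L):(off[2L] + 1L)])
  delim <- substr(text, 1L, 1L)
  parts <- strsplit(substring(text, 2L), delim, fixed = TRUE)[[1L]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[seq(2L, length(parts), by = 2L)],
                        toupper(parts[seq(1L, length(parts), by = 2L)]))
  get_kw <- function(k, default = NULL) {
    k <- toupper(k)
    if (!k %in% names(kw)) default else unname(kw[[k]])
  }
  p <- as.integer(get_kw("$PAR"))
  n <- as.integer(get_kw("$TOT"))
  if (is.na(p) || is.na(n)) stop("FCS file missing $PAR/$TOT: ", path)
  dtype <- toupper(get_kw("$DATATYPE", "F"))
  byteord <- get_kw("$BYTEORD", "1,2,3,4")
  endian <- if (byteord %in% c("1,2,3,4", "1,2", "1")) "little" else "big"
  data_begin <- off[3L]
  data_end <- off[4L]
  if (is.na(data_begin) || data_begin == 0) {
    data_begin <- as.numeric(get_kw("$BEGINDATA", NA))
    data_end <- as.numeric(get_kw("$ENDDATA", NA))
  }
  if (is.na(data_begin)) stop("FCS file missing data offsets: ", path)
  bits <- as.integer(vapply(seq_len(p),
    function(i) get_kw(sprintf("$P%dB", i), "32"), character(1L)))
  if (dtype %in% c("F", "D")) {
    size <- if (dtype == "F") 4L else 8L
    what <- "double"
  } else if (dtype == "I") {
    if (length(unique(bits)) != 1L)
      stop("mixed $PnB widths in integer FCS data are not supported")
    size <- bits[1L] %/% 8L
    what <- "integer"
  } else stop("unsupported $DATATYPE '", dtype, "'")
  nvals <- n * p
  avail <- (data_end - data_begin + 1) %/% size
  if (!is.na(avail) && avail < nvals)
    stop("FCS data segment holds ", avail, " values but $PAR*$TOT = ", nvals,
         ": channel/event count mismatch in ", path)
  raw_data <- bytes[(data_begin + 1L):(data_begin + nvals * size)]
  v <- readBin(raw_data, what, n = nvals, size = size, endian = endian,
               signed = size > 2L)
  values <- matrix(as.double(v), ncol = p, byrow = TRUE)
  nm <- vapply(seq_len(p),
    function(i) get_kw(sprintf("$P%dN", i), sprintf("ch%d", i)), character(1L))
  tag <- vapply(seq_len(p),
    function(i) get_kw(sprintf("$P%dS", i), "") , character(1L))
  tag[!nzchar(tag)] <- nm[!nzchar(tag)]
  if (anyDuplicated(tag)) tag <- make.unique(tag, sep = "_")
  kind <- vapply(seq_len(p),
    function(i) get_kw(sprintf("TRSYN%dKIND", i), "phenotype"), character(1L))
  kind[!kind %in% channel_kinds()] <- "phenotype"
  xf <- vapply(seq_len(p),
    function(i) get_kw(sprintf("TRSYN%dXFORM", i), "0"), character(1L))
  chan <- data.frame(name = nm, mass_tag = tag, kind = kind,
                     stringsAsFactors = FALSE)
  event_table(values, chan, transformed = xf == "1")
}

fcs_write <- function(x, path) {
  stopifnot(inherits(x, "event_table"))
  n <- n_events(x)
  p <- nrow(x$channels)
  if (n < 1L) stop("refusing to write an empty event table to FCS")
  vals <- x$values
  kv <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%",
          "$NEXTDATA", "0",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$PAR", as.character(p), "$TOT", as.character(n))
  rng <- pmax(1, ceiling(apply(vals, 2L, function(v) max(v, 0))))
  for (i in seq_len(p)) {
    kv <- c(kv,
            sprintf("$P%dN", i), x$channels$name[i],
            sprintf("$P%dS", i), x$channels$mass_tag[i],
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), as.character(rng[i]),
            sprintf("TRSYN%dKIND", i), x$channels$kind[i],
            sprintf("TRSYN%dXFORM", i), if (x$transformed[i]) "1" else "0")
  }
  if (any(grepl("/", kv, fixed = TRUE)))
    stop("channel metadata must not contain the FCS delimiter '/'")
  # offsets are rendered at a fixed 10-digit width so the TEXT length is
  # known before the data offsets that live inside it are known
  text_for <- function(bd, ed) {
    kv2 <- kv
    kv2[kv2 == "%BD%"] <- sprintf("%010d", bd)
    kv2[kv2 == "%ED%"] <- sprintf("%010d", ed)
    paste0("/", paste(kv2, collapse = "/"), "/")
  }
  text_begin <- 58L
  text_nchar <- nchar(text_for(0L, 0L))
  text_end <- text_begin + text_nchar - 1L
  data_begin <- text_begin + text_nchar
  data_end <- data_begin + 4L * n * p - 1L
  text <- text_for(data_begin, data_end)
  hoff <- function(v) if (v > 99999999) sprintf("%8d", 0L) else sprintf("%8d", v)
  header <- paste0("FCS3.1    ", hoff(text_begin), hoff(text_end),
                   hoff(data_begin), hoff(data_end),
                   sprintf("%8d", 0L), sprintf("%8d", 0L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(vals)), con, size = 4L, endian = "little")
  invisible(path)
}
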