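`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-stage seed derived from the run seed and the stage name,
# so inserting or skipping a stage does not perturb the seeds of the others.
# Polynomial string hash folded into [0, 2^31 - 1]; plain doubles keep every
# intermediate below 2^53, so the arithmetic is exact.
string_hash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% (2^31 - 1)
  h
}

stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  as.integer((seed + string_hash(stage)) %% (2^31 - 1))
}

config_hash <- function(x) {
  sprintf("%08x", string_hash(paste(deparse(x), collapse = "\n")))
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(name, " must be a fraction in [0, 1]")
  invisible(x)
}

# Column medians of a numeric matrix (fast path via matrixStats).
col_medians <- function(m) {
  matrixStats::colMedians(m, useNames = FALSE)
}
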