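#' Friedman-Rafsky test parameters
#'
#' @param channels Channels compared (default the nascent-RNA and
#'   nascent-protein channels, `BRU` and `Puromycin`).
#' @param S Total cells per pooled sub-dataset (even, >= 4; default 200).
#' @param N Number of subsample iterations (default 100).
#' @param seed Seed for the subsampling draws.
#' @return An `fr_params` list.
#' @export
fr_params <- function(channels = c("BRU", "Puromycin"), S = 200L, N = 100L,
                      seed = 0L) {
  S <- as.integer(S)
  N <- as.integer(N)
  if (S < 4L || S %% 2L != 0L) stop("S must be even and at least 4")
  if (N < 1L) stop("N must be at least 1")
  structure(list(channels = channels, S = S, N = N, seed = as.integer(seed)),
            class = "fr_params")
}

#' Friedman-Rafsky statistic for one pooled sub-dataset
#'
#' Builds the Euclidean minimum spanning tree of the pooled events and counts
#' the cross edges `R` joining a cell of `a` to a cell of `b`. Under random
#' labeling of the fixed tree with `n1 = |a|`, `n2 = |b|`, `n = n1 + n2`:
#' `E[R] = 2 n1 n2 / n`, and the conditional variance given the tree's degree
#' structure is
#' `Var[R] = (2 n1 n2)/(n(n-1)) * [ (2 n1 n2 - n)/n +
#'   ((C - n + 2)/((n-2)(n-3))) * (n(n-1) - 4 n1 n2 + 2) ]`
#' with `C` the number of MST edge pairs sharing a node. Fewer cross edges
#' than expected indicate segregation of the two samples, so the one-sided
#' lower-tail normal probability of `W = (R - E[R])/sqrt(Var[R])` is the
#' p-value. Duplicate points (tied MSTs) are resolved by the deterministic
#' lowest-index rule with a warning.
#'
#' @param a,b Numeric matrices (events x channels) on a common scale
#'   (typically arcsinh-transformed), each with at least 2 rows.
#' @param warn_ties Warn on duplicate points (suppressed by [fr_test()],
#'   which handles duplicates deterministically anyway).
#' @return An `fr_iteration` list: `R_cross`, `E_R`, `Var_R`, `W`, `p`, `C`,
#'   `n1`, `n2`.
#' @export
fr_statistic <- function(a, b, warn_ties = TRUE) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  n1 <- nrow(a)
  n2 <- nrow(b)
  if (n1 < 2L || n2 < 2L) stop("both samples need at least 2 events")
  x <- rbind(a, b)
  D <- as.matrix(dist(x))
  if (warn_ties && any(D[upper.tri(D)] == 0))
    warning("duplicate points in pooled sub-dataset; MST ties broken by event index")
  edges <- prim_mst(D)
  lab <- c(rep(1L, n1), rep(2L, n2))
  e1 <- edges[, 1L]
  e2 <- edges[, 2L]
  R_cross <- sum(lab[e1] != lab[e2])
  n <- n1 + n2
  deg <- tabulate(c(e1, e2), n)
  C <- sum(deg * (deg - 1L)) / 2
  E_R <- 2 * n1 * n2 / n
  Var_R <- fr_variance(n1, n2, C)
  W <- (R_cross - E_R) / sqrt(Var_R)
  structure(list(R_cross = R_cross, E_R = E_R, Var_R = Var_R, W = W,
                 p = pnorm(W), C = C, n1 = n1, n2 = n2),
            class = "fr_iteration")
}

# Conditional variance of the cross-edge count given the tree's degree
# structure (C = number of edge pairs sharing a node).
fr_variance <- function(n1, n2, C) {
  n <- n1 + n2
  (2 * n1 * n2) / (n * (n - 1)) *
    ((2 * n1 * n2 - n) / n +
       ((C - n + 2) / ((n - 2) * (n - 3))) * (n * (n - 1) - 4 * n1 * n2 + 2))
}

#' Friedman-Rafsky population-equivalence test
#'
#' Repeats the pooled-subsample statistic `N` times: each iteration draws
#' `S/2` events without replacement from each population, pools them, and
#' computes [fr_statistic()]. The summary probability is the median of the
#' per-iteration p-values (mean and minimum are also reported); values near 1
#' indicate the populations are likely drawn from the same distribution. If a
#' population holds fewer than `S/2` events, `S` is lowered to twice the
#' smaller size with a warning. Deterministic given `params$seed`.
#'
#' @param pop_a,pop_b Numeric matrices (events x channels), or
#'   [event_table()]s (the `params$channels` are then extracted and must be
#'   transformed).
#' @param params [fr_params()].
#' @return An `fr_result`: `iterations` (data frame of per-iteration
#'   `R_cross`, `W`, `p`), `p_summary`, `p_mean`, `p_min`, `params`.
#' @export
fr_test <- function(pop_a, pop_b, params = fr_params()) {
  a <- fr_extract(pop_a, params$channels)
  b <- fr_extract(pop_b, params$channels)
  if (nrow(a) < 2L || nrow(b) < 2L) stop("populations must have at least 2 events")
  S <- params$S
  half <- S %/% 2L
  if (nrow(a) < half || nrow(b) < half) {
    S <- 2L * min(nrow(a), nrow(b))
    half <- S %/% 2L
    warning("population smaller than S/2; lowering S to ", S)
  }
  set.seed(params$seed)
  degenerate <- nrow(a) == half && nrow(b) == half
  N_draw <- if (degenerate) 1L else params$N  # n-of-n subsampling is the identity
  iters <- vector("list", N_draw)
  for (i in seq_len(N_draw)) {
    sa <- a[sample.int(nrow(a), half), , drop = FALSE]
    sb <- b[sample.int(nrow(b), half), , drop = FALSE]
    it <- fr_statistic(sa, sb, warn_ties = FALSE)
    iters[[i]] <- data.frame(R_cross = it$R_cross, E_R = it$E_R,
                             Var_R = it$Var_R, W = it$W, p = it$p)
  }
  iterations <- do.call(rbind, iters)
  if (degenerate && params$N > 1L)
    iterations <- iterations[rep(1L, params$N), , drop = FALSE]
  rownames(iterations) <- NULL
  structure(list(iterations = iterations,
                 p_summary = median(iterations$p),
                 p_mean = mean(iterations$p),
                 p_min = min(iterations$p),
                 S_used = S, params = params),
            class = "fr_result")
}

fr_extract <- function(x, channels) {
  if (inherits(x, "event_table")) {
    ci <- match_channel(x, channels)
    if (any(!x$transformed[ci]))
      stop("FR channels must be arcsinh-transformed; apply arcsinh_transform()")
    x$values[, ci, drop = FALSE]
  } else as.matrix(x)
}

#' @export
print.fr_result <- function(x, ...) {
  cat(sprintf("Friedman-Rafsky: p_summary = %.3g %s (mean %.3g, min %.3g; S = %d, N = %d)\n",
              x$p_summary, star_bins(x$p_summary), x$p_mean, x$p_min,
              x$S_used, nrow(x$iterations)))
  invisible(x)
}

#' Friedman-Rafsky comparison matrix against a reference population
#'
#' Runs [fr_test()] of the reference against each listed population (one
#' shared seed stream) and tabulates the summary probabilities with their
#' display stars. The self-comparison (reference vs itself), when included,
#' should carry the largest summary probability.
#'
#' @param populations Named list of numeric matrices (events x channels).
#' @param reference Name of the reference population.
#' @param others Names to compare against (default: all, including the
#'   reference itself).
#' @param params [fr_params()].
#' @return Data frame: `population`, `R_cross_mean`, `W_mean`, `p_summary`,
#'   `stars`; plus attribute `"results"` with the full `fr_result`s.
#' @export
fr_matrix <- function(populations, reference, others = names(populations),
                      params = fr_params()) {
  stopifnot(reference %in% names(populations))
  out <- data.frame(population = character(0L), R_cross_mean = numeric(0L),
                    W_mean = numeric(0L), p_summary = numeric(0L),
                    stars = character(0L))
  results <- list()
  for (i in seq_along(others)) {
    nm <- others[[i]]
    pi <- params
    pi$seed <- stage_seed(params$seed, paste0("fr_matrix:", nm))
    res <- fr_test(populations[[reference]], populations[[nm]], pi)
    results[[nm]] <- res
    out <- rbind(out, data.frame(
      population = nm, R_cross_mean = mean(res$iterations$R_cross),
      W_mean = mean(res$iterations$W), p_summary = res$p_summary,
      stars = star_bins(res$p_summary)))
  }
  attr(out, "results") <- results
  out
}

#' Exact null distribution of the cross-edge count on a fixed tree
#'
#' Enumerates all `choose(n, n1)` labelings of the given tree and tabulates
#' the cross-edge count `R` -- the oracle for the normal approximation used
#' by [fr_statistic()]. Only feasible for small `n`.
#'
#' @param edges Two-column matrix of tree edges (node indices 1..n).
#' @param n1,n2 Group sizes (`n1 + n2` = number of nodes, at most 14).
#' @return List: `support`, `pmf`, `cdf`, `mean`, `var`, and
#'   `p_leq(r)` -- the exact lower-tail probability function.
#' @export
fr_exact_null <- function(edges, n1, n2) {
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  n <- n1 + n2
  if (n > 14L) stop("exact enumeration limited to n <= 14")
  if (nrow(edges) != n - 1L) stop("a tree on ", n, " nodes has ", n - 1L, " edges")
  combos <- utils::combn(n, n1)
  R <- integer(ncol(combos))
  for (i in seq_len(ncol(combos))) {
    member <- logical(n)
    member[combos[, i]] <- TRUE
    R[i] <- sum(member[edges[, 1L]] != member[edges[, 2L]])
  }
  tb <- table(R)
  support <- as.integer(names(tb))
  pmf <- as.numeric(tb) / length(R)
  list(support = support, pmf = pmf, cdf = cumsum(pmf),
       mean = mean(R), var = mean((R - mean(R))^2) * length(R) / (length(R) - 1L),
       var_pop = mean((R - mean(R))^2),
       p_leq = function(r) mean(R <= r))
}
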