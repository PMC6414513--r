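#' Trajectory parameters
#'
#' Parameters of the simplified graph-based pseudotime stage: a single-branch
#' ordering of cells along a developmental axis from ensembles of k-NN
#' graphs with waypoint refinement.
#'
#' @param channels Trajectory-construction markers.
#' @param k Neighbors of the k-NN graph (default 30).
#' @param l Edges kept per node in each ensemble graph (default 15, `l <= k`).
#' @param n_graphs Ensemble size (default 20).
#' @param n_waypoints Number of waypoints (default 150, >= 2).
#' @param start_rule Either an explicit event index, or a function
#'   `f(matrix) -> index` selecting the start cell from the (transformed)
#'   channel matrix (e.g. the most CD34-high cell).
#' @param seed Seed.
#' @return A `trajectory_params` list.
#' @export
trajectory_params <- function(channels, k = 30L, l = 15L, n_graphs = 20L,
                              n_waypoints = 150L, start_rule = 1L,
                              seed = 0L) {
  if (l > k) stop("l must be at most k")
  if (n_waypoints < 2L) stop("n_waypoints must be at least 2")
  structure(list(channels = channels, k = as.integer(k), l = as.integer(l),
                 n_graphs = as.integer(n_graphs),
                 n_waypoints = as.integer(n_waypoints),
                 start_rule = start_rule, seed = as.integer(seed)),
            class = "trajectory_params")
}

#' Weighted k-NN graph
#'
#' Undirected k-nearest-neighbor graph with Euclidean edge weights.
#' Disconnected components are joined by their shortest bridging edge (with a
#' warning), so shortest-path distances are always finite.
#'
#' @param m Numeric matrix (events x channels).
#' @param k Neighbor count.
#' @return An `igraph` graph with edge attribute `weight`.
#' @export
knn_graph <- function(m, k) {
  m <- as.matrix(m)
  n <- nrow(m)
  k <- min(k, n - 1L)
  nn <- suppressWarnings(BiocNeighbors::findKNN(m, k = k))
  from <- rep(seq_len(n), k)
  to <- as.vector(nn$index)
  w <- as.vector(nn$distance)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::E(g)$weight <- w
  g <- igraph::simplify(g, edge.attr.comb = list(weight = "min"))
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    warning("k-NN graph has ", comp$no, " components; adding bridging edges")
    while (comp$no > 1L) {
      a_idx <- which(comp$membership == 1L)
      b_idx <- which(comp$membership != 1L)
      # shortest bridge between component 1 and the rest
      d2 <- outer(rowSums(m[a_idx, , drop = FALSE]^2),
                  rowSums(m[b_idx, , drop = FALSE]^2), `+`) -
        2 * m[a_idx, , drop = FALSE] %*% t(m[b_idx, , drop = FALSE])
      hit <- arrayInd(which.min(d2), dim(d2))
      g <- igraph::add_edges(g, c(a_idx[hit[1L]], b_idx[hit[2L]]),
                             weight = sqrt(max(d2[hit], 0)))
      comp <- igraph::components(g)
    }
  }
  g
}

#' Graph-based pseudotime along a single developmental branch
#'
#' For each of `n_graphs` ensemble graphs (a random `l`-of-`k` out-edge
#' subset per node), shortest-path distances from the start cell initialize
#' the ordering, which is then refined with `n_waypoints` randomly chosen
#' waypoints by iterated inverse-distance-weighted averaging of
#' waypoint-relative distances (each waypoint votes `t(w) + d(w, i)` for
#' cells beyond it and `t(w) - d(w, i)` for cells before it) until the mean
#' absolute change drops below 1e-3 or 20 iterations. The ensemble mean is
#' min-max normalized to \[0, 1\]; the start cell is at 0. Deterministic
#' given the seed.
#'
#' @param x [event_table()] or numeric matrix; channels are used on the
#'   arcsinh-transformed scale (raw channels are transformed with cofactor
#'   `cofactor`).
#' @param params [trajectory_params()].
#' @param cofactor Arcsinh cofactor for raw channels.
#' @return A `pseudotime_result`: `pseudotime` (per event, in \[0, 1\]),
#'   `start`, `waypoints` (per graph), `convergence` (iterations per graph).
#' @export
pseudotime <- function(x, params, cofactor = 5) {
  if (inherits(x, "event_table")) {
    ci <- match_channel(x, params$channels)
    m <- x$values[, ci, drop = FALSE]
    raw <- !x$transformed[ci]
    if (any(raw)) m[, raw] <- asinh(m[, raw, drop = FALSE] / cofactor)
  } else m <- as.matrix(x)
  n <- nrow(m)
  start <- if (is.function(params$start_rule)) params$start_rule(m)
           else as.integer(params$start_rule)
  if (is.na(start) || length(start) != 1L || start < 1L || start > n)
    stop("start_rule matched no event")
  set.seed(params$seed)
  k <- min(params$k, n - 1L)
  l <- min(params$l, k)
  nn <- suppressWarnings(BiocNeighbors::findKNN(m, k = k))
  n_wp <- min(params$n_waypoints, n - 1L)
  traj <- matrix(0, params$n_graphs, n)
  waypoints <- matrix(0L, params$n_graphs, n_wp)
  convergence <- integer(params$n_graphs)
  for (gidx in seq_len(params$n_graphs)) {
    keep <- t(vapply(seq_len(n), function(i) sort(sample.int(k, l)),
                     integer(l)))
    from <- rep(seq_len(n), l)
    to <- as.vector(nn$index[cbind(rep(seq_len(n), l), as.vector(keep))])
    w <- as.vector(nn$distance[cbind(rep(seq_len(n), l), as.vector(keep))])
    g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
    igraph::E(g)$weight <- w
    g <- igraph::simplify(g, edge.attr.comb = list(weight = "min"))
    if (igraph::components(g)$no > 1L)
      g <- connect_components(g, m)
    wp <- c(start, sample(setdiff(seq_len(n), start), n_wp - 1L))
    waypoints[gidx, ] <- wp
    D <- igraph::distances(g, v = wp, algorithm = "dijkstra")
    t_cur <- D[1L, ]
    Winv <- 1 / (D + 1e-9)
    Winv <- Winv / matrix(colSums(Winv), nrow(Winv), ncol(Winv), byrow = TRUE)
    for (it in 1:20) {
      t_wp <- t_cur[wp]
      sign_mat <- ifelse(matrix(t_cur, n_wp, n, byrow = TRUE) >= t_wp, 1, -1)
      votes <- t_wp + sign_mat * D
      t_new <- colSums(Winv * votes)
      t_new <- t_new - t_new[start]
      delta <- mean(abs(t_new - t_cur))
      t_cur <- t_new
      convergence[gidx] <- it
      if (delta < 1e-3) break
    }
    traj[gidx, ] <- t_cur
  }
  pt <- colMeans(traj)
  pt <- pt - pt[start]
  rng <- range(pt)
  pt <- if (rng[2L] > rng[1L]) (pt - rng[1L]) / (rng[2L] - rng[1L]) else pt * 0
  structure(list(pseudotime = pt, start = start, waypoints = waypoints,
                 convergence = convergence, params = params),
            class = "pseudotime_result")
}

connect_components <- function(g, m) {
  comp <- igraph::components(g)
  while (comp$no > 1L) {
    a_idx <- which(comp$membership == 1L)
    b_idx <- which(comp$membership != 1L)
    d2 <- outer(rowSums(m[a_idx, , drop = FALSE]^2),
                rowSums(m[b_idx, , drop = FALSE]^2), `+`) -
      2 * m[a_idx, , drop = FALSE] %*% t(m[b_idx, , drop = FALSE])
    hit <- arrayInd(which.min(d2), dim(d2))
    g <- igraph::add_edges(g, c(a_idx[hit[1L]], b_idx[hit[2L]]),
                           weight = sqrt(max(d2[hit], 0)))
    comp <- igraph::components(g)
  }
  g
}

#' Channel trends along pseudotime
#'
#' Sliding-window medians of each channel at evenly spaced pseudotime
#' positions; the window holds a fixed fraction of cells (default 5%), so the
#' trend depends only on the ordering of the cells, not on the pseudotime
#' values themselves.
#'
#' @param x [event_table()] or matrix supplying the channel values.
#' @param result [pseudotime()] result (or numeric pseudotime vector).
#' @param channels Channels to extract trends for.
#' @param window Fraction of cells per window (default 0.05).
#' @param n_points Number of trend positions (default 100).
#' @return Data frame: `pseudotime`, then one column per channel.
#' @export
channel_trends <- function(x, result, channels, window = 0.05,
                           n_points = 100L) {
  pt <- if (inherits(result, "pseudotime_result")) result$pseudotime
        else as.numeric(result)
  vals <- if (inherits(x, "event_table"))
    x$values[, match_channel(x, channels), drop = FALSE]
  else as.matrix(x)[, channels, drop = FALSE]
  n <- length(pt)
  stopifnot(nrow(vals) == n)
  half <- max(1L, ceiling(window * n / 2))
  ord <- order(pt)
  sorted_vals <- vals[ord, , drop = FALSE]
  positions <- seq(0, 1, length.out = n_points)
  # window centers move through the *ranks*, so the trend commutes with any
  # strictly monotone relabeling of pseudotime
  centers <- pmin(pmax(round(positions * (n - 1)) + 1, 1L), n)
  out <- matrix(0, n_points, length(channels),
                dimnames = list(NULL, channels))
  size <- min(n, 2L * half + 1L)
  for (i in seq_len(n_points)) {
    # clamp the window's position, not its size, so edge estimates use as
    # many events as interior ones (and window = 1 is the global median)
    lo <- min(max(1L, centers[i] - half), n - size + 1L)
    out[i, ] <- col_medians(sorted_vals[lo:(lo + size - 1L), , drop = FALSE])
  }
  data.frame(pseudotime = positions, out, check.names = FALSE)
}

#' Half-rise position of a monotone trend
#'
#' The first trend position where the channel crosses the midpoint between
#' its minimum and maximum -- used e.g. to locate the IgM onset along the
#' B-cell axis.
#'
#' @param trend Data frame from [channel_trends()].
#' @param channel Channel name.
#' @return Pseudotime of the half-rise.
#' @export
trend_half_rise <- function(trend, channel) {
  v <- trend[[channel]]
  mid <- (min(v) + max(v)) / 2
  trend$pseudotime[which(v >= mid)[1L]]
}
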