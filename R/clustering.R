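# Prim's algorithm on a full distance matrix, O(n^2). Returns an (n-1) x 3
# matrix [from, to, length]. Ties are broken by lowest event index (which.min
# takes the first minimum), which keeps repeated runs and duplicate points
# deterministic. Hand-rolled rather than graph-library-based because the
# Friedman-Rafsky stage builds tens of thousands of small MSTs.
prim_mst <- function(D) {
  n <- nrow(D)
  if (n < 2L) return(matrix(numeric(0L), 0L, 3L,
                            dimnames = list(NULL, c("from", "to", "length"))))
  in_tree <- logical(n)
  in_tree[1L] <- TRUE
  best <- D[1L, ]
  parent <- rep(1L, n)
  edges <- matrix(0, n - 1L, 3L,
                  dimnames = list(NULL, c("from", "to", "length")))
  for (i in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    edges[i, ] <- c(parent[j], j, best[j])
    in_tree[j] <- TRUE
    upd <- which(!in_tree & D[j, ] < best)
    best[upd] <- D[j, upd]
    parent[upd] <- j
  }
  edges
}

#' SPADE-style clustering parameters
#'
#' @param clustering_channels Phenotype channels used for distances;
#'   biosynthesis and signaling channels are deliberately excluded from
#'   clustering and used only for per-node statistics.
#' @param downsample_target Density-dependent downsampling target fraction
#'   (default 0.15).
#' @param n_nodes Target cluster (node) count, e.g. 150 or 175.
#' @param density_k Neighbor count for the k-NN density estimate (default 15).
#' @param seed Seed for the downsampling draw.
#' @return A `spade_params` list.
#' @export
spade_params <- function(clustering_channels, downsample_target = 0.15,
                         n_nodes = 150L, density_k = 15L, seed = 0L) {
  if (downsample_target <= 0 || downsample_target > 1)
    stop("downsample_target must be in (0, 1]")
  if (n_nodes < 2L) stop("n_nodes must be at least 2")
  if (density_k < 1L) stop("density_k must be at least 1")
  structure(list(clustering_channels = clustering_channels,
                 downsample_target = downsample_target,
                 n_nodes = as.integer(n_nodes),
                 density_k = as.integer(density_k), seed = as.integer(seed)),
            class = "spade_params")
}

#' Local density per event
#'
#' k-NN density proxy: `1 / max(r_k, floor)^d` where `r_k` is the distance to
#' the k-th nearest neighbor in the (transformed) clustering-channel space
#' and `d` its dimension. Only the ordering and relative magnitude matter
#' downstream (density-dependent downsampling).
#'
#' @param x Numeric matrix (events x channels) or [event_table()].
#' @param channels Channels to use when `x` is an event table.
#' @param k Neighbor count.
#' @param dist_floor Lower bound on `r_k` keeping densities finite for
#'   duplicated points.
#' @return Numeric density per event.
#' @export
local_density <- function(x, channels = NULL, k = 15L, dist_floor = 1e-6) {
  m <- if (inherits(x, "event_table"))
    x$values[, match_channel(x, channels %||% channel_names(x)), drop = FALSE]
  else as.matrix(x)
  n <- nrow(m)
  if (n == 1L) return(1 / dist_floor^ncol(m))
  k <- min(k, n - 1L)
  # tied-distance warnings are expected on discrete count data and harmless
  r <- suppressWarnings(
    BiocNeighbors::findKNN(m, k = k, get.index = FALSE))$distance[, k]
  (1 / pmax(r, dist_floor))^ncol(m)
}

#' Density-dependent downsampling
#'
#' Keeps event `i` with probability `min(1, TD / u_i)`, where `u_i` is the
#' event's density rank scaled into (0, 1] and the target density `TD` is
#' chosen by bisection so that the expected kept fraction equals `target`.
#' Only the ordering of the supplied densities is used: the k-NN proxy
#' scales as `r^-d` and spans dozens of orders of magnitude in
#' high-dimensional panels, which under a literal `TD / density` rule would
#' reduce abundant populations to a handful of events. Rare (low-density)
#' events are retained at rates at least as high as their dense
#' counterparts, which is the point of the procedure; homogeneous densities
#' reduce to uniform subsampling at `target`.
#'
#' @param density Density per event (see [local_density()]); only its
#'   ordering matters (ties share their average rank).
#' @param target Target kept fraction in (0, 1].
#' @param seed Seed for the Bernoulli draw.
#' @return Integer indices of the kept events (increasing order).
#' @export
density_downsample <- function(density, target, seed = 0L) {
  if (target > 1) stop("downsample target must be at most 1")
  if (target <= 0) stop("downsample target must be positive")
  n <- length(density)
  if (target == 1) return(seq_len(n))
  # Only the ordering of the density is meaningful (the r^-d proxy spans
  # dozens of orders of magnitude in high-dimensional panels), so the keep
  # probability works on the scaled density rank.
  u <- rank(density, ties.method = "average") / n
  f <- function(td) mean(pmin(1, td / u)) - target
  lo <- 0
  hi <- 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  p <- pmin(1, hi / u)
  set.seed(seed)
  which(runif(n) < p)
}

#' Agglomerate events into a target number of clusters
#'
#' Hierarchical agglomeration with average linkage on Euclidean distance in
#' the transformed clustering channels, cut at `n_nodes` clusters.
#' Deterministic given the input order.
#'
#' @param m Numeric matrix (downsampled events x clustering channels).
#' @param n_nodes Target cluster count (capped at the number of events).
#' @return Integer cluster assignment per row of `m`.
#' @export
agglomerate <- function(m, n_nodes) {
  m <- as.matrix(m)
  n_nodes <- min(n_nodes, nrow(m))
  if (nrow(m) == n_nodes) return(seq_len(nrow(m)))
  cutree(hclust(dist(m), method = "average"), k = n_nodes)
}

#' Minimum spanning tree over cluster medians
#'
#' @param node_medians Numeric matrix (nodes x channels).
#' @return Data frame of MST edges: `from`, `to`, `length` (Euclidean);
#'   `n_nodes - 1` rows, connected by construction.
#' @export
build_mst <- function(node_medians) {
  D <- as.matrix(dist(node_medians))
  as.data.frame(prim_mst(D))
}

#' Assign all events to their nearest cluster node
#'
#' Every event -- including those dropped by downsampling -- is assigned to
#' the node with the nearest median in the transformed clustering-channel
#' space; exact ties go to the lowest node index. Events listed in `fixed`
#' keep their given assignment (the SPADE pipeline pins the downsampled
#' events to their agglomerative cluster).
#'
#' @param m Numeric matrix (events x clustering channels).
#' @param node_medians Numeric matrix (nodes x same channels).
#' @param fixed Optional named assignment: `fixed$idx` event indices,
#'   `fixed$node` their node ids.
#' @param block Events per distance block (memory control).
#' @return Integer node assignment per event.
#' @export
upsample <- function(m, node_medians, fixed = NULL, block = 20000L) {
  m <- as.matrix(m)
  nm <- as.matrix(node_medians)
  n <- nrow(m)
  out <- integer(n)
  nm2 <- rowSums(nm^2)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(n, start + block - 1L)
    E <- m[idx, , drop = FALSE]
    d2 <- outer(rowSums(E^2), nm2, `+`) - 2 * E %*% t(nm)
    out[idx] <- max.col(-d2, ties.method = "first")
  }
  if (!is.null(fixed)) out[fixed$idx] <- fixed$node
  out
}

#' Full SPADE-style clustering
#'
#' Density-dependent downsampling, average-linkage agglomeration to
#' `n_nodes`, MST over node medians, and upsampling of all events. Distances
#' are computed on arcsinh-transformed values; raw clustering channels are
#' transformed on the fly.
#'
#' @param x An [event_table()].
#' @param params A [spade_params()].
#' @param cofactor Arcsinh cofactor for channels still raw.
#' @return A `cluster_graph`: `node_medians` (nodes x clustering channels),
#'   `mst_edges`, `assignment` (node per event), `downsampled` (kept event
#'   indices), `annotations` (filled by [annotate_nodes()]), `params`.
#' @export
spade_cluster <- function(x, params, cofactor = 5) {
  stopifnot(inherits(x, "event_table"), inherits(params, "spade_params"))
  full <- x$values
  raw <- !x$transformed
  if (any(raw)) full[, raw] <- asinh(full[, raw, drop = FALSE] / cofactor)
  ci <- match_channel(x, params$clustering_channels)
  m <- full[, ci, drop = FALSE]
  density <- local_density(m, k = params$density_k)
  kept <- density_downsample(density, params$downsample_target,
                             seed = params$seed)
  cl <- agglomerate(m[kept, , drop = FALSE], params$n_nodes)
  k <- max(cl)
  # node medians over ALL channels (transformed scale) so biosynthesis
  # overlays and annotation predicates can reference any channel; distances
  # (upsampling, MST) use the clustering channels only
  medians <- matrix(0, k, ncol(full), dimnames = list(NULL, colnames(full)))
  for (j in seq_len(k))
    medians[j, ] <- col_medians(full[kept[cl == j], , drop = FALSE])
  assignment <- upsample(m, medians[, params$clustering_channels, drop = FALSE],
                         fixed = list(idx = kept, node = cl))
  structure(list(node_medians = medians,
                 mst_edges = build_mst(medians[, params$clustering_channels,
                                               drop = FALSE]),
                 assignment = assignment, downsampled = kept,
                 annotations = NULL, params = params),
            class = "cluster_graph")
}

#' @export
print.cluster_graph <- function(x, ...) {
  cat("cluster_graph: ", nrow(x$node_medians), " nodes, ",
      length(x$assignment), " events (", length(x$downsampled),
      " downsampled)\n", sep = "")
  if (!is.null(x$annotations)) {
    tb <- table(x$annotations)
    cat("  annotations:", paste(names(tb), tb, sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

#' Annotation rule
#'
#' A population definition as marker high/low predicates on transformed node
#' medians, e.g. `ann_rule("HSC", "CD34 > 2.5", "CD38 < 2")`. Rules are
#' applied first-match in order by [annotate_nodes()].
#'
#' @param name Population name.
#' @param ... Predicate strings `"channel op threshold"` with op one of
#'   `>`, `>=`, `<`, `<=`.
#' @return An `ann_rule` list.
#' @export
ann_rule <- function(name, ...) {
  preds <- lapply(list(...), parse_predicate)
  structure(list(name = name, when = preds), class = "ann_rule")
}

parse_predicate <- function(s) {
  if (is.list(s)) return(s)  # already parsed
  m <- regmatches(s, regexec("^\\s*(\\S+)\\s*(>=|<=|>|<)\\s*([-0-9.eE]+)\\s*$", s))[[1L]]
  if (length(m) != 4L) stop("cannot parse predicate: '", s, "'")
  list(channel = m[2L], op = m[3L], threshold = as.numeric(m[4L]))
}

#' Annotate cluster nodes into populations
#'
#' Each node receives the name of the first rule whose predicates all hold on
#' its (transformed) medians; nodes matching no rule are `"unassigned"`.
#'
#' @param graph A `cluster_graph` from [spade_cluster()].
#' @param rules List of [ann_rule()]s, in priority order.
#' @return The graph with `annotations` (one name per node) filled in.
#' @export
annotate_nodes <- function(graph, rules) {
  stopifnot(inherits(graph, "cluster_graph"))
  med <- graph$node_medians
  ann <- rep("unassigned", nrow(med))
  for (j in seq_len(nrow(med))) {
    for (r in rules) {
      hit <- all(vapply(r$when, function(p) {
        v <- med[j, p$channel]
        switch(p$op, ">" = v > p$threshold, ">=" = v >= p$threshold,
               "<" = v < p$threshold, "<=" = v <= p$threshold)
      }, logical(1L)))
      if (hit) {
        ann[j] <- r$name
        break
      }
    }
  }
  graph$annotations <- ann
  graph
}

#' Per-event population from an annotated graph
#'
#' @param graph An annotated `cluster_graph`.
#' @return Character vector: each event's node annotation.
#' @export
event_populations <- function(graph) {
  if (is.null(graph$annotations)) stop("graph is not annotated")
  graph$annotations[graph$assignment]
}
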