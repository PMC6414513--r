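test_that("prim_mst matches igraph on random point sets", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rnorm(30 * 3), 30)
    D <- as.matrix(dist(m))
    edges <- trisyn:::prim_mst(D)
    expect_equal(nrow(edges), 29L)
    g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                             weighted = TRUE)
    ref <- sum(igraph::E(igraph::mst(g))$weight)
    expect_equal(sum(edges[, "length"]), ref, tolerance = 1e-12)
    # result is a spanning tree: connected, n-1 edges
    gt <- igraph::graph_from_edgelist(edges[, 1:2], directed = FALSE)
    expect_true(igraph::is_connected(gt))
  }
})

test_that("prim_mst matches the exhaustive spanning-tree oracle (n <= 8)", {
  for (n in c(4, 6, 8)) {
    set.seed(n)
    D <- as.matrix(dist(matrix(runif(n * 2), n)))
    edges <- trisyn:::prim_mst(D)
    expect_equal(sum(edges[, "length"]), brute_force_mst_length(D),
                 tolerance = 1e-12)
  }
})

test_that("prim_mst breaks ties by lowest index", {
  # three identical points: edges must attach to the lowest available index
  D <- matrix(0, 3, 3)
  edges <- trisyn:::prim_mst(D)
  expect_equal(unname(edges[, "from"]), c(1, 1))
  expect_equal(unname(edges[, "to"]), c(2, 3))
})

test_that("local_density ranks dense regions above sparse ones", {
  set.seed(5)
  m <- rbind(matrix(rnorm(400, 0, 0.5), 200),   # dense blob
             matrix(rnorm(40, 10, 5), 20))      # sparse blob
  dens <- local_density(m, k = 10)
  expect_gt(median(dens[1:200]), median(dens[201:220]))
  expect_true(all(is.finite(dens)))
  # duplicated points stay finite via the distance floor
  dup <- local_density(matrix(1, 20, 2), k = 5)
  expect_true(all(is.finite(dup)))
})

test_that("density_downsample hits the target fraction and favors rare events", {
  set.seed(6)
  m <- rbind(matrix(rnorm(2000 * 2, 0, 0.5), 2000),
             matrix(rnorm(100 * 2, 20, 0.5), 100))
  dens <- local_density(m, k = 15)
  kept <- density_downsample(dens, 0.15, seed = 1)
  expect_equal(length(kept) / 2100, 0.15, tolerance = 0.05)
  # the rare population is kept at a higher rate than the abundant one
  rate_rare <- mean(kept > 2000)
  expect_gt(sum(kept > 2000) / 100, length(kept) / 2100)
  expect_equal(density_downsample(dens, 1), seq_len(2100))
  expect_error(density_downsample(dens, 0), "positive")
  expect_error(density_downsample(dens, 1.2), "at most 1")
})

test_that("agglomerate separates well-separated blobs perfectly", {
  m <- two_blobs(100, gap = 20)
  cl <- agglomerate(m, 2)
  truth <- rep(1:2, each = 100)
  expect_equal(length(unique(cl)), 2L)
  # purity 100%: each cluster maps to one truth blob
  expect_true(all(table(cl, truth) %in% c(0L, 100L)))
  # n_nodes = n -> singletons
  expect_equal(agglomerate(m[1:10, ], 10), 1:10)
})

test_that("build_mst returns a connected tree with n-1 edges", {
  set.seed(7)
  med <- matrix(rnorm(20 * 4), 20)
  mst <- build_mst(med)
  expect_equal(nrow(mst), 19L)
  g <- igraph::graph_from_edgelist(as.matrix(mst[, 1:2]), directed = FALSE)
  expect_true(igraph::is_connected(g))
})

test_that("upsample assigns nearest node with lowest-index ties", {
  nodes <- rbind(c(0, 0), c(2, 0), c(4, 0))
  # event at x=1 is equidistant to nodes 1 and 2 -> node 1
  ev <- rbind(c(1, 0), c(3.9, 0), c(0.1, 0))
  expect_equal(upsample(ev, nodes), c(1L, 3L, 1L))
  # exact node median -> that node
  expect_equal(upsample(nodes, nodes), 1:3)
  # pinning overrides
  expect_equal(upsample(ev, nodes, fixed = list(idx = 2L, node = 1L)),
               c(1L, 1L, 1L))
})

test_that("spade_cluster keeps downsampled assignments through upsampling", {
  set.seed(8)
  m <- two_blobs(400, gap = 8)
  p <- panel(channel_def("A", "M1", "phenotype"),
             channel_def("B", "M2", "phenotype"))
  x <- event_table(asinh(abs(m)), p, transformed = TRUE)
  params <- spade_params(c("A", "B"), downsample_target = 0.3, n_nodes = 10,
                         density_k = 10, seed = 1)
  g1 <- spade_cluster(x, params)
  expect_equal(nrow(g1$node_medians), 10L)
  expect_equal(nrow(g1$mst_edges), 9L)
  expect_length(g1$assignment, 800L)
  # the downsampled events keep their agglomerative cluster
  cl <- agglomerate(x$values[g1$downsampled, c("A", "B")], 10)
  expect_equal(g1$assignment[g1$downsampled], unname(cl))
  # determinism
  g2 <- spade_cluster(x, params)
  expect_identical(g1$assignment, g2$assignment)
  expect_identical(g1$node_medians, g2$node_medians)
})

test_that("node medians cover all channels, distances only clustering ones", {
  set.seed(9)
  p <- tiny_panel()  # A, B phenotype; C biosynthesis
  v <- cbind(rnorm(300), rnorm(300), rnorm(300, 5))
  x <- event_table(v, p, transformed = TRUE)
  params <- spade_params(c("A", "B"), downsample_target = 0.5, n_nodes = 5,
                         seed = 2)
  g <- spade_cluster(x, params)
  expect_equal(colnames(g$node_medians), c("A", "B", "C"))
  # biosynthesis medians hover around the simulated mean
  expect_equal(mean(g$node_medians[, "C"]), 5, tolerance = 0.5)
})

test_that("annotate_nodes applies rules first-match in order", {
  g <- list(node_medians = rbind(c(A = 5, B = 0), c(A = 5, B = 5),
                                 c(A = 0, B = 0)),
            annotations = NULL)
  class(g) <- "cluster_graph"
  rules <- list(ann_rule("both", "A > 1", "B > 1"),
                ann_rule("a_only", "A > 1"))
  ann <- annotate_nodes(g, rules)$annotations
  expect_equal(ann, c("a_only", "both", "unassigned"))
  # contradictory order: first match wins
  rules2 <- list(ann_rule("first", "A > 1"), ann_rule("second", "A > 1"))
  expect_equal(annotate_nodes(g, rules2)$annotations[1], "first")
  # empty rules -> all unassigned
  expect_equal(annotate_nodes(g, list())$annotations, rep("unassigned", 3))
  expect_error(ann_rule("x", "A >> 1"), "cannot parse")
})

test_that("event_populations maps node annotations to events", {
  g <- structure(list(annotations = c("x", "y"),
                      assignment = c(1L, 2L, 2L, 1L)),
                 class = "cluster_graph")
  expect_equal(event_populations(g), c("x", "y", "y", "x"))
  g$annotations <- NULL
  expect_error(event_populations(g), "not annotated")
})
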