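# Density thresholding and graph statistics, validated against closed forms
# and exhaustive brute-force oracles on small graphs.

test_that("density thresholding keeps exactly the strongest positive edges", {
  # n = 4: six uniquely ranked weights, density 0.5 keeps the top 3
  W <- matrix(0, 4, 4)
  W[upper.tri(W)] <- c(0.9, 0.1, 0.6, 0.8, 0.2, 0.4)
  W <- W + t(W); diag(W) <- 1
  g <- threshold_by_density(W, 0.5)
  expect_equal(g$m, 3)
  expect_equal(g$density, 0.5)
  pairs_kept <- which(g$adj == 1 & upper.tri(g$adj), arr.ind = TRUE)
  got <- apply(pairs_kept, 1, paste, collapse = "-")
  expect_setequal(got, c("1-2", "2-3", "1-4"))  # weights 0.9, 0.8, 0.6
  # full density gives the complete graph
  expect_equal(threshold_by_density(W, 1)$adj, complete_adjacency(4),
               ignore_attr = TRUE)
  expect_error(threshold_by_density(W, 0), class = "mcnet_validation_error")
})

test_that("ties at the cut break deterministically with exact edge count", {
  W <- matrix(0, 4, 4)
  W[upper.tri(W)] <- c(0.9, 0.5, 0.5, 0.5, 0.5, 0.1)
  W <- W + t(W); diag(W) <- 1
  g1 <- threshold_by_density(W, 0.5)
  g2 <- threshold_by_density(W, 0.5)
  expect_equal(g1$m, 3)
  expect_identical(g1$adj, g2$adj)
  # lexicographically earliest tied pairs are kept
  expect_equal(g1$adj[1, 2], 1L)
  kept <- which(g1$adj == 1 & upper.tri(g1$adj), arr.ind = TRUE)
  expect_equal(nrow(kept), 3)
})

test_that("negative weights are discarded and all-negative input warns", {
  W <- matrix(-0.5, 3, 3); diag(W) <- 1
  expect_warning(g <- threshold_by_density(W, 0.5), "empty")
  expect_equal(g$m, 0)
})

test_that("edge sets are nested and density non-decreasing across the grid", {
  set.seed(31)
  n <- 12
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- stats::runif(n * (n - 1) / 2, 0.01, 1)
  W <- W + t(W); diag(W) <- 1
  grid <- seq(0.05, 0.5, by = 0.05)
  prev <- NULL
  for (d in grid) {
    g <- threshold_by_density(W, d)
    if (!is.null(prev)) {
      expect_true(all(g$adj[prev$adj == 1L] == 1L))  # nesting
      expect_gte(g$density, prev$density)
    }
    expect_lte(abs(g$density - d), 1 / (g$n * (g$n - 1)))
    prev <- g
  }
})

test_that("complete, star, ring and path graphs match their closed forms", {
  # K4 and K6
  for (n in c(4, 6)) {
    g <- as_binary_graph(complete_adjacency(n))
    nm <- nodal_metrics(g)
    expect_equal(nm$clustering, rep(1, n))
    expect_equal(nm$degree, rep(n - 1, n))
    expect_equal(nm$betweenness, rep(0, n))
    gm <- global_metrics(g)
    expect_equal(gm$Lp, 1)
    expect_equal(gm$Eglob, 1)
    expect_equal(gm$sync, 1)  # Laplacian spectrum {0, n}
  }
  # star with 5 leaves: centre betweenness = 5 * 4 / 2
  st <- as_binary_graph(star_adjacency(5))
  nms <- nodal_metrics(st)
  expect_equal(nms$betweenness[1], 10)
  expect_equal(nms$betweenness[-1], rep(0, 5))
  expect_equal(nms$clustering, rep(0, 6))
  # ring lattice n = 20, k = 4: Cp = 3(k-2) / (4(k-1)) = 0.5
  rl <- as_binary_graph(ring_lattice_adjacency(20, 4))
  expect_equal(global_metrics(rl)$Cp, 0.5)
  # path P5 against the BFS oracle
  p5 <- path_adjacency(5)
  gm5 <- global_metrics(as_binary_graph(p5))
  expect_equal(gm5$Lp, oracle_lp(p5))
  expect_equal(gm5$Eglob, oracle_eglob(p5))
})

test_that("all metrics match exhaustive brute force on 200 random graphs", {
  set.seed(32)
  for (rep in seq_len(200)) {
    n <- sample(3:7, 1)
    A <- random_adjacency(n, stats::runif(1, 0.2, 0.9))
    g <- as_binary_graph(A)
    nm <- nodal_metrics(g)
    expect_equal(nm$degree, rowSums(A), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(nm$clustering, oracle_clustering(A), tolerance = 1e-10)
    expect_equal(nm$betweenness, oracle_betweenness(A), tolerance = 1e-10)
    expect_equal(nm$local_efficiency, oracle_local_efficiency(A),
                 tolerance = 1e-10)
    gm <- global_metrics(g, nodal = nm)
    expect_equal(gm$Cp, mean(oracle_clustering(A)), tolerance = 1e-10)
    expect_equal(gm$Lp, oracle_lp(A), tolerance = 1e-10)
    expect_equal(gm$Eglob, oracle_eglob(A), tolerance = 1e-10)
  }
})

test_that("relabeling nodes permutes nodal metrics and fixes global ones", {
  set.seed(33)
  A <- random_adjacency(7, 0.4)
  perm <- sample(7)
  B <- A[perm, perm]
  nma <- nodal_metrics(as_binary_graph(A))
  nmb <- nodal_metrics(as_binary_graph(B))
  for (col in c("degree", "clustering", "local_efficiency", "betweenness"))
    expect_equal(nmb[[col]], nma[[col]][perm], tolerance = 1e-10)
  gma <- global_metrics(as_binary_graph(A))
  gmb <- global_metrics(as_binary_graph(B))
  for (col in c("Cp", "Lp", "Eglob", "sync"))
    expect_equal(gmb[[col]], gma[[col]], tolerance = 1e-10)
})

test_that("adding edges never decreases global efficiency or degrees", {
  set.seed(34)
  A <- random_adjacency(10, 0.2)
  g0 <- as_binary_graph(A)
  free <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
  add <- free[sample(nrow(free), 5), , drop = FALSE]
  B <- A
  B[add] <- 1L
  B[add[, c(2, 1), drop = FALSE]] <- 1L
  g1 <- as_binary_graph(B)
  expect_gte(global_metrics(g1)$Eglob, global_metrics(g0)$Eglob)
  expect_true(all(nodal_metrics(g1)$degree >= nodal_metrics(g0)$degree))
})

test_that("hierarchy is the negative log-log slope of C(k), NA when degenerate", {
  # two joined cliques of different size produce spread in both k and C
  A <- matrix(0L, 8, 8)
  A[1:5, 1:5] <- 1L
  A[6:8, 6:8] <- 1L
  diag(A) <- 0L
  A[5, 6] <- A[6, 5] <- 1L
  g <- as_binary_graph(A)
  nm <- nodal_metrics(g)
  elig <- nm$degree >= 2 & nm$clustering > 0
  fit <- stats::lm(log(nm$clustering[elig]) ~ log(nm$degree[elig]))
  expect_equal(global_metrics(g)$hierarchy, -unname(coef(fit)[2]),
               tolerance = 1e-10)
  # ring lattice: all degrees equal, slope undefined
  expect_true(is.na(global_metrics(
    as_binary_graph(ring_lattice_adjacency(12, 4)))$hierarchy))
})

test_that("metric curves integrate over the density grid by trapezoid", {
  grid <- seq(0.05, 0.5, by = 0.05)
  expect_equal(length(grid), 10)
  # constant metric: AUC = 0.45 * m
  expect_equal(auc_trapezoid(grid, rep(2, 10)), 0.45 * 2)
  # linear metric v(d) = d: AUC = (0.5^2 - 0.05^2) / 2
  expect_equal(auc_trapezoid(grid, grid), 0.12375)
  expect_error(auc_trapezoid(0.3, 1), class = "mcnet_validation_error")
  tab <- make_region_table(6, 2, 2)
  x <- simulate_uptake(tab, 15, coupling_spec(), seed = 35)
  cv <- suppressWarnings(metric_curve(covnet(x), "Cp", grid = grid))
  expect_equal(cv$auc, auc_trapezoid(grid, cv$values))
  expect_error(metric_curve(covnet(x), "Cp", grid = 0.3),
               class = "mcnet_validation_error")
})
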