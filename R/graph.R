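# Density thresholding and graph statistics. Graphs are undirected and
# binary: the sparsity sweep removes the weakest positive weights until the
# prescribed connection density remains, and all topology is computed on the
# resulting adjacency matrices.

#' Threshold a covariance network at a connection density
#'
#' Keeps the `k = round(density * n * (n - 1) / 2)` largest positive
#' off-diagonal weights (negative weights are discarded first) and binarizes
#' them. Ties spanning the cut are broken deterministically by ascending node
#' index pair. If fewer than `k` strictly positive weights exist, only those
#' are kept and a warning is raised; an all-non-positive matrix yields an
#' empty graph with a warning.
#'
#' @param network A [covnet()] object or symmetric weight matrix.
#' @param density Target connection density in (0, 1].
#' @return An object of class `binary_graph`: list with `adj` (0/1 symmetric
#'   integer matrix), `n`, `m` (edge count), `density` (attained), and
#'   `requested_density`.
#' @export
threshold_by_density <- function(network, density) {
  if (!is.numeric(density) || length(density) != 1L || density <= 0 ||
      density > 1)
    mc_stop("`density` must lie in (0, 1]", "mcnet_validation_error")
  W <- if (inherits(network, "covnet")) network$weights else as.matrix(network)
  n <- nrow(W)
  if (n < 2L || n != ncol(W))
    mc_stop("weight matrix must be square with n >= 2",
            "mcnet_validation_error")
  pr <- pair_indices(n)
  w <- W[pr]
  w[w < 0] <- 0
  M <- nrow(pr)
  k <- round(density * M)
  npos <- sum(w > 0)
  if (npos == 0L)
    warning("no positive weights: thresholding yields an empty graph",
            call. = FALSE)
  if (k > npos && npos > 0L)
    warning(sprintf(
      "only %d positive weights available for %d requested edges; density attained %.3f",
      npos, k, npos / M), call. = FALSE)
  k_eff <- min(k, npos)
  A <- matrix(0L, n, n, dimnames = dimnames(W))
  if (k_eff > 0L) {
    # pair_indices emits pairs in (i, j) lexicographic order and the stable
    # radix sort preserves it among tied weights, giving the deterministic
    # node-index tie-break
    ord <- order(-w, method = "radix")[seq_len(k_eff)]
    A[pr[ord, , drop = FALSE]] <- 1L
    A[pr[ord, c(2L, 1L), drop = FALSE]] <- 1L
  }
  structure(list(adj = A, n = n, m = k_eff, density = k_eff / M,
                 requested_density = density),
            class = "binary_graph")
}

#' Construct a binary graph from an adjacency matrix
#'
#' @param adj Symmetric 0/1 matrix with zero diagonal.
#' @return A `binary_graph`.
#' @export
as_binary_graph <- function(adj) {
  adj <- as.matrix(adj)
  n <- nrow(adj)
  if (n != ncol(adj) || !isTRUE(all.equal(adj, t(adj))))
    mc_stop("adjacency must be a symmetric square matrix",
            "mcnet_validation_error")
  if (any(diag(adj) != 0))
    mc_stop("self-loops are not allowed", "mcnet_validation_error")
  A <- matrix(as.integer(adj != 0), n, n, dimnames = dimnames(adj))
  m <- sum(A) / 2
  structure(list(adj = A, n = n, m = m, density = m / (n * (n - 1) / 2),
                 requested_density = NA_real_),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("binary graph: %d nodes, %d edges (density %.3f)\n",
              x$n, x$m, x$density))
  invisible(x)
}

as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$adj, mode = "undirected",
                                      diag = FALSE)
}

# All-pairs shortest-path lengths of a dense adjacency matrix by repeated
# boolean multiplication (breadth-first over path lengths). Cheaper than
# building an igraph object for the many small neighbour subgraphs.
adj_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- A > 0
  D[reach] <- 1
  known <- reach | diag(TRUE, n)
  d <- 1
  while (d < n) {
    reach <- (reach %*% A) > 0
    newly <- reach & !known
    if (!any(newly)) break
    d <- d + 1
    D[newly] <- d
    known <- known | newly
  }
  D
}

# Global efficiency of an adjacency matrix: mean of 1/d over all ordered
# pairs, with disconnected pairs contributing 0.
eff_global_adj <- function(A) {
  n <- nrow(A)
  if (n < 2L) return(0)
  D <- adj_distances(A)
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  sum(inv) / (n * (n - 1))
}

# Degree and clustering coefficient straight from the adjacency matrix.
degree_clustering <- function(A) {
  k <- rowSums(A)
  A2 <- A %*% A
  tri <- rowSums(A2 * A) / 2
  C <- tri / pmax(k * (k - 1) / 2, 1) * (k >= 2)
  list(degree = as.numeric(k), clustering = as.numeric(C))
}

#' Nodal graph metrics
#'
#' Per-node degree, clustering coefficient (triangle density among
#' neighbours; 0 for degree < 2), local efficiency (global efficiency of the
#' subgraph induced by the node's neighbours; 0 for degree < 2), and
#' betweenness centrality (fractional shortest-path counts, summed over
#' unordered pairs).
#'
#' @param graph A `binary_graph`.
#' @return Data frame with columns `node`, `degree`, `clustering`,
#'   `local_efficiency`, `betweenness`.
#' @export
nodal_metrics <- function(graph) {
  stopifnot(inherits(graph, "binary_graph"))
  A <- graph$adj
  n <- graph$n
  if (n < 3L) mc_stop("need at least 3 nodes", "mcnet_validation_error")
  dc <- degree_clustering(A)
  bc <- igraph::betweenness(as_igraph(graph), directed = FALSE, weights = NA)
  eloc <- local_efficiency_adj(A)
  data.frame(node = colnames(A) %||% as.character(seq_len(n)),
             degree = dc$degree, clustering = dc$clustering,
             local_efficiency = eloc, betweenness = as.numeric(bc),
             stringsAsFactors = FALSE)
}

local_efficiency_adj <- function(A) {
  storage.mode(A) <- "integer"
  as.numeric(.local_efficiency_core(A))
}

#' Global graph metrics
#'
#' Computes the raw global topology of a binary graph: mean clustering
#' coefficient `Cp`; characteristic path length `Lp` (mean shortest path over
#' connected pairs only, so sparse graphs keep a finite value); global
#' efficiency `Eglob` (mean inverse distance over all pairs, 0 for
#' disconnected pairs); hierarchy `beta` (minus the least-squares slope of
#' `log C_i` on `log k_i` over nodes with `k_i >= 2` and `C_i > 0`; `NA` when
#' fewer than two eligible nodes or no degree spread); and synchronizability
#' `sync`, the Laplacian eigenratio `lambda_2 / lambda_max` (0 for a
#' disconnected graph). The null-normalized `gamma`, `lambda` and `sigma`
#' come from [normalized_small_world()].
#'
#' @param graph A `binary_graph`.
#' @param nodal Optional precomputed [nodal_metrics()] table, to avoid
#'   recomputation.
#' @return Named list with `Cp`, `Lp`, `Eglob`, `hierarchy`, `sync`.
#' @export
global_metrics <- function(graph, nodal = NULL) {
  stopifnot(inherits(graph, "binary_graph"))
  if (graph$n < 3L) mc_stop("need at least 3 nodes", "mcnet_validation_error")
  dc <- if (is.null(nodal)) NULL
        else list(degree = nodal$degree, clustering = nodal$clustering)
  as.list(global_metrics_subset(graph, .global_metric_names, dc = dc))
}

# Compute only the requested global statistics, sharing the expensive
# intermediates (degree/clustering, the distance matrix, the Laplacian
# spectrum) across them. Saves most of the work in permutation loops that
# track a single metric.
global_metrics_subset <- function(graph, which, dc = NULL) {
  n <- graph$n
  out <- stats::setNames(rep(NA_real_, length(which)), which)
  need_dc <- any(c("Cp", "hierarchy") %in% which)
  if (need_dc && is.null(dc)) dc <- degree_clustering(graph$adj)
  if ("Cp" %in% which) out["Cp"] <- mean(dc$clustering)
  if (any(c("Lp", "Eglob") %in% which)) {
    D <- adj_distances(graph$adj)
    if ("Lp" %in% which) {
      v <- D[upper.tri(D)]
      v <- v[is.finite(v)]
      out["Lp"] <- if (length(v) > 0L) mean(v) else NA_real_
    }
    if ("Eglob" %in% which) {
      inv <- 1 / D
      diag(inv) <- 0
      inv[is.infinite(D)] <- 0
      out["Eglob"] <- sum(inv) / (n * (n - 1))
    }
  }
  if ("hierarchy" %in% which) {
    elig <- dc$degree >= 2 & dc$clustering > 0
    if (sum(elig) >= 2L) {
      lk <- log(dc$degree[elig])
      lc <- log(dc$clustering[elig])
      if (stats::var(lk) > 0)
        out["hierarchy"] <- -unname(stats::coef(stats::lm(lc ~ lk))[2L])
    }
  }
  if ("sync" %in% which) {
    L <- diag(rowSums(graph$adj)) - graph$adj
    ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
    lmax <- ev[1L]
    l2 <- max(0, ev[length(ev) - 1L])
    out["sync"] <- if (lmax > 1e-12) l2 / lmax else 0
  }
  out
}

.global_metric_names <- c("Cp", "Lp", "Eglob", "hierarchy", "sync")
.null_metric_names <- c("gamma", "lambda", "sigma")
.nodal_metric_names <- c("degree", "clustering", "local_efficiency",
                         "betweenness")

# Evaluate one named metric on one thresholded graph. `node` selects a nodal
# metric's node (name or index); NULL averages over nodes.
eval_metric <- function(graph, metric, node = NULL, n_null = 100,
                        swap_factor = 10, seed = NULL) {
  if (metric %in% .global_metric_names) {
    return(global_metrics(graph)[[metric]])
  }
  if (metric %in% .null_metric_names) {
    nsw <- normalized_small_world(graph, n_null = n_null,
                                  swap_factor = swap_factor, seed = seed)
    return(nsw[[metric]])
  }
  if (metric %in% .nodal_metric_names) {
    # compute only the requested statistic: the per-node subgraph efficiencies
    # and betweenness are much costlier than degree or clustering
    v <- switch(metric,
                degree = degree_clustering(graph$adj)$degree,
                clustering = degree_clustering(graph$adj)$clustering,
                betweenness = as.numeric(igraph::betweenness(
                  as_igraph(graph), directed = FALSE, weights = NA)),
                local_efficiency = local_efficiency_adj(graph$adj))
    if (is.null(node)) return(mean(v))
    idx <- if (is.character(node))
      match(node, colnames(graph$adj) %||% as.character(seq_len(graph$n)))
    else as.integer(node)
    if (is.na(idx) || idx < 1L || idx > graph$n)
      mc_stop(paste("unknown node:", node), "mcnet_validation_error")
    return(v[idx])
  }
  mc_stop(paste("unknown metric:", metric), "mcnet_validation_error")
}

#' Metric values over the density grid with an AUC summary
#'
#' Evaluates a named graph statistic at each density of the sparsity grid
#' (default 5% to 50% in 5% steps, the standard sweep) and summarises the
#' curve by its trapezoidal area under the curve.
#'
#' Available metrics: global `"Cp"`, `"Lp"`, `"Eglob"`, `"hierarchy"`,
#' `"sync"`; null-normalized `"gamma"`, `"lambda"`, `"sigma"` (these draw
#' `n_null` degree-preserving surrogates per density); nodal `"degree"`,
#' `"clustering"`, `"local_efficiency"`, `"betweenness"` (averaged over nodes,
#' or taken at `node`).
#'
#' @param network A [covnet()] object or weight matrix.
#' @param metric Metric name (see Details).
#' @param grid Strictly increasing densities in (0, 1]; at least two points.
#' @param node Node name for nodal metrics (`NULL` = mean over nodes).
#' @param n_null,swap_factor Null-ensemble settings for `gamma`/`lambda`/
#'   `sigma`.
#' @param seed RNG seed for the null ensembles.
#' @return Object of class `metric_curve`: list with `metric`, `grid`,
#'   `values`, `auc`, `node`.
#' @export
metric_curve <- function(network, metric, grid = seq(0.05, 0.5, by = 0.05),
                         node = NULL, n_null = 100, swap_factor = 10,
                         seed = NULL) {
  if (length(grid) < 2L)
    mc_stop("AUC is undefined on a single-point grid",
            "mcnet_validation_error")
  if (any(diff(grid) <= 0) || any(grid <= 0) || any(grid > 1))
    mc_stop("`grid` must be strictly increasing within (0, 1]",
            "mcnet_validation_error")
  values <- vapply(seq_along(grid), function(i) {
    g <- threshold_by_density(network, grid[i])
    eval_metric(g, metric, node = node, n_null = n_null,
                swap_factor = swap_factor, seed = seed_stream(seed, i))
  }, 0)
  structure(list(metric = metric, grid = grid, values = values,
                 auc = auc_trapezoid(grid, values), node = node),
            class = "metric_curve")
}

#' @export
print.metric_curve <- function(x, ...) {
  lab <- if (is.null(x$node)) x$metric else paste0(x$metric, "[", x$node, "]")
  cat(sprintf("metric curve %s over %d densities [%.2f, %.2f]: AUC = %.4f\n",
              lab, length(x$grid), min(x$grid), max(x$grid), x$auc))
  invisible(x)
}

#' @export
plot.metric_curve <- function(x, ...) {
  lab <- if (is.null(x$node)) x$metric else paste0(x$metric, " [", x$node, "]")
  graphics::plot(x$grid, x$values, type = "b", pch = 16,
                 xlab = "connection density", ylab = lab,
                 main = sprintf("AUC = %.4f", x$auc), ...)
  invisible(x)
}
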