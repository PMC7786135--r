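# Independent brute-force oracles for graph statistics, kept deliberately
# naive: exhaustive path enumeration and explicit triangle counting on tiny
# graphs. They share no code with the package's metric implementations.

# All-pairs shortest-path distances by Floyd-Warshall.
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Enumerate all simple paths between s and t, keep the shortest, and return
# list(count = number of shortest paths, through = per-node counts of
# shortest paths passing through each intermediate node).
oracle_shortest_paths <- function(A, s, t) {
  n <- nrow(A)
  best_len <- Inf
  paths <- list()
  walk <- function(v, visited, len) {
    if (len > best_len) return()
    if (v == t) {
      if (len < best_len) { best_len <<- len; paths <<- list() }
      if (len == best_len) paths[[length(paths) + 1L]] <<- visited
      return()
    }
    for (w in which(A[v, ] > 0))
      if (!(w %in% visited)) walk(w, c(visited, w), len + 1L)
  }
  walk(s, s, 0L)
  through <- numeric(n)
  for (p in paths) {
    mid <- setdiff(p, c(s, t))
    through[mid] <- through[mid] + 1
  }
  list(count = length(paths), through = through)
}

# Betweenness centrality by exhaustive shortest-path enumeration, summed over
# unordered pairs with fractional counting.
oracle_betweenness <- function(A) {
  n <- nrow(A)
  bc <- numeric(n)
  for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
    sp <- oracle_shortest_paths(A, s, t)
    if (sp$count > 0) bc <- bc + sp$through / sp$count
  }
  bc
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(A[nb, nb]) / 2
    links / (k * (k - 1) / 2)
  }, 0)
}

oracle_eglob <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- oracle_distances(A)
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_eglob(A[nb, nb, drop = FALSE])
  }, 0)
}

oracle_lp <- function(A) {
  D <- oracle_distances(A)
  v <- D[upper.tri(D)]
  v <- v[is.finite(v)]
  if (length(v) == 0) NA_real_ else mean(v)
}

# Random undirected graph on n nodes with edge probability p.
random_adjacency <- function(n, p) {
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  on <- up[stats::runif(length(up)) < p]
  A[on] <- 1L
  A + t(A)
}

# Deterministic lattice/star/complete constructors used across tests.
complete_adjacency <- function(n) {
  A <- matrix(1L, n, n); diag(A) <- 0L; A
}

ring_lattice_adjacency <- function(n, k) {
  stopifnot(k %% 2 == 0)
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) for (d in seq_len(k / 2)) {
    j1 <- ((i - 1 + d) %% n) + 1
    j2 <- ((i - 1 - d) %% n) + 1
    A[i, j1] <- A[j1, i] <- 1L
    A[i, j2] <- A[j2, i] <- 1L
  }
  A
}

star_adjacency <- function(leaves) {
  A <- matrix(0L, leaves + 1, leaves + 1)
  A[1, -1] <- 1L
  A[-1, 1] <- 1L
  A
}

path_adjacency <- function(n) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1L
  A
}

# Classical regress-out-everything partial correlation oracle: correlation of
# residuals after OLS regression of each pair on all remaining columns.
oracle_partial_correlations <- function(x) {
  p <- ncol(x)
  out <- diag(1, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    z <- x[, -c(i, j), drop = FALSE]
    ri <- stats::lm.fit(cbind(1, z), x[, i])$residuals
    rj <- stats::lm.fit(cbind(1, z), x[, j])$residuals
    out[i, j] <- out[j, i] <- stats::cor(ri, rj)
  }
  out
}

# Small region table used by many fixtures.
tiny_table <- function(n_neo = 3, n_sub = 1, n_bs = 1) {
  make_region_table(n_neo, n_sub, n_bs, seed_name = "Insula")
}
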