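# Two-group inference: regional uptake t-tests with step-down multiplicity
# control, and subject-relabeling permutation tests for differences between
# the two groups' network-metric AUCs (group networks are single objects, so
# a within-group sampling distribution does not exist; relabeling subjects
# and refitting both networks is the exchangeable null).

#' Regional uptake comparison between two groups
#'
#' Welch two-sample t-test per region (optionally restricted to a subset,
#' e.g. the regions with significant seed covariance), with Holm step-down
#' adjustment across the tested regions.
#'
#' @param group_a,group_b Uptake matrices with identical region columns.
#' @param regions Optional character vector restricting the tested regions.
#' @param alpha Significance level for the `significant` flag.
#' @return Data frame with per-region group means, mean difference (A - B),
#'   Welch t, raw and Holm-adjusted p, and significance flag.
#' @export
regional_ttests <- function(group_a, group_b, regions = NULL, alpha = 0.05) {
  a <- as.matrix(group_a); b <- as.matrix(group_b)
  if (!identical(colnames(a), colnames(b)))
    mc_stop("groups must share an identical region order",
            "mcnet_alignment_error")
  if (nrow(a) < 2 || nrow(b) < 2)
    mc_stop("both groups need at least 2 subjects", "mcnet_validation_error")
  regions <- regions %||% colnames(a)
  bad <- setdiff(regions, colnames(a))
  if (length(bad) > 0L)
    mc_stop(paste("unknown regions:", paste(bad, collapse = ", ")),
            "mcnet_validation_error")
  res <- lapply(regions, function(rg) {
    xa <- a[, rg]; xb <- b[, rg]
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      if (mean(xa) == mean(xb))
        return(data.frame(region = rg, mean_a = mean(xa), mean_b = mean(xb),
                          diff = 0, t = 0, p = 1, stringsAsFactors = FALSE))
      mc_stop(paste("zero within-group variance in both groups for region",
                    rg), "mcnet_degenerate_error")
    }
    tt <- stats::t.test(xa, xb, var.equal = FALSE)
    data.frame(region = rg, mean_a = mean(xa), mean_b = mean(xb),
               diff = mean(xa) - mean(xb),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out$significant <- out$p_holm <= alpha
  out
}

# AUC of one or more metrics for one group's fitted network; shared by the
# observed statistic and every permutation replicate. Metrics that share an
# expensive intermediate (the global-metric set; degree/clustering) are
# computed together per thresholded graph.
net_metric_aucs <- function(x, metrics, grid, shrinkage = "auto", node = NULL,
                            n_null = 100, swap_factor = 10, seed = NULL) {
  fit <- covnet(x, shrinkage = shrinkage)
  globals <- intersect(metrics, .global_metric_names)
  others <- setdiff(metrics, globals)
  vals <- matrix(NA_real_, length(grid), length(metrics),
                 dimnames = list(NULL, metrics))
  for (i in seq_along(grid)) {
    g <- suppressWarnings(threshold_by_density(fit, grid[i]))
    if (length(globals) > 0L)
      vals[i, globals] <- global_metrics_subset(g, globals)
    for (mt in others)
      vals[i, mt] <- eval_metric(g, mt, node = node, n_null = n_null,
                                 swap_factor = swap_factor,
                                 seed = seed_stream(seed, i))
  }
  apply(vals, 2L, function(v) auc_trapezoid(grid, v))
}

#' Permutation inference on network-metric AUC differences
#'
#' Tests whether a graph-metric AUC differs between the two groups' metabolic
#' covariance networks. The observed statistic is
#' `AUC_A - AUC_B`; the null distribution relabels subjects into groups of
#' the original sizes, refits both networks, and recomputes the difference.
#' The two-sided p-value is `(1 + #{|null| >= |obs|}) / (n_perm + 1)`. When
#' `n_perm` is at least the number of distinct relabelings, all of them are
#' enumerated instead and the p-value is exact.
#'
#' @param group_a,group_b Uptake matrices with identical region columns.
#' @param metrics Character vector of metric names (see [metric_curve()]);
#'   all metrics share the same permutations.
#' @param grid Density grid.
#' @param n_perm Number of random relabelings (>= 99).
#' @param seed RNG seed.
#' @param shrinkage Shrinkage mode passed to [covnet()].
#' @param node Node name for nodal metrics.
#' @param n_null,swap_factor Null-ensemble settings when a metric requires
#'   degree-preserving surrogates.
#' @return Data frame of class `perm_result` with one row per metric:
#'   `metric`, `observed` (A - B AUC difference), `p`, `n_perm`, `exact`.
#' @export
permute_network_metric <- function(group_a, group_b, metrics = "Cp",
                                   grid = seq(0.05, 0.5, by = 0.05),
                                   n_perm = 1000, seed = NULL,
                                   shrinkage = "auto", node = NULL,
                                   n_null = 100, swap_factor = 10) {
  a <- as.matrix(group_a); b <- as.matrix(group_b)
  if (!identical(colnames(a), colnames(b)))
    mc_stop("groups must share an identical region order",
            "mcnet_alignment_error")
  na <- nrow(a); nb <- nrow(b)
  if (na + nb < 6)
    mc_stop("need at least 6 subjects combined", "mcnet_validation_error")
  if (!is_count(n_perm) || n_perm < 99)
    mc_stop("`n_perm` must be an integer >= 99", "mcnet_validation_error")
  pooled <- rbind(a, b)
  aucs <- function(split_a, s) {
    xa <- pooled[split_a, , drop = FALSE]
    xb <- pooled[-split_a, , drop = FALSE]
    net_metric_aucs(xa, metrics, grid, shrinkage, node, n_null, swap_factor,
                    seed = seed_stream(s, 1L)) -
      net_metric_aucs(xb, metrics, grid, shrinkage, node, n_null, swap_factor,
                      seed = seed_stream(s, 2L))
  }
  obs <- aucs(seq_len(na), seed)
  n_all <- choose(na + nb, na)
  exact <- is.finite(n_all) && n_perm >= n_all
  if (exact) {
    message(sprintf(
      "n_perm >= %d distinct relabelings: enumerating exhaustively", n_all))
    splits <- utils::combn(na + nb, na, simplify = FALSE)
    null_diffs <- matrix(NA_real_, length(splits), length(metrics))
    for (i in seq_along(splits))
      null_diffs[i, ] <- aucs(splits[[i]], seed_stream(seed, i + 2L))
    p <- vapply(seq_along(metrics), function(j)
      mean(abs(null_diffs[, j]) >= abs(obs[j]) - 1e-12), 0)
    n_used <- length(splits)
  } else {
    null_diffs <- matrix(NA_real_, n_perm, length(metrics))
    perms <- with_seed(seed, replicate(n_perm, sample.int(na + nb, na),
                                       simplify = FALSE))
    for (i in seq_len(n_perm))
      null_diffs[i, ] <- aucs(perms[[i]], seed_stream(seed, i + 2L))
    p <- vapply(seq_along(metrics), function(j)
      (1 + sum(abs(null_diffs[, j]) >= abs(obs[j]) - 1e-12)) / (n_perm + 1), 0)
    n_used <- n_perm
  }
  out <- data.frame(metric = metrics, observed = unname(obs), p = p,
                    n_perm = n_used, exact = exact, stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  attr(out, "grid") <- grid
  attr(out, "null") <- null_diffs
  class(out) <- c("perm_result", "data.frame")
  out
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("permutation test on metric AUCs (%s, %d relabelings)\n",
              if (x$exact[1L]) "exact" else "sampled", x$n_perm[1L]))
  NextMethod()
}

#' Contrast two seed covariance maps
#'
#' Pairs the per-region seed results of two groups and flags the edges that
#' are Bonferroni-surviving positive connections in group A but not in group
#' B (the disease-specific covariance pattern).
#'
#' @param result_a,result_b [seed_correlations()] results with identical
#'   region order.
#' @return Data frame with `region`, `r_a`, `sig_a`, `r_b`, `sig_b`,
#'   `a_not_b`.
#' @export
seed_edge_contrast <- function(result_a, result_b) {
  if (!identical(result_a$region, result_b$region))
    mc_stop("seed results are not aligned: region sets or order differ",
            "mcnet_alignment_error")
  data.frame(region = result_a$region,
             r_a = result_a$r, sig_a = result_a$significant,
             r_b = result_b$r, sig_b = result_b$significant,
             a_not_b = result_a$significant & !result_b$significant,
             stringsAsFactors = FALSE)
}

#' Descriptive paired t-test across a density grid
#'
#' Paired t-test of two metric curves' per-density values. Densities are not
#' independent observations, so this is a descriptive summary of curve
#' separation, not a calibrated test; permutation inference on the AUC
#' ([permute_network_metric()]) is the primary comparison.
#'
#' @param curve_a,curve_b [metric_curve()] objects on the same grid.
#' @return `htest` object from [stats::t.test()].
#' @export
curve_ttest <- function(curve_a, curve_b) {
  if (!isTRUE(all.equal(curve_a$grid, curve_b$grid)))
    mc_stop("curves are on different density grids", "mcnet_alignment_error")
  stats::t.test(curve_a$values, curve_b$values, paired = TRUE)
}
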