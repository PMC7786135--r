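# The covariance-network estimator: the group-level partial-correlation
# matrix over regions, computed across subjects, with analytic shrinkage of
# the correlation matrix toward the identity so that the precision matrix is
# well-defined even when regions outnumber subjects.

# Analytic (Schafer-Strimmer-type) shrinkage intensity for the sample
# correlation matrix toward the identity target:
#   lambda* = sum_{i<j} Var-hat(r_ij) / sum_{i<j} r_ij^2, clipped to [0, 1].
# Computed in closed form without materialising the n x p(p-1)/2 matrix of
# pairwise products: with standardized data xs and C = t(xs) %*% xs,
#   sum_{i<j} sum_k (xs_ki xs_kj)^2 = (1/2) sum_k [(sum_i xs_ki^2)^2
#                                                  - sum_i xs_ki^4]
#   sum_{i<j} C_ij^2               = (1/2) (||C||_F^2 - sum_i C_ii^2).
shrinkage_intensity <- function(x) {
  n <- nrow(x)
  xs <- scale(x)
  xs2 <- xs^2
  S2 <- sum(rowSums(xs2)^2 - rowSums(xs2^2)) / 2
  C <- crossprod(xs)
  T2 <- (sum(C^2) - sum(diag(C)^2)) / 2
  denom <- T2 / (n - 1)^2            # sum of squared correlations
  if (denom <= 0) return(1)
  num <- n / (n - 1)^3 * (S2 - T2 / n)  # sum of estimated Var(r_ij)
  min(1, max(0, num / denom))
}

#' Fit a metabolic covariance network
#'
#' Estimates the group-level partial-correlation network over regions: for
#' each pair of regions, the correlation of uptake across subjects while
#' controlling for all remaining regions. The sample correlation matrix is
#' shrunk toward the identity with an analytically chosen intensity (or a
#' user-forced one), variances are restored, the result is inverted, and
#' partial correlations are read off the precision matrix Omega as
#' `rho_ij = -Omega_ij / sqrt(Omega_ii * Omega_jj)`.
#'
#' Shrinkage makes the construction well-defined in the regime typical of
#' covariance mapping (more regions than subjects), where the plain sample
#' covariance is singular. With `shrinkage = 0` and more subjects than
#' regions the estimate coincides with the classical regress-out-everything
#' partial correlation.
#'
#' @param uptake Subjects x regions uptake matrix (named columns).
#' @param shrinkage `"auto"` for the analytic intensity, or a number in
#'   `[0, 1]` to force one.
#' @return An object of class `covnet` with elements `weights` (symmetric
#'   partial-correlation matrix, unit diagonal), `regions`, `shrinkage`
#'   (intensity used), and `n_subjects`.
#' @examples
#' tab <- make_region_table(3, 1, 1)
#' x <- simulate_uptake(tab, 40, coupling_spec(), seed = 1)
#' fit <- covnet(x)
#' fit
#' @export
covnet <- function(uptake, shrinkage = "auto") {
  x <- as.matrix(uptake)
  if (!is.numeric(x) || is.null(colnames(x)))
    mc_stop("`uptake` must be a numeric matrix with region column names",
            "mcnet_validation_error")
  n <- nrow(x); p <- ncol(x)
  if (n < 3) mc_stop("need at least 3 subjects", "mcnet_validation_error")
  mu <- colMeans(x)
  sds <- sqrt(pmax(colSums(x^2) - n * mu^2, 0) / (n - 1))
  if (any(sds == 0))
    mc_stop(paste("constant uptake column(s):",
                  paste(colnames(x)[sds == 0], collapse = ", ")),
            "mcnet_degenerate_error")
  lam <- if (identical(shrinkage, "auto")) shrinkage_intensity(x) else {
    if (!is.numeric(shrinkage) || shrinkage < 0 || shrinkage > 1)
      mc_stop("`shrinkage` must be \"auto\" or a number in [0, 1]",
              "mcnet_validation_error")
    as.numeric(shrinkage)
  }
  R <- stats::cor(x)
  Rs <- (1 - lam) * R
  diag(Rs) <- 1
  Sigma <- Rs * outer(sds, sds)
  omega <- tryCatch(chol2inv(chol(Sigma)), error = function(e)
    mc_stop(paste0("shrunk covariance is not invertible (n = ", n, ", p = ", p,
                   ", shrinkage = ", signif(lam, 4),
                   "); increase the shrinkage intensity"),
            "mcnet_degenerate_error"))
  w <- partial_from_precision(omega)
  w <- (w + t(w)) / 2
  w[w > 1] <- 1; w[w < -1] <- -1
  diag(w) <- 1
  dimnames(w) <- list(colnames(x), colnames(x))
  structure(list(weights = w, regions = colnames(x), shrinkage = lam,
                 n_subjects = n, call = match.call()),
            class = "covnet")
}

#' @export
print.covnet <- function(x, ...) {
  cat("Metabolic covariance network (partial correlations)\n")
  cat(sprintf("  regions: %d   subjects: %d   shrinkage intensity: %.4f\n",
              length(x$regions), x$n_subjects, x$shrinkage))
  off <- x$weights[upper.tri(x$weights)]
  cat(sprintf("  off-diagonal weights: min %.3f, median %.3f, max %.3f\n",
              min(off), stats::median(off), max(off)))
  invisible(x)
}

#' @export
summary.covnet <- function(object, densities = seq(0.05, 0.5, by = 0.05), ...) {
  off <- object$weights[upper.tri(object$weights)]
  out <- list(n_regions = length(object$regions),
              n_subjects = object$n_subjects,
              shrinkage = object$shrinkage,
              weight_summary = summary(off),
              prop_positive = mean(off > 0),
              densities = densities)
  class(out) <- "summary.covnet"
  out
}

#' @export
print.summary.covnet <- function(x, ...) {
  cat(sprintf("covnet: %d regions, %d subjects, shrinkage %.4f\n",
              x$n_regions, x$n_subjects, x$shrinkage))
  cat(sprintf("  positive off-diagonal weights: %.1f%%\n",
              100 * x$prop_positive))
  print(x$weight_summary)
  invisible(x)
}

#' @export
plot.covnet <- function(x, ...) {
  p <- length(x$regions)
  graphics::image(seq_len(p), seq_len(p), t(x$weights[p:1, , drop = FALSE]),
                  zlim = c(-1, 1), axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  main = "Partial correlation weights", ...)
  graphics::box()
  invisible(x)
}

#' @export
as.matrix.covnet <- function(x, ...) x$weights

#' Write / read a covariance network
#'
#' The matrix goes to a square CSV with region names as header row and first
#' column; estimator metadata (shrinkage intensity, subject count) goes to a
#' JSON sidecar next to it.
#'
#' @param fit A [covnet()] object.
#' @param path CSV path; the sidecar is `path` with extension `.json`.
#' @export
write_covnet <- function(fit, path) {
  stopifnot(inherits(fit, "covnet"))
  utils::write.csv(data.frame(region = fit$regions, fit$weights,
                              check.names = FALSE), path, row.names = FALSE,
                   quote = FALSE)
  meta <- list(shrinkage = fit$shrinkage, n_subjects = fit$n_subjects,
               n_regions = length(fit$regions))
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_covnet
#' @export
read_covnet <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  w <- as.matrix(df[, -1L, drop = FALSE])
  rownames(w) <- df[[1L]]
  meta_path <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(list(weights = w, regions = rownames(w),
                 shrinkage = meta$shrinkage %||% NA_real_,
                 n_subjects = meta$n_subjects %||% NA_integer_,
                 call = NULL),
            class = "covnet")
}

#' Seed-region Pearson covariance map
#'
#' Correlates uptake in the seed region (the insula) with uptake in each of
#' the other `m = p - 1` regions across subjects, with two-sided p-values from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, a
#' Bonferroni threshold `alpha / m`, and the positive-sign filter (negative
#' correlations are never declared connections).
#'
#' @param uptake Subjects x regions uptake matrix.
#' @param seed_region Seed column name.
#' @param alpha Family-wise significance level (default 0.05).
#' @return A data frame of class `seed_edges` with columns `region`, `r`,
#'   `p`, `p_bonferroni_threshold`, `significant` (Bonferroni-surviving AND positive)
#'   and `positive`.
#' @export
seed_correlations <- function(uptake, seed_region, alpha = 0.05) {
  x <- as.matrix(uptake)
  n <- nrow(x)
  if (n < 4) mc_stop("need at least 4 subjects", "mcnet_validation_error")
  if (!seed_region %in% colnames(x))
    mc_stop(paste("seed region not found:", seed_region),
            "mcnet_validation_error")
  if (stats::sd(x[, seed_region]) == 0)
    mc_stop("seed region has zero variance", "mcnet_degenerate_error")
  others <- setdiff(colnames(x), seed_region)
  m <- length(others)
  r <- as.vector(stats::cor(x[, seed_region], x[, others, drop = FALSE]))
  df <- n - 2
  denom <- 1 - r^2
  p <- ifelse(denom <= 0, 0,
              2 * stats::pt(-abs(r * sqrt(df / pmax(denom, 0))), df))
  thr <- alpha / m
  out <- data.frame(region = others, r = r, p = p, p_bonferroni_threshold = thr,
                    significant = (p <= thr) & (r > 0), positive = r > 0,
                    stringsAsFactors = FALSE)
  attr(out, "n") <- n
  attr(out, "seed_region") <- seed_region
  attr(out, "alpha") <- alpha
  attr(out, "m") <- m
  class(out) <- c("seed_edges", "data.frame")
  out
}

#' @export
print.seed_edges <- function(x, ...) {
  cat(sprintf("Seed covariance map: %s vs %d regions (n = %d)\n",
              attr(x, "seed_region"), attr(x, "m"), attr(x, "n")))
  cat(sprintf("  Bonferroni-surviving positive edges: %d (threshold p <= %.2e)\n",
              sum(x$significant), x$p_bonferroni_threshold[1L]))
  NextMethod()
}

#' Bonferroni-surviving positive seed edges
#'
#' Filters a seed covariance map to the edges with `p <= alpha / m` and
#' `r > 0`, ordered by descending correlation strength (ties broken by region
#' table order).
#'
#' @param result A [seed_correlations()] result.
#' @param alpha Family-wise level; defaults to the level stored in `result`.
#' @param m Number of tests in the family; defaults to the number of rows.
#' @return Data frame of surviving edges (`region`, `r`, `p`); possibly empty.
#' @export
filter_significant_edges <- function(result, alpha = NULL, m = NULL) {
  alpha <- alpha %||% attr(result, "alpha") %||% 0.05
  m <- m %||% nrow(result)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    mc_stop("`alpha` must lie in (0, 1)", "mcnet_validation_error")
  if (!is_count(m) || m < 1)
    mc_stop("`m` must be a positive integer", "mcnet_validation_error")
  keep <- which(result$p <= alpha / m & result$r > 0)
  keep <- keep[order(-result$r[keep], keep)]
  out <- result[keep, c("region", "r", "p")]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}
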