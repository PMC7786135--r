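# Internal helpers shared across the package.

# Classed errors so callers (and the CLI) can distinguish validation problems
# from stage failures.
mc_stop <- function(msg, class = "mcnet_error", call. = FALSE) {
  stop(structure(
    class = c(class, "mcnet_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so seeded internals do not perturb user-level streams.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    mc_stop("`seed` must be a single finite number", "mcnet_validation_error")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream index, kept inside the
# 32-bit integer range.
seed_stream <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 1103L + 7L * i) %% 2147483647)
}

# Row/column indices of the upper triangle in (i, j) lexicographic order:
# (1,2), (1,3), ..., (1,n), (2,3), ...
pair_indices <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i = i, j = j)
}

#' Trapezoidal area under a curve
#'
#' Integrates `y` over the abscissa `x` by the trapezoidal rule. Used to
#' summarise a graph metric over the connection-density grid in one number.
#'
#' @param x Strictly increasing numeric vector (at least two points).
#' @param y Numeric vector of metric values, same length as `x`.
#' @return The trapezoidal integral, a single number.
#' @examples
#' auc_trapezoid(seq(0.05, 0.5, by = 0.05), rep(2, 10)) # 0.45 * 2
#' @export
auc_trapezoid <- function(x, y) {
  if (length(x) < 2L)
    mc_stop("AUC is undefined on fewer than two grid points",
            "mcnet_validation_error")
  if (length(x) != length(y))
    mc_stop("`x` and `y` must have the same length", "mcnet_validation_error")
  if (any(diff(x) <= 0))
    mc_stop("`x` must be strictly increasing", "mcnet_validation_error")
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
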