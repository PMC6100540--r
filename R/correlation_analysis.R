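#' Correlate percent-NAC with percent reactivation
#'
#' Ordinary least-squares line and Pearson correlation of paired per-oxime
#' statistics: the percentage of low-energy docking poses at the near
#' attack conformation (x) against the experimental percent reactivation
#' (y). A permutation p-value for the correlation can be attached via
#' [permutation_pvalue()] or computed here directly.
#'
#' @param pairs Data.frame with columns `pct_nac` and `pct_R` (an optional
#'   `oxime` column is carried through), or a two-column numeric matrix.
#' @param p_perm If `TRUE`, also compute the permutation p-value.
#' @param seed,max_exact,n_mc Passed to [permutation_pvalue()] when
#'   `p_perm = TRUE`.
#' @return An object of class `correlation_result`: `n_pairs`, `slope`,
#'   `intercept`, `pearson_r`, `p_perm` (NA unless requested), `degenerate`
#'   flag (zero variance in either axis), and the input `pairs`.
#' @export
correlate_nac_reactivation <- function(pairs, p_perm = FALSE, seed = NULL,
                                       max_exact = 5040, n_mc = 10000) {
  pairs <- as.data.frame(pairs)
  if (!all(c("pct_nac", "pct_R") %in% names(pairs))) {
    stopifnot(ncol(pairs) >= 2L)
    names(pairs)[1:2] <- c("pct_nac", "pct_R")
  }
  x <- pairs$pct_nac; y <- pairs$pct_R
  if (length(x) < 3L) stop("need at least 3 pairs for a correlation")
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  degenerate <- stats::var(x) == 0 || stats::var(y) == 0
  if (degenerate) {
    res <- list(n_pairs = length(x), slope = NA_real_,
                intercept = NA_real_, pearson_r = NA_real_,
                p_perm = if (p_perm) 1 else NA_real_,
                degenerate = TRUE, pairs = pairs)
    warning("zero variance in one axis; correlation undefined")
    return(structure(res, class = "correlation_result"))
  }
  fit <- stats::lm(y ~ x)
  cf <- unname(stats::coef(fit))
  r <- stats::cor(x, y)
  p <- if (p_perm)
    permutation_pvalue(x, y, max_exact = max_exact, n_mc = n_mc,
                       seed = seed) else NA_real_
  structure(list(n_pairs = length(x), slope = cf[2L], intercept = cf[1L],
                 pearson_r = r, p_perm = p, degenerate = FALSE,
                 pairs = pairs),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (x$degenerate) {
    cat("correlation_result: degenerate (zero variance), n =", x$n_pairs,
        "\n")
  } else {
    cat(sprintf(
      "correlation_result: n = %d, r = %.3f, slope = %.3f, intercept = %.3f",
      x$n_pairs, x$pearson_r, x$slope, x$intercept))
    if (!is.na(x$p_perm)) cat(sprintf(", permutation p = %.4g", x$p_perm))
    cat("\n")
  }
  invisible(x)
}

# All permutations of 1..n as a matrix (n! rows); recursion is fine for the
# n <= 7 regime where exact enumeration is used.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Permutation p-value for a Pearson correlation
#'
#' Two-sided test of the observed |r| against the permutation null obtained
#' by re-pairing y with x in every possible order. When `n! <= max_exact`
#' all pairings are enumerated and the p-value is exact (deterministic and
#' invariant to input order); otherwise a seeded Monte-Carlo sample of
#' `n_mc` permutations is used with the standard add-one correction.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param max_exact Largest permutation count for exhaustive enumeration
#'   (default 5040 = 7!).
#' @param n_mc Monte-Carlo sample size beyond that (default 10000).
#' @param seed Seed for the Monte-Carlo branch.
#' @return The p-value in \[0, 1\]. Degenerate variance gives 1 with a
#'   warning.
#' @export
permutation_pvalue <- function(x, y, max_exact = 5040, n_mc = 10000,
                               seed = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero variance; permutation p-value undefined, returning 1")
    return(1)
  }
  n <- length(x)
  r_obs <- abs(stats::cor(x, y))
  tol <- 1e-12
  if (factorial(n) <= max_exact) {
    perms <- all_permutations(n)
    r_perm <- apply(perms, 1L, function(p) abs(stats::cor(x, y[p])))
    mean(r_perm >= r_obs - tol)
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- sum(vapply(seq_len(n_mc), function(i)
      abs(stats::cor(x, sample(y))) >= r_obs - tol, TRUE))
    (1 + hits) / (n_mc + 1)
  }
}
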