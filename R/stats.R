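# Resampling statistics used across the pipeline: a one-tailed permutation
# test of the difference of means (daughter-size comparisons) and percentile
# bootstrap confidence intervals of the mean (radial recoil velocities,
# texture curves).

#' One-tailed permutation test of the difference of means
#'
#' Observed statistic is `mean(x) - mean(y)`. Group labels are shuffled
#' `n_perm` times with a seeded generator and the Monte-Carlo p-value uses
#' the +1 correction, `p = (1 + n_extreme) / (n_perm + 1)`, so it can never
#' be 0. When the number of distinct label splits `choose(nx+ny, nx)` is at
#' most `enumerate_limit` and `mode` is `"auto"` or `"exact"`, all splits
#' are enumerated instead and the p-value is exact (`n_perm` is ignored).
#' The tail direction must be supplied explicitly.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param alternative `"greater"` (mean(x) > mean(y)) or `"less"`.
#' @param n_perm number of Monte-Carlo permutations (default 9999).
#' @param seed integer seed for the shuffles.
#' @param mode `"auto"`, `"montecarlo"` or `"exact"` (full enumeration).
#' @param enumerate_limit largest split count enumerated in auto mode
#'   (default 1e5).
#' @return a `permutation_result`: list with `observed`, `p_value`,
#'   `n_permutations`, `alternative`, `exact`, `seed`.
#' @export
permutation_test_diff_means <- function(x, y,
                                        alternative = c("greater", "less"),
                                        n_perm = 9999L, seed = 1L,
                                        mode = c("auto", "montecarlo",
                                                 "exact"),
                                        enumerate_limit = 1e5) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("both groups need at least 2 observations")
  }
  nx <- length(x); ny <- length(y)
  pool <- c(x, y)
  obs <- mean(x) - mean(y)
  as_extreme <- function(stat) {
    if (alternative == "greater") stat >= obs - 1e-12 * max(1, abs(obs))
    else stat <= obs + 1e-12 * max(1, abs(obs))
  }
  n_splits <- choose(nx + ny, nx)
  if (mode == "exact" || (mode == "auto" && n_splits <= enumerate_limit)) {
    idx <- utils::combn(nx + ny, nx)
    tot <- sum(pool)
    stats_all <- colSums(matrix(pool[idx], nrow = nx)) / nx -
      (tot - colSums(matrix(pool[idx], nrow = nx))) / ny
    p <- mean(as_extreme(stats_all))  # includes the observed split itself
    return(structure(list(observed = obs, p_value = p,
                          n_permutations = ncol(idx),
                          alternative = alternative, exact = TRUE,
                          seed = NA_integer_),
                     class = "permutation_result"))
  }
  n_perm <- as.integer(n_perm)
  stats_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      id <- sample.int(nx + ny, nx)
      mean(pool[id]) - mean(pool[-id])
    }, numeric(1))
  })
  p <- (1 + sum(as_extreme(stats_perm))) / (n_perm + 1)
  structure(list(observed = obs, p_value = p, n_permutations = n_perm,
                 alternative = alternative, exact = FALSE,
                 seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test of difference of means (%s)\n  observed = %.6g, p = %.4g (%s, %d %s)\n",
    x$alternative, x$observed, x$p_value,
    if (x$exact) "exact enumeration" else "+1-corrected Monte-Carlo",
    x$n_permutations,
    if (x$exact) "splits" else "permutations"))
  invisible(x)
}

#' Percentile bootstrap confidence interval of the mean
#'
#' Resamples the data with replacement `n_boot` times under a fixed seed
#' and returns the percentile interval of the resampled mean.
#'
#' @param values numeric vector, `n >= 2`.
#' @param level confidence level (default 0.99, the level used for radial
#'   recoil velocities).
#' @param n_boot number of bootstrap resamples (default 2000).
#' @param seed integer seed.
#' @return list with `lo`, `hi`, `level`, `n_boot`, `mean`.
#' @export
bootstrap_ci_mean <- function(values, level = 0.99, n_boot = 2000L,
                              seed = 1L) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("need at least 2 values for a bootstrap CI")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  n_boot <- as.integer(n_boot)
  means <- with_seed(seed, {
    idx <- sample.int(n, n * n_boot, replace = TRUE)
    colMeans(matrix(values[idx], nrow = n))
  })
  qs <- stats::quantile(means, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  list(lo = qs[1L], hi = qs[2L], level = level, n_boot = n_boot,
       mean = mean(values))
}

# run code under a local RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}
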