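# cache for exact null distributions of the rank statistic, keyed by n
.spearman_cache <- new.env(parent = emptyenv())

#' Exact null counts of T = sum(i * pi(i)) over all permutations of 1..n
#'
#' Spearman's S = sum((i - pi(i))^2) relates to T by
#' S = n(n+1)(2n+1)/3 - 2T, so the null distribution of S (and of rs)
#' follows from the counts of T. Computed by a bit-mask dynamic program
#' over value subsets: positions are assigned in order, and each state
#' holds the count vector over partial sums. Exact for n <= 13 (counts
#' stay below 2^53).
#'
#' @param n number of untied rank pairs (2 <= n <= 13).
#' @return numeric vector `counts` where `counts[t + 1]` is the number
#'   of permutations with T = t; sums to n!.
#' @export
spearman_s_null_counts <- function(n) {
  n <- as.integer(n)
  if (n < 2L || n > 13L) {
    stop("exact null distribution supported for 2 <= n <= 13", call. = FALSE)
  }
  key <- as.character(n)
  if (!is.null(.spearman_cache[[key]])) return(.spearman_cache[[key]])
  full <- bitwShiftL(1L, n) - 1L
  popcnt <- integer(full + 1L)
  for (m in seq_len(full)) {
    popcnt[m + 1L] <- popcnt[bitwShiftR(m, 1L) + 1L] + (m %% 2L)
  }
  dp <- vector("list", full + 1L)
  dp[[1L]] <- 1  # empty assignment, T = 0
  for (m in seq_len(full)) {
    pos <- popcnt[m + 1L]  # position being assigned (1-based)
    acc <- NULL
    for (j in seq_len(n)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(m, bit) != 0L) {
        prev <- dp[[bitwXor(m, bit) + 1L]]
        shifted <- c(numeric(pos * j), prev)
        if (is.null(acc)) {
          acc <- shifted
        } else {
          if (length(shifted) > length(acc)) {
            acc <- c(acc, numeric(length(shifted) - length(acc)))
          } else if (length(acc) > length(shifted)) {
            shifted <- c(shifted, numeric(length(acc) - length(shifted)))
          }
          acc <- acc + shifted
        }
      }
    }
    dp[[m + 1L]] <- acc
  }
  counts <- dp[[full + 1L]]
  .spearman_cache[[key]] <- counts
  counts
}

#' Exact two-sided p-value for Spearman's S
#'
#' @param s_obs observed sum of squared rank differences (integer-valued
#'   when ranks are untied).
#' @param n number of pairs.
#' @return P(|RS| >= |rs_obs|) under the permutation null.
#' @noRd
spearman_exact_p <- function(s_obs, n) {
  counts <- spearman_s_null_counts(n)
  tvals <- seq_along(counts) - 1
  svals <- n * (n + 1) * (2 * n + 1) / 3 - 2 * tvals
  mu <- (n^3 - n) / 6  # S value at rs = 0 (symmetry center)
  sum(counts[abs(svals - mu) >= abs(s_obs - mu) - 1e-9]) / sum(counts)
}

#' Spearman rank correlation with exact small-sample p-values
#'
#' Computes the Spearman coefficient (Pearson correlation of average
#' ranks) and a two-sided p-value. With `method = "auto"`, untied
#' samples of n <= 9 get an exact permutation p-value (full null
#' distribution of the rank statistic); otherwise the t approximation
#' `t = rs * sqrt((n - 2) / (1 - rs^2))` on n - 2 df is used.
#' `method = "exact_s"` opts in to the exact distribution up to n = 13
#' (untied ranks only).
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @param method `"auto"`, `"exact"`, `"exact_s"` or `"t"`.
#' @return list of class `correlation_result` with elements `rs`,
#'   `p_value`, `n`, `method` (`"exact_permutation"` or
#'   `"t_approximation"`) and `s_statistic` (sum of squared rank
#'   differences).
#' @export
#' @examples
#' spearman_rank(1:5, c(2, 1, 4, 3, 5))
spearman_rank <- function(x, y, method = c("auto", "exact", "exact_s", "t")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant input vector", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rs <- stats::cor(rx, ry)
  s_stat <- sum((rx - ry)^2)
  ties <- anyDuplicated(rx) > 0L || anyDuplicated(ry) > 0L
  n_cap <- switch(method, auto = 9L, exact = 9L, exact_s = 13L, t = -1L)
  use_exact <- !ties && n <= n_cap
  if (!use_exact && method %in% c("exact", "exact_s")) {
    warning(sprintf(
      "exact p-value unavailable (%s); using t approximation",
      if (ties) "tied ranks" else sprintf("n > %d", n_cap)), call. = FALSE)
  }
  if (use_exact) {
    p <- spearman_exact_p(s_stat, n)
    meth <- "exact_permutation"
  } else {
    if (abs(rs) >= 1) {
      p <- 0
    } else {
      tval <- rs * sqrt((n - 2) / (1 - rs^2))
      p <- 2 * stats::pt(-abs(tval), df = n - 2)
    }
    meth <- "t_approximation"
  }
  structure(list(rs = rs, p_value = p, n = n, method = meth,
                 s_statistic = s_stat),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rs = %.3f (n = %d, p = %.4g, %s)\n",
              x$rs, x$n, x$p_value, x$method))
  invisible(x)
}
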