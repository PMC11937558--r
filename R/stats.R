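# Inference utilities: Monte-Carlo Fisher-Pitman permutation test and
# Spearman rank correlation.

#' Fisher-Pitman permutation test (Monte-Carlo)
#'
#' Two-sample comparison of means under the exchangeability null: the
#' observed statistic is the difference of group means, the null
#' distribution is generated by randomly reallocating the pooled values to
#' the two groups. The two-sided p-value uses the add-one correction
#' `p = (1 + #(|perm| >= |obs|)) / (1 + n_iter)`, so a Monte-Carlo p is
#' never exactly zero.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param n_iter number of Monte-Carlo permutations.
#' @param seed integer seed; results are deterministic per seed.
#' @return list of class `fisher_pitman`: `observed_stat`, `p_value`,
#'   `n_iter`, `seed`.
#' @export
fisher_pitman <- function(x, y, n_iter = 1000, seed = 1L) {
  stop_if(length(x) < 2 || length(y) < 2, "each sample needs >= 2 values")
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  obs <- mean(x) - mean(y)
  if (max(pooled) - min(pooled) == 0) {
    return(structure(list(observed_stat = 0, p_value = 1,
                          n_iter = as.integer(n_iter),
                          seed = as.integer(seed)),
                     class = "fisher_pitman"))
  }
  tot <- sum(pooled)
  perm <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      s1 <- sum(pooled[sample.int(n, n1)])
      s1 / n1 - (tot - s1) / (n - n1)
    }, 0)
  })
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (1 + n_iter)
  structure(list(observed_stat = obs, p_value = p,
                 n_iter = as.integer(n_iter), seed = as.integer(seed)),
            class = "fisher_pitman")
}

#' @export
print.fisher_pitman <- function(x, ...) {
  cat(sprintf("Fisher-Pitman permutation test: diff of means = %.4g, p = %.4g (%d Monte-Carlo iterations)\n",
              x$observed_stat, x$p_value, x$n_iter))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties averaged), computed explicitly.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\]; `NA` with a warning if either input is
#'   constant.
#' @export
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3))  # 0.6
spearman_rho <- function(x, y) {
  stop_if(length(x) != length(y), "x and y must have equal length")
  stop_if(length(x) < 3, "need at least 3 paired observations")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  stop_if(length(x) < 3, "need at least 3 complete pairs")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(NA_real_)
  }
  cx <- rx - mean(rx); cy <- ry - mean(ry)
  sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
}
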