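#' Filter an expression table to expressed transcripts
#'
#' Retains transcripts with expression strictly greater than the threshold
#' (default TPM > 1).
#'
#' @param expression Data.frame \code{transcript_id}, \code{tpm}, or a named
#'   numeric vector.
#' @param threshold Strict lower bound (default 1).
#' @return Character vector of retained transcript ids.
#' @export
filter_expressed <- function(expression, threshold = 1) {
  if (is.data.frame(expression)) {
    tpm <- expression$tpm
    ids <- expression$transcript_id
  } else {
    tpm <- as.numeric(expression)
    ids <- names(expression)
  }
  if (anyNA(tpm) || any(!is.finite(tpm)) || any(tpm < 0))
    stop_("expression values must be finite and non-negative")
  ids[tpm > threshold]
}

#' One-sided rank-sum comparison of two expression groups
#'
#' Wilcoxon rank-sum test with alternative "group greater than other", using
#' the normal approximation with tie correction.
#'
#' @param group_values,other_values Non-empty numeric vectors.
#' @return The one-sided p-value.
#' @export
group_compare <- function(group_values, other_values) {
  if (length(group_values) == 0 || length(other_values) == 0)
    stop_("both groups must be non-empty")
  stats::wilcox.test(group_values, other_values, alternative = "greater",
                     exact = FALSE)$p.value
}

#' Repeated simple-random-sampling expression comparison
#'
#' Compares a group of transcripts against repeated equally sized random
#' draws from a pool. Each round draws, without replacement, a comparison
#' set of size k = min(group size, pool size) from the pool (and, if the
#' group is larger than k, an equally sized subset of the group) and records
#' the one-sided rank-sum p-value for "group greater". The number of rounds
#' with p below \code{alpha} summarizes how consistently the group exceeds
#' random sets of equal size.
#'
#' \code{pseudocode_literal = TRUE} instead draws, with replacement, a set
#' of the group's size from the pool each round and compares the full group
#' against it.
#'
#' @param group_values,pool_values Numeric expression values; if named, the
#'   two sets of names must be disjoint.
#' @param n_rounds Number of sampling rounds (default 10000).
#' @param seed RNG seed.
#' @param alpha Per-round significance threshold (default 0.05).
#' @param pseudocode_literal See Details.
#' @return An object of class \code{"sampling_result"}: list with \code{p}
#'   (the per-round p-values), \code{n_significant}, \code{n_rounds},
#'   \code{alpha}, \code{k}, group and pool sizes, and \code{seed}.
#' @export
random_sampling_test <- function(group_values, pool_values,
                                 n_rounds = 10000, seed = 1, alpha = 0.05,
                                 pseudocode_literal = FALSE) {
  if (!is.null(names(group_values)) && !is.null(names(pool_values)) &&
      length(intersect(names(group_values), names(pool_values))) > 0)
    stop_("group and pool must be disjoint sets of transcripts")
  if (length(pool_values) < 2) stop_("pool must contain at least 2 values")
  if (length(group_values) == 0) stop_("group must be non-empty")
  k <- min(length(group_values), length(pool_values))
  P <- with_seed(seed, vapply(seq_len(n_rounds), function(i) {
    if (pseudocode_literal) {
      tmp <- sample(pool_values, length(group_values), replace = TRUE)
      group_compare(group_values, tmp)
    } else {
      g <- if (length(group_values) > k) sample(group_values, k)
           else group_values
      group_compare(g, sample(pool_values, k))
    }
  }, numeric(1)))
  structure(list(p = P, n_significant = sum(P < alpha),
                 n_rounds = n_rounds, alpha = alpha, k = k,
                 group_size = length(group_values),
                 pool_size = length(pool_values), seed = seed),
            class = "sampling_result")
}

#' @export
print.sampling_result <- function(x, ...) {
  cat(sprintf("Random-sampling expression comparison (%d rounds, seed %d)\n",
              x$n_rounds, x$seed))
  cat(sprintf("  group %d vs pool %d (per-round comparison size %d)\n",
              x$group_size, x$pool_size, x$k))
  cat(sprintf("  rounds with p < %g: %d/%d (%.1f%%)\n", x$alpha,
              x$n_significant, x$n_rounds,
              100 * x$n_significant / x$n_rounds))
  invisible(x)
}

#' Plot the p-value distribution of a sampling comparison
#'
#' @param x A \code{sampling_result} object.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.sampling_result <- function(x, ...) {
  graphics::hist(x$p, breaks = 50, col = "grey85", border = "white",
                 main = "Per-round one-sided p-values", xlab = "p", ...)
  graphics::abline(v = x$alpha, col = "darkorange", lwd = 2, lty = 2)
  invisible(x)
}
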