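#' Analysis of similarity (ANOSIM)
#'
#' Rank-based test of whether between-group dissimilarities are larger
#' than within-group dissimilarities. All `n(n-1)/2` pairwise distances
#' are ranked (average ranks for ties) and
#' `R = (mean rank between - mean rank within) / (n(n-1)/4)`.
#' `R` close to 1 indicates cohesive, well separated groups; values near 0
#' indicate no group structure. Because the statistic depends on the
#' distances only through their ranks, it is invariant under any strictly
#' monotone transform of the distances.
#'
#' The p-value is obtained by permuting group labels: with the add-one
#' convention `p = (#(R_perm >= R_obs) + 1) / (n_perm + 1)`, so the
#' observed labelling counts as one permutation and `p` is never 0.
#'
#' @param d distance matrix (labelled square matrix or `dist`).
#' @param groups group labels: a named vector (matched to `d`'s labels) or
#'   an unnamed vector in `d`'s order. Every group must have >= 2 members.
#' @param n_perm number of label permutations (default 9999).
#' @param seed optional RNG seed for the permutations.
#' @param keep_permuted keep the permuted R values in the result.
#' @return an object of class `anosim_result` with elements `statistic`
#'   (Global R), `p_value`, `n_perm`, `group_sizes`, and optionally
#'   `permuted`.
#' @examples
#' d <- as.matrix(dist(c(0, 0.1, 5, 5.1)))
#' rownames(d) <- colnames(d) <- letters[1:4]
#' anosim(d, c(a = "x", b = "x", c = "y", d = "y"), n_perm = 99, seed = 1)
#' @export
anosim <- function(d, groups, n_perm = 9999, seed = NULL,
                   keep_permuted = FALSE) {
  dm <- as_distance_matrix(d)
  n <- nrow(dm)
  g <- align_groups(groups, rownames(dm))
  sizes <- table(g)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2)) {
    stop("group(s) with a single member (no within-group pair): ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  rk <- rank(lower_vec(dm))
  denom <- n * (n - 1) / 4
  gi <- as.integer(factor(g))
  r_of <- function(gi) {
    within <- lower_vec(outer(gi, gi, "=="))
    (mean(rk[!within]) - mean(rk[within])) / denom
  }
  r_obs <- r_of(gi)
  permuted <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) r_of(sample(gi)), numeric(1))
  })
  p <- (sum(permuted >= r_obs) + 1) / (n_perm + 1)
  structure(list(
    statistic = r_obs, p_value = p, n_perm = n_perm,
    group_sizes = as.integer(sizes),
    permuted = if (keep_permuted) permuted else NULL
  ), class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: Global R = %.4f%s  (p = %.4g, %d permutations)\n",
              x$statistic, p_stars(x$p_value), x$p_value, x$n_perm))
  invisible(x)
}
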