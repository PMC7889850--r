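#' Mantel test of matrix correlation
#'
#' Pearson correlation between the upper-triangle entries of two distance
#' matrices over the same objects, with significance from jointly
#' permuting the rows and columns of the second matrix. The test is
#' one-sided (permuted r >= observed r) with the add-one convention. The
#' matrices are aligned by label before computation, so input row order is
#' irrelevant.
#'
#' @param d1,d2 labelled distance matrices (or `dist` objects) over the
#'   same label set.
#' @param n_perm number of permutations (default 9999, the conventional
#'   choice for distance-matrix correlation tests).
#' @param seed optional RNG seed.
#' @return an object of class `mantel_result` with `r`, `p_value`,
#'   `n_perm`.
#' @export
mantel <- function(d1, d2, n_perm = 9999, seed = NULL) {
  m1 <- as_distance_matrix(d1, "d1")
  m2 <- as_distance_matrix(d2, "d2")
  if (!setequal(rownames(m1), rownames(m2))) {
    only1 <- setdiff(rownames(m1), rownames(m2))
    only2 <- setdiff(rownames(m2), rownames(m1))
    stop("label mismatch between matrices",
         if (length(only1)) paste0("; only in d1: ", paste(only1, collapse = ", ")),
         if (length(only2)) paste0("; only in d2: ", paste(only2, collapse = ", ")))
  }
  m2 <- m2[rownames(m1), rownames(m1)]
  v1 <- lower_vec(m1)
  v2 <- lower_vec(m2)
  if (sd(v1) == 0 || sd(v2) == 0) {
    stop("zero variance in a distance matrix: Mantel r undefined")
  }
  r_obs <- cor(v1, v2)
  n <- nrow(m1)
  permuted <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      cor(v1, lower_vec(m2[idx, idx]))
    }, numeric(1))
  })
  p <- (sum(permuted >= r_obs) + 1) / (n_perm + 1)
  structure(list(r = r_obs, p_value = p, n_perm = n_perm),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f%s  (p = %.4g, %d permutations)\n",
              x$r, p_stars(x$p_value), x$p_value, x$n_perm))
  invisible(x)
}
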