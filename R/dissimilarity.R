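#' p-distance between two binary profiles
#'
#' Proportion of positions at which two equal-length 0/1 profiles differ.
#' This is the distance used to score blind-replicate reproducibility: two
#' perfect technical replicates have p-distance zero.
#'
#' @param a,b binary vectors of equal length (>= 1).
#' @return a value in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop(sprintf("profile length mismatch: %d vs %d", length(a), length(b)))
  }
  if (length(a) == 0) stop("profiles must have at least one position")
  mean(a != b)
}

#' Jaccard dissimilarity matrix for binary marker data
#'
#' `d(i, j) = 1 - shared / union`, where `shared` counts loci with a band
#' in both samples and `union` counts loci with a band in at least one of
#' the two. Shared absences carry no information for dominant markers and
#' are ignored. A pair of all-zero profiles has an undefined (0/0) Jaccard
#' value; it is reported as 0 with a warning.
#'
#' @param m an [aflp_matrix()] (or a plain 0/1 matrix with dimnames).
#' @return a labelled symmetric distance matrix with zero diagonal.
#' @export
jaccard_matrix <- function(m) {
  x <- unclass(m)
  if (!is.matrix(x) || nrow(x) < 2 || ncol(x) < 1) {
    stop("need a matrix with >= 2 samples and >= 1 locus")
  }
  storage.mode(x) <- "double"
  shared <- x %*% t(x)
  bands <- rowSums(x)
  union <- outer(bands, bands, "+") - shared
  d <- 1 - shared / union
  dz <- union == 0
  if (any(dz[lower.tri(dz)])) {
    warning("double-zero sample pair(s): Jaccard undefined, reported as 0")
    d[dz] <- 0
  }
  diag(d) <- 0
  rownames(d) <- colnames(d) <- rownames(x)
  d
}

#' Gower distance matrix for dosage genotype data
#'
#' `d(i, j)` is the mean, over loci at which both samples are scored, of
#' `|x_il - x_jl| / r_l` with `r_l` the locus's observed dosage range.
#' Monomorphic loci (zero range) contribute nothing and are excluded from
#' the mean; missing entries are handled by pairwise deletion (no
#' imputation). Suitable for SNP matrices with substantial random
#' missingness.
#'
#' @param g a [genotype_matrix()] (or a numeric matrix with `NA` missing).
#' @return a labelled symmetric distance matrix with zero diagonal.
#' @export
gower_matrix <- function(g) {
  x <- unclass(g)
  if (!is.matrix(x) || nrow(x) < 2) stop("need >= 2 samples")
  storage.mode(x) <- "double"
  rng <- suppressWarnings(apply(x, 2, function(col) {
    v <- col[!is.na(col)]
    if (length(v) == 0) NA_real_ else max(v) - min(v)
  }))
  keep <- !is.na(rng) & rng > 0
  xs <- sweep(x[, keep, drop = FALSE], 2, rng[keep], "/")
  obs <- !is.na(x)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    rest <- (i + 1):n
    # pairs must share at least one jointly scored locus (any range)
    joint <- obs[rest, , drop = FALSE] %*% obs[i, ]
    if (any(joint == 0)) {
      j <- rest[which(joint == 0)[1]]
      stop(sprintf("samples '%s' and '%s' share no jointly scored locus",
                   rownames(x)[i], rownames(x)[j]))
    }
    diffs <- abs(sweep(xs[rest, , drop = FALSE], 2, xs[i, ], "-"))
    usable <- rowSums(!is.na(diffs))
    # all shared loci monomorphic: every contribution is 0, distance 0
    d[i, rest] <- d[rest, i] <-
      ifelse(usable > 0, rowSums(diffs, na.rm = TRUE) / usable, 0)
  }
  d
}
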