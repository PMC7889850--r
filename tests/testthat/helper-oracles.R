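# Independent brute-force oracles. These deliberately re-derive every
# statistic from its definition with naive loops, so they share no code
# path with the implementations they check.

# ANOSIM Global R straight from the definition: rank all pairwise
# distances, compare mean between-group and within-group ranks.
oracle_anosim_r <- function(dm, groups) {
  n <- nrow(dm)
  pairs <- which(lower.tri(dm), arr.ind = TRUE)
  dvals <- dm[pairs]
  rk <- rank(dvals)
  within <- groups[pairs[, 1]] == groups[pairs[, 2]]
  (mean(rk[!within]) - mean(rk[within])) / (n * (n - 1) / 4)
}

# Pearson correlation of the two upper triangles, from the raw formula.
oracle_mantel_r <- function(m1, m2) {
  v1 <- m1[upper.tri(m1)]
  v2 <- m2[upper.tri(m2)]
  num <- sum((v1 - mean(v1)) * (v2 - mean(v2)))
  num / sqrt(sum((v1 - mean(v1))^2) * sum((v2 - mean(v2))^2))
}

# All permutations of 1..n as a matrix (n! rows); n <= 7 only.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- vector("list", n)
  for (pos in seq_len(n)) {
    block <- matrix(0L, nrow(sub), n)
    block[, pos] <- n
    block[, -pos] <- sub
    out[[pos]] <- block
  }
  do.call(rbind, out)
}

# Exact ANOSIM p-value by enumerating every label assignment.
oracle_anosim_p_exact <- function(dm, groups) {
  r_obs <- oracle_anosim_r(dm, groups)
  perms <- all_perms(nrow(dm))
  rs <- apply(perms, 1, function(idx) oracle_anosim_r(dm, groups[idx]))
  mean(rs >= r_obs - 1e-12)
}

# Exact Mantel p-value by enumerating every joint row/column permutation.
oracle_mantel_p_exact <- function(m1, m2) {
  r_obs <- oracle_mantel_r(m1, m2)
  perms <- all_perms(nrow(m1))
  rs <- apply(perms, 1, function(idx) oracle_mantel_r(m1, m2[idx, idx]))
  mean(rs >= r_obs - 1e-12)
}

# Literal re-application of the remove-recompute-compare rule, computed
# with p-distances in floating point (an epsilon keeps exact ties as
# "keep", matching the strict-inequality rule).
oracle_greedy <- function(values, pairs) {
  repsum <- function(v) {
    sum(apply(pairs, 1, function(p) mean(v[p[1], ] != v[p[2], ])))
  }
  v <- values
  removed <- character(0)
  for (loc in colnames(values)) {
    if (ncol(v) <= 1) break
    s_now <- repsum(v)
    v_try <- v[, setdiff(colnames(v), loc), drop = FALSE]
    if (repsum(v_try) < s_now - 1e-9) {
      v <- v_try
      removed <- c(removed, loc)
    }
  }
  list(removed = removed, final_sum = repsum(v))
}

# Naive Jaccard by counting bands pair by pair.
oracle_jaccard <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      shared <- sum(x[i, ] == 1 & x[j, ] == 1)
      union <- sum(x[i, ] == 1 | x[j, ] == 1)
      d[i, j] <- if (union == 0) 0 else 1 - shared / union
    }
  }
  d
}

# Naive Gower with range scaling, zero-range exclusion and pairwise
# deletion, locus by locus.
oracle_gower <- function(x) {
  n <- nrow(x)
  rng <- apply(x, 2, function(col) {
    v <- col[!is.na(col)]
    if (length(v) == 0) NA else max(v) - min(v)
  })
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      num <- 0
      cnt <- 0
      for (l in seq_len(ncol(x))) {
        if (is.na(x[i, l]) || is.na(x[j, l])) next
        if (is.na(rng[l]) || rng[l] == 0) next
        num <- num + abs(x[i, l] - x[j, l]) / rng[l]
        cnt <- cnt + 1
      }
      d[i, j] <- num / cnt
    }
  }
  d
}

# Naive NMDS: isotonic regression + numeric gradient descent on Kruskal
# stress-1, from a given start configuration.
oracle_nmds_stress <- function(dm, x0, iters = 200, lr = 0.05) {
  dv <- dm[lower.tri(dm)]
  ord <- order(dv)
  stress_of <- function(x) {
    cd <- as.matrix(dist(matrix(x, nrow(dm))))
    dvec <- cd[lower.tri(cd)]
    dhat <- numeric(length(dvec))
    dhat[ord] <- isoreg(dvec[ord])$yf
    sqrt(sum((dvec - dhat)^2) / sum(dvec^2))
  }
  x <- as.vector(x0)
  s <- stress_of(x)
  h <- 1e-5
  for (it in seq_len(iters)) {
    grad <- vapply(seq_along(x), function(i) {
      xp <- x
      xp[i] <- xp[i] + h
      (stress_of(xp) - s) / h
    }, numeric(1))
    step <- lr
    repeat {
      xn <- x - step * grad
      sn <- stress_of(xn)
      if (sn < s || step < 1e-8) break
      step <- step / 2
    }
    if (sn >= s) break
    x <- xn
    s <- sn
  }
  s
}

# Random labelled distance matrix fixture.
random_dist <- function(n, seed) {
  withr::with_seed(seed, {
    x <- matrix(runif(n * n), n)
    d <- as.matrix(dist(x))
    rownames(d) <- colnames(d) <- paste0("s", seq_len(n))
    d
  })
}

# Random group assignment with every group size >= 2.
random_groups <- function(n, k, seed) {
  withr::with_seed(seed, {
    repeat {
      g <- sample(paste0("g", seq_len(k)), n, replace = TRUE)
      if (all(table(g) >= 2) && length(unique(g)) == k) return(g)
    }
  })
}
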