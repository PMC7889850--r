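mk_aflp <- function(vals, ids = NULL, loci = NULL) {
  ids <- ids %||% paste0("s", seq_len(nrow(vals)))
  loci <- loci %||% paste0("L", seq_len(ncol(vals)))
  dimnames(vals) <- list(ids, loci)
  aflp_matrix(vals)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("p_distance matches direct mismatch counting", {
  expect_identical(p_distance(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_identical(p_distance(c(1, 0), c(0, 1)), 1)
  expect_identical(p_distance(c(1, 0, 1, 1), c(1, 1, 0, 1)), 0.5)
  expect_error(p_distance(c(1, 0), c(1, 0, 1)), "length mismatch")
  expect_error(p_distance(numeric(0), numeric(0)), "at least one")
})

test_that("Jaccard follows the shared/union definition", {
  m <- mk_aflp(rbind(c(1, 1, 0, 0), c(1, 0, 1, 0)))
  d <- jaccard_matrix(m)
  expect_equal(d["s1", "s2"], 2 / 3)  # shared 1, union 3
  expect_equal(diag(d), c(s1 = 0, s2 = 0))
  # identical rows
  m2 <- mk_aflp(rbind(c(1, 0, 1), c(1, 0, 1)))
  expect_equal(jaccard_matrix(m2)["s1", "s2"], 0)
  # double-zero pair: defined as 0 with a warning
  m3 <- mk_aflp(rbind(c(0, 0), c(0, 0), c(1, 0)))
  expect_warning(d3 <- jaccard_matrix(m3), "double-zero")
  expect_equal(d3["s1", "s2"], 0)
})

test_that("Jaccard agrees with a naive oracle and with vegan on random data", {
  skip_if_not_installed("vegan")
  for (seed in 1:5) {
    x <- withr::with_seed(seed, matrix(rbinom(12 * 20, 1, 0.4), 12, 20))
    x[1, ] <- 1L  # avoid all-zero rows
    m <- mk_aflp(x)
    d <- jaccard_matrix(m)
    expect_equal(d, oracle_jaccard(unclass(m)), tolerance = 1e-12)
    dv <- as.matrix(vegan::vegdist(unclass(m), method = "jaccard",
                                   binary = TRUE))
    dimnames(dv) <- dimnames(d)
    expect_equal(d, dv, tolerance = 1e-10)
  }
})

test_that("Gower follows the range-scaled pairwise-deletion definition", {
  vals <- rbind(c(0, 2, 1), c(2, 2, NA))
  dimnames(vals) <- list(c("a", "b"), c("L1", "L2", "L3"))
  # ranges {2, 0, NA-tolerant}: L2 monomorphic -> excluded; L3 missing in b
  # -> only L1 usable: |0-2|/2 = 1
  g <- genotype_matrix(vals)
  expect_equal(gower_matrix(g)["a", "b"], 1)

  # spec-style hand case with full per-locus ranges: add rows so each locus
  # spans 0..2, then check the pair (0,2,1) vs (2,2,NA): contributions
  # (1, 0) over 2 usable loci -> 0.5
  vals2 <- rbind(c(0, 2, 1), c(2, 2, NA), c(2, 0, 0), c(0, 1, 2))
  dimnames(vals2) <- list(letters[1:4], c("L1", "L2", "L3"))
  g2 <- genotype_matrix(vals2)
  expect_equal(gower_matrix(g2)["a", "b"], 0.5)

  # identical rows, no missing
  vals3 <- rbind(c(0, 1, 2), c(0, 1, 2))
  dimnames(vals3) <- list(c("a", "b"), c("L1", "L2", "L3"))
  expect_equal(gower_matrix(genotype_matrix(vals3))["a", "b"], 0)

  # a pair sharing no jointly scored polymorphic locus errors with names
  vals4 <- rbind(c(0L, NA), c(NA, 2L), c(1L, 0L))
  dimnames(vals4) <- list(c("a", "b", "c"), c("L1", "L2"))
  expect_error(gower_matrix(genotype_matrix(vals4)), "'a' and 'b'")
})

test_that("Gower matches the naive oracle and cluster::daisy", {
  skip_if_not_installed("cluster")
  for (seed in 1:5) {
    sim <- simulate_paired(sim_params(n_loci_aflp = 4, n_loci_snp = 40,
                                      n_regions = 3, n_per_region = 4,
                                      missing_rate = 0.15, seed = seed))
    g <- sim$snp$matrix
    d <- gower_matrix(g)
    expect_equal(d, oracle_gower(unclass(g)), tolerance = 1e-12)
    # daisy agrees when every locus is polymorphic (it treats zero-range
    # columns differently, which our definition excludes from the mean)
    poly <- apply(unclass(g), 2, function(col) {
      v <- col[!is.na(col)]
      length(unique(v)) > 1
    })
    dd <- as.matrix(suppressWarnings(cluster::daisy(
      as.data.frame(unclass(g)[, poly, drop = FALSE]), metric = "gower")))
    dimnames(dd) <- dimnames(d)
    expect_equal(d, dd, tolerance = 1e-10)
  }
})

test_that("distance outputs satisfy the distance-matrix contract", {
  sim <- simulate_paired(sim_params(n_loci_aflp = 50, n_loci_snp = 50,
                                    missing_rate = 0.1, seed = 3))
  dj <- suppressWarnings(jaccard_matrix(sim$aflp$matrix))
  dg <- gower_matrix(sim$snp$matrix)
  for (d in list(dj, dg)) {
    expect_identical(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1 + 1e-12))
  }
})

test_that("Jaccard is locus-permutation equivariant; Gower polarity-invariant", {
  sim <- simulate_paired(sim_params(n_loci_aflp = 30, n_loci_snp = 30,
                                    missing_rate = 0.1, seed = 8))
  m <- sim$aflp$matrix
  perm <- withr::with_seed(1, sample(ncol(m)))
  expect_equal(jaccard_matrix(m), jaccard_matrix(m[, perm]), tolerance = 1e-12)

  g <- sim$snp$matrix
  flip <- withr::with_seed(2, sample(c(TRUE, FALSE), ncol(g), replace = TRUE))
  gf <- unclass(g)
  gf[, flip] <- 2L - gf[, flip]
  expect_equal(gower_matrix(g), gower_matrix(genotype_matrix(gf)),
               tolerance = 1e-12)
})

test_that("constant loci: all-0 leaves Jaccard unchanged, all-1 weakly shrinks it; zero-range loci leave Gower unchanged", {
  sim <- simulate_paired(sim_params(n_loci_aflp = 25, n_loci_snp = 25,
                                    missing_rate = 0, seed = 12))
  m <- sim$aflp$matrix
  base <- jaccard_matrix(m)
  add_locus <- function(m, v) {
    x <- cbind(unclass(m), newL = v)
    aflp_matrix(x)
  }
  with_zero <- jaccard_matrix(add_locus(m, 0L))
  expect_equal(with_zero, base, tolerance = 1e-12)
  with_one <- jaccard_matrix(add_locus(m, 1L))
  expect_true(all(with_one <= base + 1e-12))

  g <- sim$snp$matrix
  gb <- gower_matrix(g)
  g2 <- genotype_matrix(cbind(unclass(g), mono = 1L))
  expect_equal(gower_matrix(g2), gb, tolerance = 1e-12)
})
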