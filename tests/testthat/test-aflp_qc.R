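mk_fixture <- function(vals, ids) {
  dimnames(vals) <- list(ids, paste0("L", seq_len(ncol(vals))))
  aflp_matrix(vals)
}

test_that("replicate_distance_sum sums pairwise p-distances", {
  v <- matrix(0L, 4, 8)
  ids <- c("a", "ar", "b", "br")
  # pair (a, ar) differs at 2/8 loci, pair (b, br) at 1/8
  v[2, c(1, 5)] <- 1L
  v[4, 3] <- 1L
  m <- mk_fixture(v, ids)
  pairs <- data.frame(a = c("a", "b"), b = c("ar", "br"))
  expect_equal(replicate_distance_sum(m, pairs), 0.25 + 0.125)

  # identical replicates
  m0 <- mk_fixture(matrix(1L, 4, 8), ids)
  expect_equal(replicate_distance_sum(m0, pairs), 0)
  # empty pair set: 0 with warning
  expect_warning(s <- replicate_distance_sum(m, pairs[0, ]), "empty")
  expect_equal(s, 0)
  expect_error(replicate_distance_sum(m, data.frame(a = "a", b = "zzz")), "zzz")
})

test_that("greedy filter removes noise loci and reaches the documented fixtures", {
  # identical replicates everywhere: nothing can lower a zero sum
  ids <- c("a", "ar", "b", "br")
  pairs <- data.frame(a = c("a", "b"), b = c("ar", "br"))
  m0 <- mk_fixture(matrix(rep(c(0L, 1L), each = 20), 4, 10, byrow = TRUE), ids)
  res0 <- greedy_replicate_filter(m0, pairs)
  expect_length(res0$log$removed_locus_ids, 0)
  expect_equal(res0$log$final_sum, res0$log$initial_sum)

  # locus 7 mismatches in both pairs, all others match -> removed, sum 0
  v <- matrix(0L, 4, 10)
  v[c(2, 4), 7] <- 1L
  m1 <- mk_fixture(v, ids)
  res1 <- greedy_replicate_filter(m1, pairs)
  expect_identical(res1$log$removed_locus_ids, "L7")
  expect_equal(res1$log$final_sum, 0)
  expect_false("L7" %in% colnames(res1$matrix))

  # 5 pairs, locus 3 mismatches in exactly 1 pair: removal raises the sum
  ids5 <- as.vector(rbind(paste0("s", 1:5), paste0("s", 1:5, "r")))
  pairs5 <- data.frame(a = paste0("s", 1:5), b = paste0("s", 1:5, "r"))
  v5 <- matrix(0L, 10, 10)
  v5[2, 3] <- 1L  # s1 vs s1r mismatch at L3
  # give other pairs mismatches elsewhere so the sum is not already minimal
  v5[4, 8] <- 1L
  v5[6, 9] <- 1L
  v5[8, 10] <- 1L
  v5[10, 6] <- 1L
  m5 <- mk_fixture(v5, ids5)
  # check against the brute-force definition
  orc <- oracle_greedy(unclass(m5), as.matrix(pairs5))
  res5 <- greedy_replicate_filter(m5, pairs5)
  expect_identical(res5$log$removed_locus_ids, orc$removed)
  expect_equal(res5$log$final_sum, orc$final_sum, tolerance = 1e-12)
})

test_that("greedy filter equals a literal re-application of the rule on random fixtures", {
  for (seed in 1:30) {
    fix <- withr::with_seed(seed, {
      n_loci <- sample(4:12, 1)
      n_pairs <- sample(1:4, 1)
      v <- matrix(rbinom(2 * n_pairs * n_loci, 1, 0.4), 2 * n_pairs, n_loci)
      list(v = v, n_pairs = n_pairs)
    })
    ids <- as.vector(rbind(paste0("s", seq_len(fix$n_pairs)),
                           paste0("s", seq_len(fix$n_pairs), "r")))
    m <- mk_fixture(fix$v, ids)
    pairs <- data.frame(a = paste0("s", seq_len(fix$n_pairs)),
                        b = paste0("s", seq_len(fix$n_pairs), "r"))
    orc <- try(oracle_greedy(unclass(m), as.matrix(pairs)), silent = TRUE)
    res <- try(greedy_replicate_filter(m, pairs), silent = TRUE)
    if (inherits(res, "try-error")) {
      # degenerate-replicates guard; the oracle would have removed all loci
      expect_match(attr(res, "condition")$message, "every locus")
      next
    }
    expect_identical(res$log$removed_locus_ids, orc$removed)
    expect_equal(res$log$final_sum, orc$final_sum, tolerance = 1e-12)
  }
})

test_that("greedy filter never increases the replicate distance sum", {
  for (seed in 31:60) {
    sim <- simulate_paired(sim_params(n_loci_aflp = 60, n_loci_snp = 4,
                                      n_regions = 2, n_per_region = 4,
                                      epsilon = 0.08, n_replicate_pairs = 3,
                                      seed = seed))
    res <- greedy_replicate_filter(sim$aflp$matrix,
                                   replicate_pairs(sim$aflp$meta))
    expect_lte(res$log$final_sum, res$log$initial_sum)
    if (length(res$log$removed_locus_ids) == 0) {
      expect_equal(res$log$final_sum, res$log$initial_sum)
    } else {
      expect_lt(res$log$final_sum, res$log$initial_sum)
    }
    # trajectory non-increasing at accepted removals
    tr <- res$log$trajectory
    acc <- which(tr$removed)
    if (length(acc) > 1) {
      expect_true(all(diff(tr$sum_after[acc]) <= 1e-12))
    }
  }
})

test_that("fraction of removed loci grows with simulated scoring noise", {
  eps <- c(0, 0.02, 0.05, 0.1)
  frac <- vapply(eps, function(e) {
    sim <- simulate_paired(sim_params(n_loci_aflp = 1000, n_loci_snp = 4,
                                      epsilon = e, n_replicate_pairs = 3,
                                      seed = 77))
    res <- greedy_replicate_filter(sim$aflp$matrix,
                                   replicate_pairs(sim$aflp$meta))
    length(res$log$removed_locus_ids) / 1000
  }, numeric(1))
  expect_equal(frac[1], 0)  # noiseless replicates are identical
  expect_true(all(diff(frac) > 0))
})

test_that("outlier screen finds planted outliers and flags bad combos", {
  # 3 regions x 10 individuals, 4 combos of 60 loci; each region a tight
  # cluster around its own base profile (12% flip noise)
  set.seed(42)
  n_per <- 10
  regs <- c("A1", "A2", "P")
  regions <- rep(regs, each = n_per)
  ids <- paste0(regions, "_", seq_along(regions))
  combos <- paste0("PC", 1:4)
  mats <- lapply(combos, function(cb) {
    base <- matrix(rbinom(3 * 60, 1, 0.5), 3, 60, dimnames = list(regs, NULL))
    v <- base[regions, ]
    v <- abs(v - matrix(rbinom(length(v), 1, 0.12), nrow(v), ncol(v)))
    dimnames(v) <- list(ids, paste0(cb, "_L", 1:60))
    v
  })
  # individual-level plant: ids[1] inverted in combos 1-3 (3/4 > 50%)
  for (k in 1:3) mats[[k]][1, ] <- 1L - mats[[k]][1, ]
  # combo-level plant: 6 scattered random profiles in PC4 (> 10% outside)
  for (i in c(5, 8, 12, 15, 22, 25)) mats[[4]][i, ] <- rbinom(60, 1, 0.5)
  mats <- setNames(lapply(mats, aflp_matrix), combos)
  meta <- sample_metadata(ids, regions)
  rep_result <- nmds_outlier_screen(mats, meta, seed = 7, nmds_restarts = 5)
  ind <- rep_result$individuals
  expect_true(ind$excluded[ind$sample == ids[1]])
  expect_gt(ind$outside_fraction[ind$sample == ids[1]], 0.5)
  # direct ellipse-test verification of the planted individual's flags
  expect_identical(unname(rep_result$outside[ids[1], ]),
                   c(TRUE, TRUE, TRUE, FALSE))

  # determinism under a fixed seed
  rep2 <- nmds_outlier_screen(mats, meta, seed = 7, nmds_restarts = 5)
  expect_identical(rep_result$outside, rep2$outside)
  expect_identical(rep_result$individuals, rep2$individuals)

  # combo exclusion is exactly "outside fraction > threshold"
  cb <- rep_result$combos
  expect_true(cb$excluded[cb$combo == "PC4"])
  expect_gt(cb$outside_fraction[cb$combo == "PC4"], 0.1)
  expect_identical(cb$excluded, cb$outside_fraction > 0.1)
  # direct fraction computation from the outside matrix
  expect_equal(cb$outside_fraction, unname(colMeans(rep_result$outside)),
               tolerance = 1e-12)
})

test_that("coincident individuals produce no exclusions; tiny regions are unassessable", {
  ids <- paste0("s", 1:9)
  regions <- rep(c("A1", "A2", "P"), each = 3)
  v <- matrix(rep(c(1L, 0L), length.out = 9 * 12), 9, 12, byrow = TRUE)
  v[] <- rep(c(1L, 0L), each = 6)  # all samples identical profiles
  m <- mk_fixture(v, ids)
  meta <- sample_metadata(ids, regions)
  sr <- suppressWarnings(nmds_outlier_screen(m, meta, seed = 1,
                                             nmds_restarts = 2))
  expect_false(any(sr$individuals$excluded, na.rm = TRUE))
  expect_false(any(sr$combos$excluded, na.rm = TRUE))

  # a region with < 3 members stays NA (unassessable), never "outside"
  meta2 <- sample_metadata(ids, c(rep("A1", 7), "tiny", "tiny"))
  sim <- simulate_paired(sim_params(n_regions = 1, n_per_region = 9,
                                    n_loci_aflp = 24, n_loci_snp = 4,
                                    n_replicate_pairs = 0, seed = 3))
  m2 <- sim$aflp$matrix
  rownames(m2) <- ids
  m2 <- aflp_matrix(unclass(m2), primer_combos(m2))
  sr2 <- nmds_outlier_screen(m2, meta2, seed = 2, nmds_restarts = 2)
  expect_true(all(is.na(sr2$outside[c("s8", "s9"), ])))
})
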