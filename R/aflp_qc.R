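#' Sum of replicate p-distances
#'
#' Total p-distance over all blind-replicate pairs: the quantity the
#' replicate-guided locus filter minimizes. Perfectly reproducible scoring
#' gives 0.
#'
#' @param m an [aflp_matrix()].
#' @param pairs two-column data.frame/matrix of sample-id pairs (e.g. from
#'   [replicate_pairs()]).
#' @return non-negative real; 0 (with a warning) for an empty pair set.
#' @export
replicate_distance_sum <- function(m, pairs) {
  stopifnot(inherits(m, "aflp_matrix"))
  if (ncol(m) < 1) stop("matrix has no loci")
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0) {
    warning("empty replicate pair set: sum is 0 by convention")
    return(0)
  }
  unknown <- setdiff(c(pairs), rownames(m))
  if (length(unknown) > 0) {
    stop("pair member(s) not in the matrix: ", paste(unknown, collapse = ", "))
  }
  sum(apply(pairs, 1, function(p) p_distance(m[p[1], ], m[p[2], ])))
}

#' Replicate-guided greedy locus filter
#'
#' Single sequential pass over loci in stored order. At each locus the
#' locus is tentatively removed and the replicate p-distance sum is
#' recomputed on the remaining loci (the p-distance denominator is the
#' current locus count, so removing a locus on which replicates agree
#' *increases* the sum). The removal is accepted iff the new sum is
#' strictly lower than the current one; ties keep the locus. Loci whose
#' mismatches inflate the replicate distance are thereby stripped as
#' scoring noise.
#'
#' The comparison is done in exact integer arithmetic
#' (`sum_mismatches_new * L_old < sum_mismatches_old * L_new`), so
#' floating-point rounding can never flip a tie.
#'
#' @param m an [aflp_matrix()] with >= 2 loci.
#' @param pairs non-empty two-column data.frame/matrix of replicate
#'   sample-id pairs.
#' @param iterate repeat the pass until no locus is removed (default
#'   `FALSE`: one pass, matching the one-sweep description of the original
#'   procedure).
#' @return a list with `matrix` (the filtered [aflp_matrix()]) and `log`,
#'   a `qc_log` holding `removed_locus_ids`, the per-locus decision
#'   `trajectory` (data.frame: locus, pass, sum_if_removed, removed,
#'   sum_after), `initial_sum` and `final_sum`.
#' @export
greedy_replicate_filter <- function(m, pairs, iterate = FALSE) {
  stopifnot(inherits(m, "aflp_matrix"))
  if (ncol(m) < 2) stop("need at least 2 loci")
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0) stop("need at least one replicate pair")
  unknown <- setdiff(c(pairs), rownames(m))
  if (length(unknown) > 0) {
    stop("pair member(s) not in the matrix: ", paste(unknown, collapse = ", "))
  }
  x <- unclass(m)
  # pair x locus mismatch indicators; everything below is integer-exact
  mis <- t(apply(pairs, 1, function(p) as.integer(x[p[1], ] != x[p[2], ])))
  if (nrow(pairs) == 1) mis <- matrix(mis, nrow = 1)
  colnames(mis) <- colnames(x)

  active <- rep(TRUE, ncol(x))
  names(active) <- colnames(x)
  per_pair <- rowSums(mis)
  l_act <- ncol(x)
  initial_sum <- sum(per_pair) / l_act
  trajectory <- list()
  removed <- character(0)

  pass <- 0L
  repeat {
    pass <- pass + 1L
    removed_this_pass <- 0L
    for (j in seq_len(ncol(x))) {
      if (!active[j]) next
      l_new <- l_act - 1L
      if (l_new == 0L) {
        if (sum(per_pair) == 0) next  # nothing to improve; keep the locus
        stop("filter would remove every locus: replicates disagree ",
             "pervasively, inspect the replicate samples before filtering")
      }
      new_tot <- sum(per_pair) - sum(mis[, j])
      # accept iff new_tot / l_new < old_tot / l_act  (exact in integers)
      accept <- new_tot * l_act < sum(per_pair) * l_new
      sum_if_removed <- new_tot / l_new
      if (accept) {
        active[j] <- FALSE
        per_pair <- per_pair - mis[, j]
        l_act <- l_new
        removed <- c(removed, colnames(x)[j])
        removed_this_pass <- removed_this_pass + 1L
      }
      trajectory[[length(trajectory) + 1L]] <- data.frame(
        locus = colnames(x)[j], pass = pass,
        sum_if_removed = sum_if_removed, removed = accept,
        sum_after = sum(per_pair) / l_act, stringsAsFactors = FALSE
      )
    }
    if (!iterate || removed_this_pass == 0L) break
  }

  log <- structure(list(
    removed_locus_ids = removed,
    trajectory = do.call(rbind, trajectory),
    initial_sum = initial_sum,
    final_sum = sum(per_pair) / l_act,
    passes = pass
  ), class = "qc_log")
  list(matrix = m[, which(active)], log = log)
}

#' @export
print.qc_log <- function(x, ...) {
  cat(sprintf(
    "Replicate-guided locus filter: %d locus/loci removed in %d pass(es)\n",
    length(x$removed_locus_ids), x$passes
  ))
  cat(sprintf("  replicate p-distance sum: %.5f -> %.5f\n",
              x$initial_sum, x$final_sum))
  invisible(x)
}

# Mahalanobis ellipse membership at the given coverage; falls back to a
# pseudo-inverse for (near-)singular covariances, where coincident points
# sit at the center and count as inside.
ellipse_inside <- function(pts, coverage) {
  ctr <- colMeans(pts)
  s <- cov(pts)
  md2 <- tryCatch(
    mahalanobis(pts, ctr, s),
    error = function(e) {
      centered <- sweep(pts, 2, ctr)
      rowSums((centered %*% MASS::ginv(s)) * centered)
    }
  )
  md2 <- pmax(md2, 0)
  list(inside = md2 <= qchisq(coverage, df = ncol(pts)) + 1e-8,
       center = ctr, cov = s)
}

#' Ordination-based outlier screen for AFLP individuals and primer combos
#'
#' Per primer combination: Jaccard distances are computed, ordinated with
#' 2-dimensional NMDS, and a `coverage` (default 90%) quantile ellipse
#' (chi-square quantile on the sample covariance of the ordination
#' coordinates) is drawn for each region. An individual is "outside" when
#' it falls outside its own region's ellipse. Individuals outside in more
#' than `indiv_threshold` of the combinations are flagged for exclusion;
#' combinations in which more than `combo_threshold` of the individuals
#' are outside are flagged for exclusion. Individual flags are assigned
#' first; individual outside-fractions are then recomputed once over the
#' retained combinations (no fixpoint iteration).
#'
#' Regions with fewer than 3 members in a combination have no defined
#' ellipse: their samples are marked unassessable (`NA`) and never counted
#' as outside.
#'
#' @param x an [aflp_matrix()] (split internally by primer combination) or
#'   a named list of `aflp_matrix` objects over the same samples.
#' @param meta a [sample_metadata()] covering all samples.
#' @param coverage ellipse coverage probability (default 0.90).
#' @param indiv_threshold exclusion threshold on an individual's outside
#'   fraction across combinations (default 0.5).
#' @param combo_threshold exclusion threshold on a combination's fraction
#'   of outside individuals (default 0.1).
#' @param per_region one ellipse per region (default) or a single global
#'   ellipse over all samples.
#' @param nmds_restarts NMDS restarts per combination.
#' @param seed RNG seed; the screen is deterministic given a seed.
#' @return an object of class `screen_report`: `outside` (samples x combos
#'   logical matrix, `NA` = unassessable), `individuals` (data.frame:
#'   sample, outside_fraction, excluded, outside_fraction_retained),
#'   `combos` (data.frame: combo, outside_fraction, excluded),
#'   `ellipses`, and the thresholds used.
#' @export
nmds_outlier_screen <- function(x, meta, coverage = 0.90,
                                indiv_threshold = 0.5,
                                combo_threshold = 0.1,
                                per_region = TRUE,
                                nmds_restarts = 10, seed = NULL) {
  mats <- if (inherits(x, "aflp_matrix")) split_by_combo(x) else x
  stopifnot(is.list(mats), length(mats) > 0)
  samples <- rownames(mats[[1]])
  for (m in mats) {
    if (!identical(rownames(m), samples)) {
      stop("all combination matrices must cover the same samples, in order")
    }
  }
  groups <- region_groups(meta, samples)
  outside <- matrix(NA, length(samples), length(mats),
                    dimnames = list(samples, names(mats)))
  ellipses <- list()
  for (ci in seq_along(mats)) {
    combo_seed <- if (is.null(seed)) NULL else derive_seed(seed, ci)
    d <- suppressWarnings(jaccard_matrix(mats[[ci]]))
    ord <- nmds(d, k = 2, restarts = nmds_restarts, seed = combo_seed)
    pts <- ord$points
    blocks <- if (per_region) split(samples, groups) else list(all = samples)
    ell <- list()
    for (bn in names(blocks)) {
      members <- blocks[[bn]]
      if (length(members) < 3) next  # unassessable, stays NA
      res <- ellipse_inside(pts[members, , drop = FALSE], coverage)
      outside[members, ci] <- !res$inside
      ell[[bn]] <- list(center = res$center, cov = res$cov,
                        coverage = coverage)
    }
    ellipses[[names(mats)[ci]]] <- ell
  }

  indiv_frac <- rowMeans(outside, na.rm = TRUE)
  indiv_frac[is.nan(indiv_frac)] <- NA
  excluded_indiv <- !is.na(indiv_frac) & indiv_frac > indiv_threshold
  combo_frac <- colMeans(outside, na.rm = TRUE)
  combo_frac[is.nan(combo_frac)] <- NA
  excluded_combo <- !is.na(combo_frac) & combo_frac > combo_threshold
  retained <- which(!excluded_combo)
  frac_retained <- if (length(retained) > 0) {
    f <- rowMeans(outside[, retained, drop = FALSE], na.rm = TRUE)
    f[is.nan(f)] <- NA
    f
  } else {
    rep(NA_real_, length(samples))
  }

  structure(list(
    outside = outside,
    individuals = data.frame(
      sample = samples, outside_fraction = unname(indiv_frac),
      excluded = unname(excluded_indiv),
      outside_fraction_retained = unname(frac_retained),
      stringsAsFactors = FALSE
    ),
    combos = data.frame(
      combo = names(mats), outside_fraction = unname(combo_frac),
      excluded = unname(excluded_combo), stringsAsFactors = FALSE
    ),
    ellipses = ellipses,
    coverage = coverage, indiv_threshold = indiv_threshold,
    combo_threshold = combo_threshold, per_region = per_region
  ), class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf(
    "NMDS outlier screen (%d%% ellipses, %s): %d individual(s), %d combo(s) flagged\n",
    round(100 * x$coverage),
    if (x$per_region) "per region" else "global",
    sum(x$individuals$excluded, na.rm = TRUE),
    sum(x$combos$excluded, na.rm = TRUE)
  ))
  invisible(x)
}
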