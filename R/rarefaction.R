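#' Randomly subsample loci without replacement
#'
#' Draws a uniformly random `n`-subset of loci (no locus twice within a
#' draw); the sample set and the original relative locus order are
#' preserved.
#'
#' @param g a [genotype_matrix()].
#' @param n number of loci to keep, `1 <= n <= ncol(g)`.
#' @param seed optional RNG seed.
#' @return a [genotype_matrix()] with `n` loci.
#' @export
subsample_loci <- function(g, n, seed = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 || n > ncol(g)) {
    stop(sprintf("`n` must be in [1, %d], got %s", ncol(g), n))
  }
  idx <- with_seed(seed, sort(sample.int(ncol(g), as.integer(n))))
  g[, idx]
}

#' Locus rarefaction of a SNP matrix
#'
#' Measures how the regional signal of a SNP dataset depends on the number
#' of loci. For each step `s` in `step, 2*step, ...` (plus any
#' `extra_steps`, e.g. an AFLP-matched locus count), `reps` independent
#' random locus subsets of size `s` are drawn; per subset the Gower
#' distance matrix is computed, ANOSIM Global R (with regions as groups)
#' and the Mantel correlation of the subset matrix with the full-matrix
#' Gower distances are inferred, and each test is flagged significant at
#' `alpha`.
#'
#' Degenerate subsets — a sample pair with no jointly scored polymorphic
#' locus, which can happen at small `s` with heavy missing data — are
#' recorded as not-applicable rows (statistics `NA`, reason filled in),
#' never silently dropped.
#'
#' Each (step, replicate) record runs under a seed substream derived
#' deterministically from `seed`, so the full result is reproducible and
#' any single record can be recomputed in isolation.
#'
#' @param g a [genotype_matrix()].
#' @param groups region labels (named vector or vector in row order).
#' @param step locus-count step size (default 50).
#' @param reps replicates per step (default 50).
#' @param n_perm permutations for the per-replicate ANOSIM and Mantel
#'   tests (default 999; the summary statistics, not the p-values, are the
#'   primary read-out, so a modest count keeps the sweep tractable).
#' @param alpha significance level for the per-record flags.
#' @param extra_steps additional locus counts to include (sorted in, e.g.
#'   an AFLP-matched count that is not a multiple of `step`).
#' @param seed master RNG seed.
#' @return an object of class `rarefaction_result`: `records` (one row
#'   per step x replicate), `summaries` (per-step mean/sd of Global R and
#'   Mantel r, plus not-applicable counts), `steps`, `full_R` (ANOSIM on
#'   the full matrix), and the parameters.
#' @export
rarefaction_curves <- function(g, groups, step = 50, reps = 50,
                               n_perm = 999, alpha = 0.05,
                               extra_steps = integer(0), seed = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (step < 1) stop("`step` must be >= 1")
  if (reps < 1) stop("`reps` must be >= 1")
  total <- ncol(g)
  if (total < step) stop("matrix has fewer loci than one step")
  steps <- sort(unique(c(seq(step, total, by = step),
                         extra_steps[extra_steps >= 1 & extra_steps <= total])))
  full_d <- gower_matrix(g)
  groups <- align_groups(groups, rownames(full_d))
  full_R <- anosim(full_d, groups, n_perm = n_perm,
                   seed = if (is.null(seed)) NULL else derive_seed(seed, 0, 0))

  records <- vector("list", length(steps) * reps)
  ri <- 0L
  for (si in seq_along(steps)) {
    s <- steps[si]
    for (rep_i in seq_len(reps)) {
      rec_seed <- if (is.null(seed)) NULL else derive_seed(seed, si, rep_i)
      sub <- subsample_loci(g, s, seed = rec_seed)
      rec <- data.frame(step = s, rep = rep_i, global_R = NA_real_,
                        anosim_p = NA_real_, anosim_significant = NA,
                        mantel_r_vs_full = NA_real_, mantel_p = NA_real_,
                        mantel_significant = NA, note = "",
                        stringsAsFactors = FALSE)
      d <- tryCatch(gower_matrix(sub), error = function(e) e)
      if (inherits(d, "error")) {
        rec$note <- paste0("not applicable: ", conditionMessage(d))
      } else {
        an <- tryCatch(
          anosim(d, groups, n_perm = n_perm,
                 seed = if (is.null(rec_seed)) NULL else derive_seed(rec_seed, 1)),
          error = function(e) e
        )
        if (inherits(an, "error")) {
          rec$note <- paste0("not applicable: ", conditionMessage(an))
        } else {
          rec$global_R <- an$statistic
          rec$anosim_p <- an$p_value
          rec$anosim_significant <- an$p_value <= alpha
          mt <- tryCatch(
            mantel(d, full_d, n_perm = n_perm,
                   seed = if (is.null(rec_seed)) NULL else derive_seed(rec_seed, 2)),
            error = function(e) e
          )
          if (inherits(mt, "error")) {
            rec$note <- paste0("mantel not applicable: ", conditionMessage(mt))
          } else {
            rec$mantel_r_vs_full <- mt$r
            rec$mantel_p <- mt$p_value
            rec$mantel_significant <- mt$p_value <= alpha
          }
        }
      }
      ri <- ri + 1L
      records[[ri]] <- rec
    }
  }
  records <- do.call(rbind, records)

  summaries <- do.call(rbind, lapply(split(records, records$step), function(df) {
    data.frame(
      step = df$step[1],
      n_applicable = sum(!is.na(df$global_R)),
      n_not_applicable = sum(is.na(df$global_R)),
      mean_global_R = mean(df$global_R, na.rm = TRUE),
      sd_global_R = sd(df$global_R, na.rm = TRUE),
      mean_mantel_r = mean(df$mantel_r_vs_full, na.rm = TRUE),
      sd_mantel_r = sd(df$mantel_r_vs_full, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }))
  rownames(summaries) <- NULL

  structure(list(
    records = records, summaries = summaries, steps = steps,
    full_R = full_R,
    params = list(step = step, reps = reps, n_perm = n_perm, alpha = alpha,
                  seed = seed, n_loci = total)
  ), class = "rarefaction_result")
}

#' @export
print.rarefaction_result <- function(x, ...) {
  cat(sprintf(
    "Locus rarefaction: %d steps x %d replicates on %d loci (full Global R = %.3f)\n",
    length(x$steps), x$params$reps, x$params$n_loci, x$full_R$statistic
  ))
  print(head(x$summaries, 5))
  if (nrow(x$summaries) > 5) cat("  ...\n")
  invisible(x)
}

#' @export
plot.rarefaction_result <- function(x, which = c("global_R", "mantel_r"), ...) {
  which <- match.arg(which)
  col <- if (which == "global_R") "global_R" else "mantel_r_vs_full"
  mcol <- if (which == "global_R") "mean_global_R" else "mean_mantel_r"
  plot(x$records$step, x$records[[col]], pch = 16, cex = 0.4,
       col = "#00000040", xlab = "number of loci",
       ylab = if (which == "global_R") "ANOSIM Global R" else
         "Mantel r vs full matrix", ...)
  lines(x$summaries$step, x$summaries[[mcol]], col = "red", lwd = 2)
  invisible(x)
}

#' AFLP reference overlay for rarefaction plots
#'
#' Computes the AFLP dataset's own Global R and the distribution, over
#' `reps` random draws, of the Mantel correlation between the AFLP
#' distance matrix and a SNP Gower matrix downsampled to the AFLP locus
#' count — the reference points overlaid on rarefaction curves to compare
#' a real AFLP dataset with an equally sized random SNP subset.
#'
#' AFLP and SNP samples must already be expressed on shared labels (join
#' AFLP/SNP individuals via their metadata `match_key` beforehand).
#'
#' @param aflp_dist AFLP Jaccard distance matrix (labelled).
#' @param aflp_groups region labels for the AFLP samples.
#' @param g SNP [genotype_matrix()] over the same labels.
#' @param n_loci_aflp the AFLP locus count to downsample to; must not
#'   exceed `ncol(g)`.
#' @param reps number of random subsets (default 50).
#' @param n_perm permutations per test.
#' @param seed master RNG seed.
#' @return an object of class `aflp_overlay`: `n_loci`, `global_R`,
#'   `anosim_p`, `mantel_r` (length-`reps` vector), `mantel_p`.
#' @export
aflp_overlay <- function(aflp_dist, aflp_groups, g, n_loci_aflp,
                         reps = 50, n_perm = 999, seed = NULL) {
  ad <- as_distance_matrix(aflp_dist, "aflp_dist")
  stopifnot(inherits(g, "genotype_matrix"))
  unmatched <- c(setdiff(rownames(ad), rownames(g)),
                 setdiff(rownames(g), rownames(ad)))
  if (length(unmatched) > 0) {
    stop("samples not shared between AFLP and SNP data: ",
         paste(unique(unmatched), collapse = ", "))
  }
  if (n_loci_aflp > ncol(g)) {
    stop("AFLP locus count exceeds the SNP locus count")
  }
  g <- g[rownames(ad), ]
  groups <- align_groups(aflp_groups, rownames(ad))
  an <- anosim(ad, groups, n_perm = n_perm,
               seed = if (is.null(seed)) NULL else derive_seed(seed, 0))
  mr <- mp <- numeric(reps)
  for (i in seq_len(reps)) {
    rs <- if (is.null(seed)) NULL else derive_seed(seed, i)
    d <- gower_matrix(subsample_loci(g, n_loci_aflp, seed = rs))
    mt <- mantel(ad, d, n_perm = n_perm,
                 seed = if (is.null(rs)) NULL else derive_seed(rs, 1))
    mr[i] <- mt$r
    mp[i] <- mt$p_value
  }
  structure(list(n_loci = n_loci_aflp, global_R = an$statistic,
                 anosim_p = an$p_value, mantel_r = mr, mantel_p = mp),
            class = "aflp_overlay")
}

#' @export
print.aflp_overlay <- function(x, ...) {
  cat(sprintf(
    "AFLP overlay at %d loci: Global R = %.3f%s; Mantel r vs downsampled SNP: mean %.3f (sd %.3f, %d draws)\n",
    x$n_loci, x$global_R, p_stars(x$anosim_p),
    mean(x$mantel_r), sd(x$mantel_r), length(x$mantel_r)
  ))
  invisible(x)
}
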