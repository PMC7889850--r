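#' Run the full AFLP-vs-SNP comparison pipeline
#'
#' Orchestrates: AFLP replicate-guided locus filtering (and optionally the
#' NMDS outlier screen), dropping of blind replicates, Jaccard (AFLP) and
#' Gower (SNP) distance matrices over the samples matched via the metadata
#' `match_key`, ANOSIM per marker type with regions as groups, the Mantel
#' test between the two matrices, and optionally a locus rarefaction of
#' the SNP matrix with an AFLP overlay at the AFLP locus count. Emits a
#' Table-style summary with 0.05/0.01 significance stars.
#'
#' @param config a named list, or the path of a JSON file holding one,
#'   with entries:
#'   \describe{
#'     \item{aflp}{path of the binary AFLP marker table}
#'     \item{snp}{path of the SNP matrix}
#'     \item{snp_format}{`"dosage_table"` (default) or `"structure_tworow"`}
#'     \item{aflp_meta, snp_meta}{metadata CSV paths (`meta` may be given
#'       once for both)}
#'     \item{max_missing}{per-locus missingness filter for the SNP matrix
#'       (default 0.75)}
#'     \item{screen}{logical: run the NMDS outlier screen (default FALSE)}
#'     \item{anosim_perms, mantel_perms}{permutation counts (default 9999)}
#'     \item{rarefaction}{optional list(step, reps, n_perm) enabling the
#'       rarefaction sweep}
#'     \item{seed}{master seed (default 1)}
#'     \item{out_dir}{optional output directory for summary.json,
#'       summary.txt and per-stage artifacts}
#'   }
#' @return an object of class `comparison_summary` (also written to
#'   `out_dir` when given).
#' @export
run_compare <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  need <- c("aflp", "snp")
  miss <- setdiff(need, names(config))
  if (length(miss) > 0) stop("config is missing: ", paste(miss, collapse = ", "))
  seed <- as.integer(config$seed %||% 1)
  anosim_perms <- config$anosim_perms %||% 9999
  mantel_perms <- config$mantel_perms %||% 9999

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
    out
  }

  aflp <- stage("read_aflp", read_binary_marker_table(config$aflp))
  snp <- stage("read_snp", read_genotype_table(
    config$snp, format = config$snp_format %||% "dosage_table"))
  aflp_meta <- stage("read_meta", read_sample_metadata(
    config$aflp_meta %||% config$meta))
  snp_meta <- if (!is.null(config$snp_meta)) {
    read_sample_metadata(config$snp_meta)
  } else {
    aflp_meta
  }

  aflp_loci_before <- ncol(aflp)
  snp_loci_before <- ncol(snp)
  snp <- stage("missingness_filter",
               filter_loci_by_missingness(snp, config$max_missing %||% 0.75))

  pairs <- replicate_pairs(aflp_meta)
  pairs <- pairs[pairs$a %in% rownames(aflp) & pairs$b %in% rownames(aflp), ,
                 drop = FALSE]
  qc <- if (nrow(pairs) > 0) {
    stage("replicate_filter", greedy_replicate_filter(aflp, pairs))
  } else {
    list(matrix = aflp, log = NULL)
  }
  aflp <- qc$matrix

  screen <- NULL
  if (isTRUE(config$screen)) {
    screen <- stage("outlier_screen", nmds_outlier_screen(
      aflp, aflp_meta, seed = derive_seed(seed, 11)))
    drop_ind <- screen$individuals$sample[
      !is.na(screen$individuals$excluded) & screen$individuals$excluded]
    drop_combo <- screen$combos$combo[
      !is.na(screen$combos$excluded) & screen$combos$excluded]
    keep_s <- setdiff(rownames(aflp), drop_ind)
    keep_l <- names(primer_combos(aflp))[
      !(primer_combos(aflp) %in% drop_combo)]
    if (length(keep_l) == 0) stop("outlier screen excluded every primer combination")
    aflp <- aflp[keep_s, keep_l]
  }

  # drop blind replicates: technical duplicates never enter the statistics
  reps_ids <- aflp_meta$sample[!is.na(aflp_meta$replicate_of)]
  aflp <- aflp[setdiff(rownames(aflp), reps_ids), ]

  # join AFLP and SNP individuals on match_key
  akey <- setNames(aflp_meta$match_key, aflp_meta$sample)[rownames(aflp)]
  skey <- setNames(snp_meta$match_key, snp_meta$sample)[rownames(snp)]
  shared <- intersect(akey[!is.na(akey)], skey[!is.na(skey)])
  if (length(shared) < 3) {
    stop("fewer than 3 samples joinable via match_key between AFLP and SNP data")
  }
  aflp_m <- aflp[match(shared, akey), ]
  rownames(aflp_m) <- shared
  snp_m <- snp[match(shared, skey), ]
  rownames(snp_m) <- shared
  regs <- region_groups(aflp_meta, samples = names(akey))
  groups <- setNames(unname(regs[match(shared, akey)]), shared)

  d_aflp <- stage("jaccard", suppressWarnings(jaccard_matrix(aflp_m)))
  d_snp <- stage("gower", gower_matrix(snp_m))

  an_aflp <- stage("anosim_aflp", anosim(d_aflp, groups, n_perm = anosim_perms,
                                         seed = derive_seed(seed, 21)))
  an_snp <- stage("anosim_snp", anosim(d_snp, groups, n_perm = anosim_perms,
                                       seed = derive_seed(seed, 22)))
  mt <- stage("mantel", mantel(d_aflp, d_snp, n_perm = mantel_perms,
                               seed = derive_seed(seed, 23)))

  rarefy <- NULL
  overlay <- NULL
  if (!is.null(config$rarefaction)) {
    rc <- config$rarefaction
    rarefy <- stage("rarefaction", rarefaction_curves(
      snp_m, groups,
      step = rc$step %||% 50, reps = rc$reps %||% 50,
      n_perm = rc$n_perm %||% 999,
      extra_steps = ncol(aflp_m), seed = derive_seed(seed, 31)))
    overlay <- stage("aflp_overlay", aflp_overlay(
      d_aflp, groups, snp_m, ncol(aflp_m),
      reps = rc$reps %||% 50, n_perm = rc$n_perm %||% 999,
      seed = derive_seed(seed, 32)))
  }

  summary <- structure(list(
    n_samples = length(shared),
    aflp_loci = c(before = aflp_loci_before, after = ncol(aflp_m)),
    snp_loci = c(before = snp_loci_before, after = ncol(snp_m)),
    aflp_global_R = an_aflp$statistic, aflp_anosim_p = an_aflp$p_value,
    snp_global_R = an_snp$statistic, snp_anosim_p = an_snp$p_value,
    mantel_r = mt$r, mantel_p = mt$p_value,
    qc_log = qc$log, screen = screen,
    rarefaction = rarefy, overlay = overlay,
    manifest = list(config = config[!vapply(config, is.list, logical(1))],
                    seed = seed,
                    package_version = as.character(utils::packageVersion("aflprad")))
  ), class = "comparison_summary")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      summary_to_list(summary),
      file.path(config$out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
    )
    writeLines(format_summary(summary),
               file.path(config$out_dir, "summary.txt"))
    write_binary_marker_table(aflp_m,
                              file.path(config$out_dir, "aflp_filtered.tsv"))
    write_distance_matrix(d_aflp, file.path(config$out_dir, "dist_aflp.csv"))
    write_distance_matrix(d_snp, file.path(config$out_dir, "dist_snp.csv"))
  }
  summary
}

summary_to_list <- function(s) {
  list(
    n_samples = s$n_samples,
    aflp_loci_before = unname(s$aflp_loci["before"]),
    aflp_loci_after = unname(s$aflp_loci["after"]),
    snp_loci_before = unname(s$snp_loci["before"]),
    snp_loci_after = unname(s$snp_loci["after"]),
    aflp_global_R = s$aflp_global_R, aflp_anosim_p = s$aflp_anosim_p,
    snp_global_R = s$snp_global_R, snp_anosim_p = s$snp_anosim_p,
    mantel_r = s$mantel_r, mantel_p = s$mantel_p,
    removed_loci = if (!is.null(s$qc_log)) s$qc_log$removed_locus_ids else character(0),
    manifest = s$manifest
  )
}

format_summary <- function(s) {
  c(
    "AFLP vs SNP comparison summary",
    "------------------------------",
    sprintf("matched samples:       %d", s$n_samples),
    sprintf("AFLP loci (pre/post):  %d / %d",
            s$aflp_loci["before"], s$aflp_loci["after"]),
    sprintf("SNP loci (pre/post):   %d / %d",
            s$snp_loci["before"], s$snp_loci["after"]),
    sprintf("AFLP Global R:         %.3f%s (p = %.4g)",
            s$aflp_global_R, p_stars(s$aflp_anosim_p), s$aflp_anosim_p),
    sprintf("SNP Global R:          %.3f%s (p = %.4g)",
            s$snp_global_R, p_stars(s$snp_anosim_p), s$snp_anosim_p),
    sprintf("AFLP-SNP Mantel r:     %.3f%s (p = %.4g)",
            s$mantel_r, p_stars(s$mantel_p), s$mantel_p),
    "significance: ** p <= 0.01, * p <= 0.05"
  )
}

#' @export
print.comparison_summary <- function(x, ...) {
  writeLines(format_summary(x))
  invisible(x)
}
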