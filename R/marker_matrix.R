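#' Binary AFLP marker matrix
#'
#' A samples x loci presence/absence (0/1) matrix with a primer-combination
#' tag attached to every locus. AFLP fingerprinting scores fragments per
#' selective primer pair ("primer combination"); the tag records which pair
#' a locus came from so quality screening can work combination-wise.
#'
#' The object is a plain integer matrix of class `aflp_matrix` with a
#' `primer_combo` attribute (named character vector over loci). Subsetting
#' with `[` keeps the class and the tags of the retained loci.
#'
#' @param values integer/numeric matrix with entries 0/1; rownames are
#'   sample ids, colnames are locus ids.
#' @param primer_combo optional named character vector mapping locus id to
#'   combination tag; a single default tag `"PC1"` is used when omitted.
#' @return an `aflp_matrix`.
#' @examples
#' m <- aflp_matrix(matrix(c(1, 0, 0, 1), 2, 2,
#'   dimnames = list(c("a", "b"), c("L1", "L2"))))
#' primer_combos(m)
#' @export
aflp_matrix <- function(values, primer_combo = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry sample ids (rownames) and locus ids (colnames)")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicate locus ids")
  bad <- which(!(values %in% c(0L, 1L)) | is.na(values))
  if (length(bad) > 0) {
    i <- ((bad[1] - 1) %% nrow(values)) + 1
    j <- ((bad[1] - 1) %/% nrow(values)) + 1
    stop(sprintf(
      "entry for sample '%s', locus '%s' is not 0/1 (value: %s)",
      rownames(values)[i], colnames(values)[j], values[bad[1]]
    ))
  }
  storage.mode(values) <- "integer"
  if (is.null(primer_combo)) {
    primer_combo <- setNames(rep("PC1", ncol(values)), colnames(values))
  }
  if (is.null(names(primer_combo))) names(primer_combo) <- colnames(values)
  miss <- setdiff(colnames(values), names(primer_combo))
  if (length(miss) > 0) {
    stop("loci without a primer-combination tag: ", paste(miss, collapse = ", "))
  }
  structure(values,
    primer_combo = primer_combo[colnames(values)],
    class = c("aflp_matrix", class(values))
  )
}

#' @export
`[.aflp_matrix` <- function(x, i, j, drop = FALSE) {
  combo <- attr(x, "primer_combo")
  m <- unclass(x)
  attr(m, "primer_combo") <- NULL
  if (missing(i)) i <- seq_len(nrow(m))
  if (missing(j)) j <- seq_len(ncol(m))
  out <- m[i, j, drop = FALSE]
  aflp_matrix(out, combo[colnames(out)])
}

#' @rdname aflp_matrix
#' @param x an `aflp_matrix`.
#' @export
primer_combos <- function(x) {
  stopifnot(inherits(x, "aflp_matrix"))
  attr(x, "primer_combo")
}

#' Split an AFLP matrix into one matrix per primer combination
#'
#' @param x an `aflp_matrix`.
#' @return named list of `aflp_matrix`, one per combination tag, in first
#'   appearance order.
#' @export
split_by_combo <- function(x) {
  combo <- primer_combos(x)
  tags <- unique(unname(combo))
  setNames(lapply(tags, function(tg) x[, names(combo)[combo == tg]]), tags)
}

#' @export
print.aflp_matrix <- function(x, ...) {
  cat(sprintf(
    "AFLP binary marker matrix: %d samples x %d loci (%d primer combination%s)\n",
    nrow(x), ncol(x), length(unique(primer_combos(x))),
    if (length(unique(primer_combos(x))) == 1) "" else "s"
  ))
  invisible(x)
}

#' SNP dosage genotype matrix
#'
#' A samples x loci matrix of diploid dosages (0, 1, 2 copies of the
#' reference allele) with `NA` as the missing-data sentinel. `NA` is never
#' conflated with dosage 0.
#'
#' @param values matrix with entries in `{0, 1, 2, NA}`; dimnames carry
#'   sample and locus ids.
#' @return an integer matrix of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry sample ids (rownames) and locus ids (colnames)")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicate locus ids")
  ok <- is.na(values) | values %in% c(0L, 1L, 2L)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    i <- ((bad - 1) %% nrow(values)) + 1
    j <- ((bad - 1) %/% nrow(values)) + 1
    stop(sprintf(
      "dosage for sample '%s', locus '%s' is not in {0,1,2,NA} (value: %s)",
      rownames(values)[i], colnames(values)[j], values[bad]
    ))
  }
  storage.mode(values) <- "integer"
  structure(values, class = c("genotype_matrix", class(values)))
}

#' @export
`[.genotype_matrix` <- function(x, i, j, drop = FALSE) {
  m <- unclass(x)
  if (missing(i)) i <- seq_len(nrow(m))
  if (missing(j)) j <- seq_len(ncol(m))
  genotype_matrix(m[i, j, drop = FALSE])
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "SNP dosage matrix: %d samples x %d loci (%.1f%% missing)\n",
    nrow(x), ncol(x), 100 * mean(is.na(x))
  ))
  invisible(x)
}

#' Drop loci with too much missing data
#'
#' Removes every locus whose fraction of missing calls exceeds
#' `max_missing`, mirroring the usual RADseq export filter (e.g. "more than
#' 75% missing"). Samples and the relative order of retained loci are
#' unchanged. The operation is idempotent and monotone in `max_missing`.
#'
#' @param g a [genotype_matrix()].
#' @param max_missing maximum tolerated per-locus missing fraction in
#'   `[0, 1]`; default `0.75`.
#' @return filtered `genotype_matrix`.
#' @export
filter_loci_by_missingness <- function(g, max_missing = 0.75) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is.numeric(max_missing) || length(max_missing) != 1 ||
      is.na(max_missing) || max_missing < 0 || max_missing > 1) {
    stop("`max_missing` must be a single value in [0, 1]")
  }
  frac <- colMeans(is.na(g))
  g[, which(frac <= max_missing)]
}
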