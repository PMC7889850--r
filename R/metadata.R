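#' Sample metadata table
#'
#' Per-sample study metadata: the geographic region label used as the
#' grouping prior for ANOSIM (the study design uses five regions such as
#' A1, A2, P, B, CA), an optional `replicate_of` link identifying blind
#' replicate samples (technical duplicates run through the full AFLP
#' workflow), and an optional `match_key` joining the AFLP and SNP copies
#' of the same individual when the two marker types were generated from
#' different physical extracts.
#'
#' @param sample character vector of unique sample ids.
#' @param region character vector of region labels.
#' @param replicate_of optional; for a blind replicate, the id of the
#'   sample it duplicates (`NA` otherwise). Every non-`NA` target must be a
#'   known sample.
#' @param match_key optional join key; defaults to the sample id. Must be
#'   unique over non-replicate samples.
#' @return a `data.frame` of class `sample_metadata` with columns
#'   `sample`, `region`, `replicate_of`, `match_key`.
#' @export
sample_metadata <- function(sample, region, replicate_of = NULL,
                            match_key = NULL) {
  sample <- as.character(sample)
  region <- as.character(region)
  if (length(region) != length(sample)) {
    stop("`region` must have one entry per sample")
  }
  if (anyDuplicated(sample)) {
    stop("duplicate sample ids: ",
         paste(unique(sample[duplicated(sample)]), collapse = ", "))
  }
  replicate_of <- as.character(replicate_of %||% rep(NA_character_, length(sample)))
  replicate_of[!is.na(replicate_of) & replicate_of == ""] <- NA_character_
  dangling <- setdiff(replicate_of[!is.na(replicate_of)], sample)
  if (length(dangling) > 0) {
    stop("replicate_of refers to unknown sample(s): ",
         paste(dangling, collapse = ", "))
  }
  match_key <- as.character(match_key %||% sample)
  match_key[!is.na(match_key) & match_key == ""] <- NA_character_
  mk <- match_key[is.na(replicate_of) & !is.na(match_key)]
  if (anyDuplicated(mk)) {
    stop("match_key values are not unique: ",
         paste(unique(mk[duplicated(mk)]), collapse = ", "))
  }
  structure(
    data.frame(sample = sample, region = region,
               replicate_of = replicate_of, match_key = match_key,
               stringsAsFactors = FALSE),
    class = c("sample_metadata", "data.frame")
  )
}

#' Blind replicate pairs recorded in the metadata
#'
#' @param meta a [sample_metadata()].
#' @return a two-column data.frame (`a` = original sample, `b` = its blind
#'   replicate), one row per pair.
#' @export
replicate_pairs <- function(meta) {
  stopifnot(inherits(meta, "sample_metadata"))
  idx <- which(!is.na(meta$replicate_of))
  data.frame(a = meta$replicate_of[idx], b = meta$sample[idx],
             stringsAsFactors = FALSE)
}

#' Region labels as a named vector
#'
#' @param meta a [sample_metadata()].
#' @param samples optional subset/ordering of sample ids.
#' @return named character vector `sample -> region`.
#' @export
region_groups <- function(meta, samples = NULL) {
  stopifnot(inherits(meta, "sample_metadata"))
  g <- setNames(meta$region, meta$sample)
  if (!is.null(samples)) {
    missing <- setdiff(samples, names(g))
    if (length(missing) > 0) {
      stop("samples without metadata: ", paste(missing, collapse = ", "))
    }
    g <- g[samples]
  }
  g
}
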