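#' Read a binary AFLP marker table
#'
#' Expects a delimited text file with a header row of locus ids and a
#' leading column of sample ids. Locus ids may carry their
#' primer-combination tag as a `combo:locus` prefix; untagged loci get a
#' single default tag. The delimiter (tab, comma or semicolon) is
#' auto-detected unless given.
#'
#' @param path file path.
#' @param sep field delimiter; `NULL` (default) auto-detects.
#' @return an [aflp_matrix()]; row and column order as in the file.
#' @export
read_binary_marker_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% sniff_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, row.names = NULL,
                   check.names = FALSE, stringsAsFactors = FALSE,
                   comment.char = "")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  header <- colnames(df)[-1]  # before data.frame subsetting de-duplicates
  vals <- as.matrix(df[, -1, drop = FALSE])
  colnames(vals) <- header
  tagged <- grepl(":", header, fixed = TRUE)
  combo <- ifelse(tagged, sub(":.*$", "", header), "PC1")
  locus <- ifelse(tagged, sub("^[^:]*:", "", header), header)
  if (anyDuplicated(locus)) {
    stop("duplicate locus ids in ", path, ": ",
         paste(unique(locus[duplicated(locus)]), collapse = ", "))
  }
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | !(num %in% c(0, 1)))
  if (length(bad) > 0) {
    i <- ((bad[1] - 1) %% nrow(num)) + 1
    j <- ((bad[1] - 1) %/% nrow(num)) + 1
    stop(sprintf(
      "%s: cell (sample '%s', locus '%s') is not 0/1: '%s'",
      path, ids[i], locus[j], vals[bad[1]]
    ))
  }
  dimnames(num) <- list(ids, locus)
  aflp_matrix(num, setNames(combo, locus))
}

#' Write a binary AFLP marker table
#'
#' Inverse of [read_binary_marker_table()]: loci whose combination tag is
#' not the single default are written with the `combo:locus` header prefix,
#' so a write/read round trip preserves the matrix and its tags.
#'
#' @param m an [aflp_matrix()].
#' @param path output file path.
#' @param sep field delimiter (default tab).
#' @export
write_binary_marker_table <- function(m, path, sep = "\t") {
  stopifnot(inherits(m, "aflp_matrix"))
  combo <- primer_combos(m)
  header <- if (length(unique(combo)) == 1 && unique(combo) == "PC1") {
    colnames(m)
  } else {
    paste0(combo, ":", colnames(m))
  }
  df <- data.frame(sample = rownames(m), unclass(m)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample", header)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP genotype table
#'
#' Two dialects are supported. `"dosage_table"` is one row per individual
#' with entries in `{0, 1, 2, NA}`. `"structure_tworow"` is the
#' STRUCTURE-program export with two consecutive rows per individual
#' holding integer allele codes and `-9` for missing; the pair of rows is
#' collapsed to a dosage by counting, per locus, copies of the reference
#' allele, defined as the numerically lowest allele code observed at that
#' locus. Either allele missing makes the genotype missing. Loci with more
#' than two distinct non-missing allele codes are rejected.
#'
#' @param path file path.
#' @param format `"dosage_table"` or `"structure_tworow"`.
#' @param sep field delimiter; `NULL` auto-detects (whitespace for
#'   structure files without a delimiter).
#' @return a [genotype_matrix()].
#' @export
read_genotype_table <- function(path,
                                format = c("dosage_table", "structure_tworow"),
                                sep = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% sniff_sep(path)
  if (format == "dosage_table") {
    df <- read.table(path, header = TRUE, sep = sep, row.names = NULL,
                     check.names = FALSE, stringsAsFactors = FALSE,
                     na.strings = "NA")
    ids <- as.character(df[[1]])
    vals <- as.matrix(df[, -1, drop = FALSE])
    suppressWarnings(storage.mode(vals) <- "integer")
    dimnames(vals) <- list(ids, colnames(df)[-1])
    return(genotype_matrix(vals))
  }
  # structure_tworow
  first <- strsplit(trimws(readLines(path, n = 1L, warn = FALSE)),
                    if (sep == "") "[ \t]+" else sep)[[1]]
  has_header <- !any(grepl("^-?[0-9]+$", first))
  tab <- read.table(path, header = FALSE, sep = sep, skip = as.integer(has_header),
                    stringsAsFactors = FALSE)
  ids2 <- as.character(tab[[1]])
  alle <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(alle) <- "integer")
  if (nrow(alle) %% 2 != 0) {
    stop(path, ": structure_tworow file has an odd number of rows")
  }
  odd <- seq(1, nrow(alle), by = 2)
  if (any(ids2[odd] != ids2[odd + 1])) {
    bad <- which(ids2[odd] != ids2[odd + 1])[1]
    stop(sprintf("%s: rows %d/%d have differing sample ids ('%s' vs '%s')",
                 path, 2 * bad - 1, 2 * bad, ids2[odd][bad], ids2[odd + 1][bad]))
  }
  ids <- ids2[odd]
  if (anyDuplicated(ids)) stop(path, ": duplicate sample ids")
  loci <- if (has_header) first[seq_len(ncol(alle)) +
                                  (length(first) - ncol(alle))] else
    paste0("L", seq_len(ncol(alle)))
  a1 <- alle[odd, , drop = FALSE]
  a2 <- alle[odd + 1, , drop = FALSE]
  dos <- matrix(NA_integer_, length(ids), ncol(alle),
                dimnames = list(ids, loci))
  for (j in seq_len(ncol(alle))) {
    codes <- c(a1[, j], a2[, j])
    obs <- sort(unique(codes[codes != -9L & !is.na(codes)]))
    if (length(obs) > 2) {
      stop(sprintf("%s: locus '%s' is not biallelic (allele codes: %s)",
                   path, loci[j], paste(obs, collapse = ", ")))
    }
    ref <- if (length(obs) > 0) obs[1] else NA_integer_
    miss <- a1[, j] == -9L | a2[, j] == -9L | is.na(a1[, j]) | is.na(a2[, j])
    d <- (a1[, j] == ref) + (a2[, j] == ref)
    d[miss] <- NA_integer_
    dos[, j] <- as.integer(d)
  }
  genotype_matrix(dos)
}

#' Write a SNP genotype table
#'
#' `"dosage_table"` writes `NA` for missing calls. `"structure_tworow"`
#' writes two rows per individual using allele code 1 for the reference
#' allele and 2 for the alternative, with `-9 -9` for missing genotypes.
#' The round trip is exact for every locus at which the reference allele
#' is observed at least once; a locus monomorphic for dosage 0 reads back
#' with flipped polarity (dosage 2), which leaves all downstream
#' range-scaled distances unchanged.
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @param format `"dosage_table"` or `"structure_tworow"`.
#' @param sep field delimiter (default tab).
#' @export
write_genotype_table <- function(g, path,
                                 format = c("dosage_table", "structure_tworow"),
                                 sep = "\t") {
  stopifnot(inherits(g, "genotype_matrix"))
  format <- match.arg(format)
  if (format == "dosage_table") {
    df <- data.frame(sample = rownames(g), unclass(g)[, , drop = FALSE],
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                na = "NA")
    return(invisible(path))
  }
  n <- nrow(g)
  out <- matrix(NA_integer_, 2 * n, ncol(g))
  for (j in seq_len(ncol(g))) {
    d <- g[, j]
    out[seq(1, 2 * n, 2), j] <- ifelse(is.na(d), -9L, ifelse(d >= 1, 1L, 2L))
    out[seq(2, 2 * n, 2), j] <- ifelse(is.na(d), -9L, ifelse(d == 2, 1L, 2L))
  }
  ids <- rep(rownames(g), each = 2)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample", colnames(g)), collapse = sep), con)
  writeLines(paste(ids, apply(out, 1, paste, collapse = sep), sep = sep), con)
  invisible(path)
}

#' Read sample metadata
#'
#' CSV/TSV with columns `sample`, `region`, optional `replicate_of`
#' (empty = not a replicate) and optional `match_key` (defaults to the
#' sample id).
#'
#' @param path file path.
#' @param sep delimiter; `NULL` auto-detects.
#' @return a [sample_metadata()].
#' @export
read_sample_metadata <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% sniff_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  need <- c("sample", "region")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0) {
    stop(path, ": missing metadata column(s): ", paste(miss, collapse = ", "))
  }
  sample_metadata(df$sample, df$region,
                  replicate_of = df$replicate_of,
                  match_key = df$match_key)
}

#' @rdname read_sample_metadata
#' @param meta a [sample_metadata()].
#' @export
write_sample_metadata <- function(meta, path, sep = ",") {
  stopifnot(inherits(meta, "sample_metadata"))
  write.table(meta, path, sep = sep, quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read / write a labelled square distance matrix (CSV)
#'
#' @param path file path.
#' @param sep delimiter; `NULL` auto-detects on read, comma on write.
#' @return `read_distance_matrix`: a validated square numeric matrix.
#' @export
read_distance_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% sniff_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, row.names = 1,
                   check.names = FALSE, stringsAsFactors = FALSE)
  as_distance_matrix(as.matrix(df), arg = path)
}

#' @rdname read_distance_matrix
#' @param d a square distance matrix.
#' @export
write_distance_matrix <- function(d, path, sep = ",") {
  d <- as_distance_matrix(d)
  df <- data.frame(sample = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
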