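`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed
#'
#' Thin wrapper used by every stochastic entry point: when `seed` is `NULL`
#' the current RNG stream is used, otherwise the code runs under the given
#' seed and the previous RNG state is restored afterwards.
#'
#' @param seed integer seed or `NULL`.
#' @param code code to evaluate.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    code
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Deterministic seed substream derivation (LCG-style fold, kept < 2^31 - 1
# so the result is always a valid 32-bit R seed).
derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  h <- 0
  for (k in ks) {
    h <- (h * 69069 + abs(as.double(k)) + 1) %% 2147483647
  }
  as.integer(h)
}

# Significance stars at the conventional 0.05 / 0.01 levels.
p_stars <- function(p) {
  ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", ""))
}

# Guess the field delimiter of a delimited text file from its first line.
# Candidates: tab, comma, semicolon. Ties go to tab.
sniff_sep <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  counts <- vapply(c("\t", ",", ";"), function(s) {
    lengths(regmatches(line, gregexpr(s, line, fixed = TRUE)))
  }, integer(1))
  if (all(counts == 0L)) {
    return("")  # whitespace-delimited
  }
  c("\t", ",", ";")[which.max(counts)]
}

# Lower-triangle vector of a square matrix, in the same order as
# as.dist(): column-major over i > j.
lower_vec <- function(m) {
  m[lower.tri(m)]
}

#' Coerce to a validated labelled distance matrix
#'
#' Accepts a `dist` object or a square numeric matrix and returns a full
#' symmetric matrix with a zero diagonal and row/column labels.
#'
#' @param d a `dist` or square numeric matrix.
#' @param arg name used in error messages.
#' @return a square numeric matrix with `dimnames`.
#' @export
as_distance_matrix <- function(d, arg = "d") {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d)) {
    stop(sprintf("`%s` must be a numeric matrix or 'dist' object", arg))
  }
  if (nrow(d) != ncol(d)) {
    stop(sprintf("`%s` must be square", arg))
  }
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("s", seq_len(nrow(d)))
  }
  if (is.null(colnames(d))) colnames(d) <- rownames(d)
  if (any(!is.finite(d))) {
    stop(sprintf("`%s` contains non-finite distances", arg))
  }
  if (any(abs(d - t(d)) > 1e-8)) {
    stop(sprintf("`%s` is not symmetric", arg))
  }
  if (any(abs(diag(d)) > 1e-12)) {
    stop(sprintf("`%s` must have a zero diagonal", arg))
  }
  if (any(d < -1e-12)) {
    stop(sprintf("`%s` has negative entries", arg))
  }
  d
}

# Align a vector of group labels to the labels of a distance matrix.
# `groups` may be a named vector (matched by name) or an unnamed vector in
# matrix order.
align_groups <- function(groups, labels) {
  if (!is.null(names(groups))) {
    missing <- setdiff(labels, names(groups))
    if (length(missing) > 0) {
      stop("no group label for sample(s): ", paste(missing, collapse = ", "))
    }
    groups <- groups[labels]
  } else if (length(groups) != length(labels)) {
    stop("`groups` must be named or have one entry per sample")
  }
  as.character(groups)
}
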