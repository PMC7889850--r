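#' Non-metric multidimensional scaling (NMDS)
#'
#' Embeds a dissimilarity matrix in `k` dimensions by minimizing Kruskal
#' stress-1,
#' `sqrt( sum((dhat_ij - dtilde_ij)^2) / sum(dtilde_ij^2) )`,
#' where `dtilde` are the configuration distances and `dhat` is the
#' monotone (isotonic, pool-adjacent-violators) regression of the
#' configuration distances on the input dissimilarity order. Optimization
#' alternates isotonic regression with a Guttman-transform configuration
#' update (non-metric SMACOF); the reported stress trajectory is
#' non-increasing because an update that fails to improve stress is
#' rolled back and the restart stops.
#'
#' The first restart starts from the classical (metric) scaling solution,
#' the remaining `restarts - 1` from random configurations; the best
#' solution over restarts is returned.
#'
#' @param d labelled distance matrix or `dist`.
#' @param k embedding dimension (default 2).
#' @param restarts number of starts (default 50).
#' @param maxit maximum iterations per restart.
#' @param tol stop a restart when the stress improvement falls below this.
#' @param seed optional RNG seed for the random starts.
#' @return an object of class `nmds`: `points` (n x k, labelled rows),
#'   `stress` (Kruskal stress-1), `converged`, `iterations`.
#' @export
nmds <- function(d, k = 2, restarts = 50, maxit = 500, tol = 1e-6,
                 seed = NULL) {
  dm <- as_distance_matrix(d)
  n <- nrow(dm)
  if (n < k + 1) stop("need at least k + 1 objects")
  dv <- lower_vec(dm)
  if (sum(dv^2) == 0) {
    # all objects coincident: the zero configuration is a perfect fit
    pts <- matrix(0, n, k, dimnames = list(rownames(dm), NULL))
    return(structure(list(points = pts, stress = 0, converged = TRUE,
                          iterations = 0L), class = "nmds"))
  }
  ord <- order(dv)
  tri <- lower.tri(dm)

  run_one <- function(x0) {
    x <- x0
    stress_prev <- Inf
    it <- 0L
    converged <- FALSE
    repeat {
      it <- it + 1L
      cd <- as.matrix(dist(x))
      dvec <- cd[tri]
      if (sum(dvec^2) == 0) {
        if (it >= maxit) {
          stress <- Inf
          break
        }
        # collapsed configuration; perturb minimally
        x <- x + matrix(rnorm(n * k, sd = 1e-6), n, k)
        next
      }
      dhat <- numeric(length(dvec))
      dhat[ord] <- isoreg(dvec[ord])$yf
      stress <- sqrt(sum((dvec - dhat)^2) / sum(dvec^2))
      if (stress > stress_prev) {
        # rolled back: previous configuration was better
        x <- x_prev
        stress <- stress_prev
        converged <- TRUE
        break
      }
      if (stress_prev - stress < tol) {
        converged <- TRUE
        break
      }
      if (it >= maxit) break
      stress_prev <- stress
      x_prev <- x
      # Guttman transform with the isotonic fitted values as targets
      dh <- matrix(0, n, n)
      dh[tri] <- dhat
      dh <- dh + t(dh)
      ratio <- ifelse(cd > 0, dh / cd, 0)
      b <- -ratio
      diag(b) <- rowSums(ratio)
      x <- b %*% x / n
    }
    list(x = x, stress = stress, it = it, converged = converged)
  }

  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      x0 <- if (r == 1) {
        cs <- suppressWarnings(cmdscale(dm, k = k))
        if (ncol(cs) < k) cs <- cbind(cs, matrix(0, n, k - ncol(cs)))
        cs + matrix(rnorm(n * k, sd = 1e-8), n, k)
      } else {
        matrix(runif(n * k, -1, 1), n, k)
      }
      res <- run_one(x0)
      if (is.null(best) || res$stress < best$stress) best <- res
    }
    pts <- scale(best$x, center = TRUE, scale = FALSE)
    attr(pts, "scaled:center") <- NULL
    rownames(pts) <- rownames(dm)
    structure(list(points = pts, stress = best$stress,
                   converged = best$converged, iterations = best$it),
              class = "nmds")
  })
}

#' @export
print.nmds <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d points in %d dimensions, stress-1 = %.5f%s\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}
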