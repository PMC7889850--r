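#' Parameters for the paired-marker simulator
#'
#' The generator emulates the sampling design of a multi-region
#' comparative phylogeographic study: `n_regions` geographic regions with
#' `n_per_region` individuals each, Balding–Nichols-style between-region
#' allele-frequency differentiation `fst`, dominant AFLP presence/absence
#' bands scored with per-locus flip noise `epsilon` and a set of blind
#' replicate samples, and diploid SNP dosages with
#' missing-completely-at-random rate `missing_rate`.
#'
#' The defaults mirror the cross-taxonomic design of the study system the
#' package targets: 5 regions x 3 individuals, 3 blind replicates per
#' dataset, 8 AFLP primer combinations, a few hundred AFLP bands against
#' thousands of SNPs, and substantial SNP missingness.
#'
#' @param n_regions number of regions (default 5).
#' @param n_per_region individuals per region (default 3).
#' @param n_loci_aflp AFLP loci (default 500).
#' @param n_loci_snp SNP loci (default 5000).
#' @param fst differentiation in `[0, 1)` (default 0.3).
#' @param epsilon AFLP scoring-noise flip probability in `[0, 0.5]`
#'   (default 0.05).
#' @param n_replicate_pairs blind replicates (default 3); at most the
#'   total number of individuals.
#' @param missing_rate SNP missing-call probability in `[0, 1)` (default
#'   0.2).
#' @param seed RNG seed; the full simulation is bitwise reproducible.
#' @return a validated list of class `sim_params`.
#' @export
sim_params <- function(n_regions = 5, n_per_region = 3,
                       n_loci_aflp = 500, n_loci_snp = 5000,
                       fst = 0.3, epsilon = 0.05,
                       n_replicate_pairs = 3, missing_rate = 0.2,
                       seed = 1) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(n_regions >= 1, "`n_regions` must be >= 1")
  chk(n_per_region >= 1, "`n_per_region` must be >= 1")
  chk(n_loci_aflp >= 1 && n_loci_snp >= 1, "locus counts must be >= 1")
  chk(fst >= 0 && fst < 1, "`fst` must be in [0, 1)")
  chk(epsilon >= 0 && epsilon <= 0.5, "`epsilon` must be in [0, 0.5]")
  chk(missing_rate >= 0 && missing_rate < 1, "`missing_rate` must be in [0, 1)")
  chk(n_replicate_pairs >= 0 &&
        n_replicate_pairs <= n_regions * n_per_region,
      "`n_replicate_pairs` must be between 0 and the number of individuals")
  structure(list(
    n_regions = as.integer(n_regions),
    n_per_region = as.integer(n_per_region),
    n_loci_aflp = as.integer(n_loci_aflp),
    n_loci_snp = as.integer(n_loci_snp),
    fst = fst, epsilon = epsilon,
    n_replicate_pairs = as.integer(n_replicate_pairs),
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "sim_params")
}

region_names <- function(k) {
  std <- c("A1", "A2", "P", "B", "CA")
  if (k <= length(std)) std[seq_len(k)] else paste0("R", seq_len(k))
}

#' Simulate latent regional allele-frequency structure
#'
#' The F-model: ancestral frequencies `p_l ~ Uniform(0.05, 0.95)` per
#' locus; for `fst > 0` each region draws its own frequency
#' `f_rl ~ Beta(p_l (1 - fst) / fst, (1 - p_l)(1 - fst) / fst)`
#' independently, so that `E[f_rl] = p_l` and
#' `Var(f_rl) = fst * p_l (1 - p_l)`. For `fst = 0` the regional
#' frequencies equal the ancestral ones exactly. One frequency block is
#' drawn for the AFLP loci and one for the SNP loci, so paired datasets
#' share the regional structure (same regions, same `fst`) but not the
#' physical loci — as in a real study, where the two marker types sample
#' different parts of the genome.
#'
#' @param params a [sim_params()].
#' @return an object of class `latent_structure`: `p` (ancestral
#'   frequencies, length `n_loci_aflp + n_loci_snp`), `f` (regions x loci
#'   matrix), `aflp_loci`/`snp_loci` (column index vectors), `regions`.
#' @export
simulate_structure <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n_loci <- params$n_loci_aflp + params$n_loci_snp
  regions <- region_names(params$n_regions)
  with_seed(derive_seed(params$seed, 101), {
    p <- runif(n_loci, 0.05, 0.95)
    f <- if (params$fst == 0) {
      matrix(p, params$n_regions, n_loci, byrow = TRUE)
    } else {
      a <- p * (1 - params$fst) / params$fst
      b <- (1 - p) * (1 - params$fst) / params$fst
      t(vapply(seq_len(params$n_regions),
               function(r) rbeta(n_loci, a, b), numeric(n_loci)))
    }
    rownames(f) <- regions
    structure(list(p = p, f = f,
                   aflp_loci = seq_len(params$n_loci_aflp),
                   snp_loci = params$n_loci_aflp + seq_len(params$n_loci_snp),
                   regions = regions),
              class = "latent_structure")
  })
}

sim_individuals <- function(params) {
  regions <- region_names(params$n_regions)
  data.frame(
    sample = paste0(rep(regions, each = params$n_per_region), "_i",
                    rep(seq_len(params$n_per_region), params$n_regions)),
    region = rep(regions, each = params$n_per_region),
    stringsAsFactors = FALSE
  )
}

#' Simulate a dominant AFLP fingerprint dataset with blind replicates
#'
#' An individual in region `r` carries a band at locus `l` with
#' probability `1 - (1 - f_rl)^2`: the band is dominant, so any of the two
#' allele copies produces it. Blind replicates copy the *true* band
#' profile of a randomly chosen source individual; every scored profile —
#' originals and replicates alike — then flips each locus independently
#' with probability `epsilon`, so the expected replicate p-distance is
#' `2 * epsilon * (1 - epsilon)`. Loci are assigned round-robin to 8
#' primer-combination tags.
#'
#' @param ls a [simulate_structure()] result.
#' @param params the same [sim_params()].
#' @return list with `matrix` (an [aflp_matrix()] over originals and
#'   replicates) and `meta` (a [sample_metadata()] with `replicate_of`
#'   links; `match_key` is the sample id for originals, `NA` for
#'   replicates).
#' @export
simulate_aflp <- function(ls, params) {
  stopifnot(inherits(ls, "latent_structure"), inherits(params, "sim_params"))
  ind <- sim_individuals(params)
  la <- ls$aflp_loci
  with_seed(derive_seed(params$seed, 202), {
    band_p <- 1 - (1 - ls$f[ind$region, la, drop = FALSE])^2
    true <- matrix(rbinom(length(band_p), 1, band_p), nrow(ind),
                   length(la))
    src <- sample.int(nrow(ind), params$n_replicate_pairs)
    rep_ids <- if (length(src) > 0) paste0(ind$sample[src], "_rep") else character(0)
    profiles <- rbind(true, true[src, , drop = FALSE])
    flips <- matrix(rbinom(length(profiles), 1, params$epsilon),
                    nrow(profiles), ncol(profiles))
    scored <- abs(profiles - flips)
    rownames(scored) <- c(ind$sample, rep_ids)
    colnames(scored) <- paste0("A", seq_along(la))
    combo <- setNames(paste0("PC", ((seq_along(la) - 1) %% 8) + 1),
                      colnames(scored))
    meta <- sample_metadata(
      sample = c(ind$sample, rep_ids),
      region = c(ind$region, ind$region[src]),
      replicate_of = c(rep(NA_character_, nrow(ind)), ind$sample[src]),
      match_key = c(ind$sample, rep(NA_character_, length(rep_ids)))
    )
    list(matrix = aflp_matrix(scored, combo), meta = meta)
  })
}

#' Simulate a SNP dosage dataset
#'
#' Dosages are `Binomial(2, f_rl)` draws (diploid genotypes under the
#' regional allele frequency); each entry is then independently set
#' missing with probability `missing_rate`. Individuals and their
#' `match_key`s coincide with those of [simulate_aflp()] run on the same
#' structure, so the two datasets are joinable.
#'
#' @param ls a [simulate_structure()] result.
#' @param params the same [sim_params()].
#' @return list with `matrix` (a [genotype_matrix()]) and `meta`.
#' @export
simulate_snp <- function(ls, params) {
  stopifnot(inherits(ls, "latent_structure"), inherits(params, "sim_params"))
  ind <- sim_individuals(params)
  lsnp <- ls$snp_loci
  with_seed(derive_seed(params$seed, 303), {
    fr <- ls$f[ind$region, lsnp, drop = FALSE]
    dos <- matrix(rbinom(length(fr), 2, fr), nrow(ind), length(lsnp))
    miss <- matrix(runif(length(dos)) < params$missing_rate,
                   nrow(dos), ncol(dos))
    dos[miss] <- NA_integer_
    dimnames(dos) <- list(ind$sample, paste0("S", seq_along(lsnp)))
    meta <- sample_metadata(ind$sample, ind$region)
    list(matrix = genotype_matrix(dos), meta = meta)
  })
}

#' Simulate a paired AFLP + SNP dataset
#'
#' Convenience wrapper: one latent structure, one AFLP dataset (with
#' blind replicates) and one SNP dataset from it.
#'
#' @param params a [sim_params()].
#' @return list with `structure`, `aflp` and `snp` (each as returned by
#'   the respective simulator).
#' @export
simulate_paired <- function(params = sim_params()) {
  ls <- simulate_structure(params)
  list(structure = ls,
       aflp = simulate_aflp(ls, params),
       snp = simulate_snp(ls, params))
}
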