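# Monte Carlo meiosis simulator (the simulation analog of the closed
# formulas). Recombination follows a count-location process: the number of
# crossovers on a chromosome is Poisson with mean equal to the mapped length
# in Morgans and crossover locations are i.i.d. uniform — the simulation
# equivalent of Haldane's mapping function (no interference).

# Per-chromosome marker blocks: column indices and positions in Morgans.
chr_blocks <- function(map, markers) {
  mi <- match(markers, map$marker)
  if (anyNA(mi))
    stop_validation("marker(s) absent from linkage map: ",
                    paste(utils::head(markers[is.na(mi)], 5L), collapse = ", "))
  chrom <- map$chrom[mi]
  pos <- map$pos_cM[mi] / 100
  lapply(unique(chrom), function(cc) {
    cols <- which(chrom == cc)
    if (is.unsorted(pos[cols]))
      stop_validation("markers on chromosome ", cc, " are not in map order")
    list(cols = cols, pos = pos[cols])
  })
}

# Vectorised meiosis for one chromosome: row i of the result is a gamete of
# the individual with haplotypes hapA[i, ], hapB[i, ]. `pos` in Morgans,
# nondecreasing. Crossovers are drawn over the mapped marker span (crossovers
# outside it cannot affect marker genotypes).
meiosis_batch <- function(hapA, hapB, pos) {
  n <- nrow(hapA); L <- ncol(hapA)
  start <- sample.int(2L, n, replace = TRUE) - 1L     # 0: begin on hapA
  span <- pos[L] - pos[1L]
  if (L == 1L || span <= 0) {
    phase <- matrix(start, n, L)
  } else {
    ncx <- stats::rpois(n, span)
    tot <- sum(ncx)
    if (tot == 0L) {
      before <- matrix(0, n, L)
    } else {
      gid <- rep.int(seq_len(n), ncx)
      loc <- stats::runif(tot, pos[1L], pos[L])
      iv <- findInterval(loc, pos)                    # crossover in (pos[iv], pos[iv+1])
      cnt <- matrix(tabulate((iv - 1L) * n + gid, nbins = n * (L - 1L)), n, L - 1L)
      UT <- upper.tri(matrix(0, L - 1L, L - 1L), diag = TRUE) * 1
      before <- cbind(0, cnt %*% UT)                  # crossovers left of each marker
    }
    phase <- (start + before) %% 2
  }
  hapA * (phase == 0) + hapB * (phase == 1)
}

draw_gametes <- function(hapA, hapB, blocks) {
  out <- matrix(0, nrow(hapA), ncol(hapA), dimnames = dimnames(hapA))
  for (b in blocks)
    out[, b$cols] <- meiosis_batch(hapA[, b$cols, drop = FALSE],
                                   hapB[, b$cols, drop = FALSE], b$pos)
  out
}

#' Simulate a single gamete
#'
#' Draws one gamete from an individual with the given pair of haplotypes,
#' using the count-location crossover process per chromosome (Poisson
#' crossover count over the mapped length in Morgans, uniform locations, and
#' a fair coin for the starting haplotype).
#'
#' @param parent_haplotypes list of two named binary vectors (alleles per
#'   marker) of equal length.
#' @param map a `linkage_map` covering the markers.
#' @param seed optional integer seed.
#' @return A named binary vector: the gamete's allele at each marker.
#' @export
simulate_gamete <- function(parent_haplotypes, map, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h1 <- parent_haplotypes[[1L]]; h2 <- parent_haplotypes[[2L]]
  if (length(h1) != length(h2) || is.null(names(h1)))
    stop_validation("parent haplotypes must be two named vectors of equal length")
  blocks <- chr_blocks(map, names(h1))
  drop(draw_gametes(matrix(h1, 1L, dimnames = list(NULL, names(h1))),
                    matrix(h2, 1L, dimnames = list(NULL, names(h1))), blocks))
}

#' Simulate a population of derived homozygous lines
#'
#' Builds the F1 of two homozygous parents and derives `n_progeny` fully
#' homozygous lines under the mating scheme. For DH: after `t` rounds of
#' random intermating (finite population of size `n_im`), one gamete per
#' progeny is drawn and doubled. For SSD: from the same stage, each progeny
#' starts as an F2-equivalent individual (union of two gametes from the
#' pool), is selfed for `n_self` generations taking a single seed each
#' generation, and residual heterozygous loci are fixed by a fair coin per
#' locus (an unbiased closure to complete inbreeding).
#'
#' @param parents 2 x markers dosage matrix (values 0/2) of the two
#'   homozygous parents; columns in map order.
#' @param map a `linkage_map`.
#' @param scheme a [mating_scheme()].
#' @param n_progeny number of derived lines (>= 1).
#' @param n_im finite population size during intermating rounds (default
#'   200; use a large value to suppress drift when validating expectations).
#' @param n_self selfing generations for SSD before the coin-flip closure
#'   (default 10, leaving ~0.1% residual heterozygosity per locus).
#' @param seed optional integer seed.
#' @return A `sim_population`: list with `dosage` (progeny x markers, values
#'   0/2), `scheme`, `n_progeny`, `n_im`, `n_self`, `seed`.
#' @export
simulate_population <- function(parents, map, scheme, n_progeny,
                                n_im = 200L, n_self = 10L, seed = NULL) {
  stopifnot(inherits(scheme, "mating_scheme"))
  if (!is.null(seed)) set.seed(seed)
  if (nrow(parents) != 2L) stop_validation("`parents` must have exactly 2 rows")
  if (n_progeny < 1L) stop_validation("n_progeny must be >= 1")
  markers <- colnames(parents)
  if (any(!(parents %in% c(0, 2))))
    stop_validation("parents must be fully homozygous (dosages 0/2) with no missing values")
  blocks <- chr_blocks(map, markers)
  hapA <- matrix(parents[1L, ] / 2, 1L, dimnames = list(NULL, markers))
  hapB <- matrix(parents[2L, ] / 2, 1L, dimnames = list(NULL, markers))
  pool <- list(A = hapA, B = hapB)                  # the F1
  for (round in seq_len(scheme$t)) {
    npool <- nrow(pool$A)
    mo <- sample.int(npool, n_im, replace = TRUE)
    fa <- sample.int(npool, n_im, replace = TRUE)
    pool <- list(
      A = draw_gametes(pool$A[mo, , drop = FALSE], pool$B[mo, , drop = FALSE], blocks),
      B = draw_gametes(pool$A[fa, , drop = FALSE], pool$B[fa, , drop = FALSE], blocks))
  }
  npool <- nrow(pool$A)
  if (scheme$kind == "dh") {
    rows <- sample.int(npool, n_progeny, replace = TRUE)
    gam <- draw_gametes(pool$A[rows, , drop = FALSE], pool$B[rows, , drop = FALSE], blocks)
    dosage <- 2 * gam
  } else {
    ra <- sample.int(npool, n_progeny, replace = TRUE)
    rb <- sample.int(npool, n_progeny, replace = TRUE)
    hA <- draw_gametes(pool$A[ra, , drop = FALSE], pool$B[ra, , drop = FALSE], blocks)
    hB <- draw_gametes(pool$A[rb, , drop = FALSE], pool$B[rb, , drop = FALSE], blocks)
    for (g in seq_len(n_self)) {
      nA <- draw_gametes(hA, hB, blocks)
      nB <- draw_gametes(hA, hB, blocks)
      hA <- nA; hB <- nB
    }
    het <- hA != hB
    if (any(het)) {                                  # fair-coin closure to F-infinity
      pick <- matrix(stats::rbinom(length(hA), 1L, 0.5), nrow(hA))
      hA[het & pick == 1] <- hB[het & pick == 1]
    }
    dosage <- 2 * hA
  }
  rownames(dosage) <- sprintf("progeny_%04d", seq_len(n_progeny))
  structure(list(dosage = dosage, scheme = scheme, n_progeny = n_progeny,
                 n_im = n_im, n_self = n_self, seed = seed),
            class = "sim_population")
}

#' Genotypic values of simulated lines
#'
#' `beta0 + dosage %*% u` over the markers carried by the effects object.
#'
#' @param pop a `sim_population` (or a bare dosage matrix).
#' @param effects a [marker_effects()] object.
#' @return Numeric vector of genotypic values.
#' @export
genotypic_values <- function(pop, effects) {
  dosage <- if (inherits(pop, "sim_population")) pop$dosage else pop
  use <- names(effects$effects)
  miss <- setdiff(use, colnames(dosage))
  if (length(miss))
    stop_validation("effect marker(s) absent from simulated dosages: ",
                    paste(utils::head(miss, 5L), collapse = ", "))
  drop(effects$intercept + dosage[, use, drop = FALSE] %*% effects$effects)
}

#' Simulate replicated populations for one cross
#'
#' Runs [simulate_population()] `n_reps` times with deterministically
#' derived replicate seeds (`seed + replicate index - 1`).
#'
#' @inheritParams simulate_population
#' @param n_reps number of replicate populations.
#' @param seed base integer seed.
#' @return List of `sim_population` objects.
#' @export
simulate_cross_replicates <- function(parents, map, scheme, n_progeny = 200L,
                                      n_reps = 25L, seed = 1L,
                                      n_im = 200L, n_self = 10L) {
  lapply(seq_len(n_reps), function(rep)
    simulate_population(parents, map, scheme, n_progeny,
                        n_im = n_im, n_self = n_self, seed = seed + rep - 1L))
}

#' Monte Carlo estimate of a cross mean and variance
#'
#' For each replicate population, computes the sample mean and the
#' (n-1)-denominator sample variance of the genotypic values, and averages
#' the replicate estimates; the empirical standard error of the variance
#' estimate is the standard deviation of the replicate variances divided by
#' `sqrt(n_reps)` (`NA` for a single replicate).
#'
#' @param pops a `sim_population` or a list of replicate populations.
#' @param effects a [marker_effects()] object.
#' @return List with `mean`, `variance`, `se_variance`, `rep_means`,
#'   `rep_variances`.
#' @export
mc_variance_estimate <- function(pops, effects) {
  if (inherits(pops, "sim_population")) pops <- list(pops)
  vals <- lapply(pops, genotypic_values, effects = effects)
  if (any(lengths(vals) < 2L))
    stop_validation("variance estimation needs at least 2 progeny per replicate")
  rep_means <- vapply(vals, mean, numeric(1L))
  rep_vars <- vapply(vals, stats::var, numeric(1L))
  list(mean = mean(rep_means), variance = mean(rep_vars),
       se_variance = if (length(rep_vars) > 1L)
         stats::sd(rep_vars) / sqrt(length(rep_vars)) else NA_real_,
       rep_means = rep_means, rep_variances = rep_vars)
}
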