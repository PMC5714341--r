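# Closed-form mean and segregation variance of the genotypic values of
# homozygous lines derived from a biparental cross.
#
# For a cross of two fully homozygous parents, the genotypic value of a
# derived line is Z = beta0 + sum_j Z_j, where Z_j takes the value
# g_j (= maternal dosage x u_j, i.e. twice the additive effect of the
# maternal allele) or h_j (paternal analog), each with probability 1/2.
# With q_jk the probability that locus k carries the maternal allele given
# that locus j does,
#   mu      = beta0 + sum_j (g_j + h_j) / 2
#   sigma^2 = sum_c sum_{j,k on c} (q_jk/2 - 1/4)(g_j - h_j)(g_k - h_k)
# the double sum running over all ordered locus pairs including j = k
# (q_jj = 1, so the diagonal supplies the single-locus variances).
# Pairs on different chromosomes have q = 1/2 and contribute nothing.

#' Per-cross parental allele contributions
#'
#' Builds, for one cross, the vectors `g` (maternal parent's dosage times
#' the marker effect) and `h` (paternal analog) over the markers usable in
#' that cross. Both parents must be homozygous (dosage 0 or 2) at every used
#' marker; markers with a missing dosage in either parent are excluded from
#' both sums with a warning.
#'
#' @param p1,p2 named dosage vectors (0/2, NA allowed) for the two parents.
#' @param effects a [marker_effects()] object; only markers present in it
#'   are used.
#' @param p1_id,p2_id line ids used in error messages.
#' @return List with `g`, `h` (named numeric vectors) and `beta0`.
#' @export
cross_parent_effects <- function(p1, p2, effects, p1_id = "parent1", p2_id = "parent2") {
  stopifnot(inherits(effects, "marker_effects"))
  use <- intersect(names(effects$effects), names(p1))
  use <- intersect(use, names(p2))
  if (length(use) == 0L) stop_validation("no markers shared by effects and parents")
  d1 <- p1[use]; d2 <- p2[use]
  ok <- !is.na(d1) & !is.na(d2)
  if (!all(ok)) {
    warning(sprintf("cross %s x %s: %d marker(s) with missing parental dosage excluded",
                    p1_id, p2_id, sum(!ok)), call. = FALSE)
    use <- use[ok]; d1 <- d1[ok]; d2 <- d2[ok]
  }
  check_homozygous(d1, p1_id)
  check_homozygous(d2, p2_id)
  u <- effects$effects[use]
  list(g = d1 * u, h = d2 * u, beta0 = effects$intercept)
}

check_homozygous <- function(dos, id) {
  bad <- which(!(dos %in% c(0, 2)))
  if (length(bad))
    stop_validation(sprintf("parent %s is not homozygous at marker %s (dosage %s)",
                            id, names(dos)[bad[1L]], format(dos[bad[1L]])))
  invisible(TRUE)
}

#' Expected genotypic value of a cross
#'
#' `mu = beta0 + sum_j (g_j + h_j) / 2`: the midpoint of the two parents'
#' predicted genotypic values, identical for every mating scheme.
#'
#' @param cpe a [cross_parent_effects()] list.
#' @return The cross mean.
#' @export
cross_mean <- function(cpe) cpe$beta0 + sum((cpe$g + cpe$h) / 2)

#' Covariance of the genotypic contributions of two loci
#'
#' `cov(Z_j, Z_k) = (q_jk/2 - 1/4) (g_j - h_j)(g_k - h_k)`. Zero when
#' `q = 1/2` (linkage equilibrium) or when either locus is monomorphic in
#' the cross (`g = h`).
#'
#' @param g_j,h_j,g_k,h_k parental contributions at the two loci.
#' @param q_jk conditional parental-origin probability in `[0, 1]`.
#' @return The covariance.
#' @export
pair_covariance <- function(g_j, h_j, g_k, h_k, q_jk) {
  if (any(q_jk < 0) || any(q_jk > 1))
    stop_validation("q_jk must lie in [0, 1]")
  (q_jk / 2 - 0.25) * (g_j - h_j) * (g_k - h_k)
}

#' Segregation variance of a cross
#'
#' Sums `pair_covariance()` over all ordered locus pairs within each
#' chromosome (including the diagonal, where `q_jj = 1` gives the
#' single-locus variance `(g_j - h_j)^2 / 4`), with `q_jk` from the mating
#' scheme's expected-LD formula and the Haldane map distances. Exact, no
#' distance cutoff.
#'
#' @param cpe a [cross_parent_effects()] list.
#' @param map a `linkage_map` covering every marker in `cpe`.
#' @param scheme a [mating_scheme()].
#' @param map_fun distance -> recombination-frequency function (Haldane by
#'   default), passed to [q_jk()].
#' @return The segregation variance (>= 0; tiny negative floating-point
#'   residue is clamped with a warning, material negativity is an error).
#' @export
cross_variance <- function(cpe, map, scheme, map_fun = haldane_r) {
  stopifnot(inherits(map, "linkage_map"), inherits(scheme, "mating_scheme"))
  markers <- names(cpe$g)
  mi <- match(markers, map$marker)
  if (anyNA(mi))
    stop_validation("marker(s) absent from linkage map: ",
                    paste(utils::head(markers[is.na(mi)], 5L), collapse = ", "))
  dvec <- (cpe$g - cpe$h) / 2          # cov(Z_j, Z_k) = (2 q - 1) d_j d_k
  chrom <- map$chrom[mi]
  pos <- map$pos_cM[mi]
  total <- 0
  for (cc in unique(chrom)) {
    on <- chrom == cc
    d <- dvec[on]
    if (all(d == 0)) next
    dist <- abs(outer(pos[on], pos[on], `-`))
    Q <- 2 * q_jk(scheme, dist, map_fun = map_fun) - 1
    diag(Q) <- 1                        # j = k: q_jj = 1
    total <- total + drop(d %*% Q %*% d)
  }
  if (total < -1e-9)
    stop_numerical("negative segregation variance (", format(total),
                   "): covariance assembly is inconsistent")
  if (total < 0) {
    warning("segregation variance clamped to 0 (floating-point residue ",
            format(total), ")", call. = FALSE)
    total <- 0
  }
  total
}

#' Selection intensity of truncation selection
#'
#' Mean of the selected upper fraction `p` of a standard normal:
#' `i = dnorm(z) / p` with `z` the upper-`p` quantile. `i(1) = 0`, and `i`
#' decreases monotonically in `p`.
#'
#' @param p selected fraction in `(0, 1]`.
#' @return The selection intensity.
#' @examples
#' selection_intensity(0.5)   # ~0.7979
#' selection_intensity(0.05)  # ~2.0627
#' @export
selection_intensity <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop_validation("selected fraction p must lie in (0, 1]")
  ifelse(p == 1, 0, stats::dnorm(stats::qnorm(p, lower.tail = FALSE)) / p)
}

#' Superior progeny value
#'
#' `s = mu + i * sigma`: the expected genotypic value of the selected upper
#' fraction of the derived lines.
#'
#' @param mu cross mean.
#' @param sigma segregation standard deviation (>= 0).
#' @param i selection intensity (>= 0).
#' @return `mu + i * sigma`.
#' @export
superior_progeny_value <- function(mu, sigma, i) {
  if (any(sigma < 0)) stop_validation("sigma must be >= 0")
  if (any(i < 0)) stop_validation("selection intensity must be >= 0")
  mu + i * sigma
}

#' Usefulness criterion
#'
#' `U = mu + i * sigma * h` with `h` the square root of the heritability;
#' equals the superior progeny value when `h = 1`.
#'
#' @inheritParams superior_progeny_value
#' @param h square root of the heritability, in `[0, 1]`.
#' @return `mu + i * sigma * h`.
#' @export
usefulness <- function(mu, sigma, i, h) {
  if (any(h < 0) || any(h > 1))
    stop_validation("h (square root of heritability) must lie in [0, 1]")
  if (any(sigma < 0)) stop_validation("sigma must be >= 0")
  mu + i * sigma * h
}

#' Predict mean, variance and usefulness for all pairwise crosses
#'
#' Enumerates every unordered pair of candidate parents, computes the
#' closed-form mean and segregation variance, the superior progeny value
#' `s = mu + i sigma` and the usefulness `U = mu + i sigma h`, and returns
#' the crosses sorted by `s` (descending; ties broken by the parent-id
#' pair).
#'
#' @param parents numeric lines x markers dosage matrix of fully homozygous
#'   candidate parents (rownames = line ids).
#' @param effects a [marker_effects()] object.
#' @param map a `linkage_map`.
#' @param scheme a [mating_scheme()].
#' @param p selected fraction in `(0, 1]` (default 0.05).
#' @param h square root of the heritability in `[0, 1]` (default 1, i.e.
#'   `U = s`).
#' @param map_fun optional mapping function, see [cross_variance()].
#' @return A `cross_prediction` data frame with columns `parent1`,
#'   `parent2`, `scheme`, `t`, `mu`, `sigma2`, `sigma`, `s`, `U`;
#'   attributes `i_used`, `h_used`, `p_used`.
#' @export
predict_all_crosses <- function(parents, effects, map, scheme,
                                p = 0.05, h = 1, map_fun = haldane_r) {
  stopifnot(inherits(effects, "marker_effects"), inherits(map, "linkage_map"),
            inherits(scheme, "mating_scheme"))
  if (is.null(rownames(parents)) || nrow(parents) < 2L)
    stop_validation("need a dosage matrix of at least 2 named parents")
  miss_map <- setdiff(names(effects$effects), map$marker)
  if (length(miss_map))
    stop_validation("effect marker(s) absent from linkage map: ",
                    paste(utils::head(miss_map, 5L), collapse = ", "))
  i_val <- selection_intensity(p)
  if (h < 0 || h > 1) stop_validation("h must lie in [0, 1]")
  ids <- rownames(parents)
  pairs <- utils::combn(seq_along(ids), 2L)
  res <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    cpe <- cross_parent_effects(parents[a, ], parents[b, ], effects,
                                p1_id = ids[a], p2_id = ids[b])
    mu <- cross_mean(cpe)
    s2 <- cross_variance(cpe, map, scheme, map_fun = map_fun)
    sg <- sqrt(max(s2, 0))
    res[[k]] <- data.frame(
      parent1 = ids[a], parent2 = ids[b], scheme = scheme$kind, t = scheme$t,
      mu = mu, sigma2 = s2, sigma = sg,
      s = superior_progeny_value(mu, sg, i_val),
      U = usefulness(mu, sg, i_val, h),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[order(-out$s, out$parent1, out$parent2), ]
  rownames(out) <- NULL
  attr(out, "i_used") <- i_val
  attr(out, "h_used") <- h
  attr(out, "p_used") <- p
  class(out) <- c("cross_prediction", "data.frame")
  out
}
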