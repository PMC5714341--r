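# Exact oracles for the closed formulas: exhaustive gamete enumeration for
# F1-DH crosses and the two-locus selfing recursion whose fixed point is the
# Haldane-Waddington LD attrition factor 1/(1 + 2r).

#' Exact mean and variance of an F1-DH cross by exhaustive enumeration
#'
#' Enumerates all `2^L` gamete patterns per chromosome. Under the
#' no-interference (count-location) model the crossover pattern is Markov
#' along the chromosome, so a pattern's probability is
#' `1/2 * prod(r_i if switch in interval i else 1 - r_i)` over adjacent
#' marker intervals. Chromosomes combine by independence. Valid for F1-DH
#' (t = 0) only.
#'
#' @param cpe a [cross_parent_effects()] list.
#' @param map a `linkage_map` covering the markers.
#' @param max_loci refuse chromosomes with more loci than this (default 20).
#' @return List with exact `mean` and `variance` of the genotypic value.
#' @export
exhaustive_dh_variance <- function(cpe, map, max_loci = 20L) {
  markers <- names(cpe$g)
  mi <- match(markers, map$marker)
  if (anyNA(mi))
    stop_validation("marker(s) absent from linkage map: ",
                    paste(utils::head(markers[is.na(mi)], 5L), collapse = ", "))
  chrom <- map$chrom[mi]
  pos <- map$pos_cM[mi]
  mu <- cpe$beta0
  v <- 0
  for (cc in unique(chrom)) {
    on <- which(chrom == cc)
    on <- on[order(pos[on])]
    L <- length(on)
    if (L > max_loci)
      stop_validation("chromosome ", cc, " has ", L, " loci (> ", max_loci,
                      "): use the Monte Carlo simulator instead")
    r <- haldane_r(diff(pos[on]))
    res <- enumerate_dh_chromosome(cpe$g[on], cpe$h[on], r)
    mu <- mu + res$mean
    v <- v + res$variance
  }
  list(mean = mu, variance = v)
}

# one chromosome: pattern 0 = maternal allele (value g), 1 = paternal (h)
enumerate_dh_chromosome <- function(g, h, r) {
  L <- length(g)
  pat <- as.matrix(expand.grid(rep(list(0:1), L), KEEP.OUT.ATTRS = FALSE))
  p <- rep(0.5, nrow(pat))
  for (i in seq_len(L - 1L)) {
    sw <- pat[, i + 1L] != pat[, i]
    p <- p * ifelse(sw, r[i], 1 - r[i])
  }
  val <- drop((1 - pat) %*% g + pat %*% h)
  m <- sum(p * val)
  list(mean = m, variance = sum(p * val^2) - m^2)
}

#' Fixed-point LD of the exact two-locus selfing recursion
#'
#' Starts from a Hardy-Weinberg population whose gametes carry LD `D_init`
#' between two loci with recombination frequency `r`, and iterates the exact
#' gamete-pair (diplotype) frequency recursion under selfing until the
#' population is fixed (total heterozygosity < 1e-12). Returns the LD among
#' the fixed lines, which must equal the Haldane-Waddington value
#' `D_init / (1 + 2 r)`.
#'
#' @param r recombination frequency in `[0, 0.5]`.
#' @param D_init initial gametic LD in `[-0.25, 0.25]`.
#' @param tol heterozygosity threshold declaring fixation (default 1e-12).
#' @param max_iter iteration cap (default 1e4).
#' @return The LD coefficient among the fully inbred lines.
#' @export
two_locus_selfing_fixpoint <- function(r, D_init, tol = 1e-12, max_iter = 1e4) {
  if (r < 0 || r > 0.5) stop_validation("r must lie in [0, 0.5]")
  if (abs(D_init) > 0.25) stop_validation("D_init must lie in [-0.25, 0.25]")
  # gametes: 1 = AB, 2 = Ab, 3 = aB, 4 = ab (alleles at the two loci)
  al <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  gam_idx <- function(a1, a2) which(al[, 1L] == a1 & al[, 2L] == a2)
  # meiosis output distribution of a diplotype (x, y)
  G <- array(0, c(4L, 4L, 4L))
  for (x in 1:4) for (y in 1:4) {
    p <- numeric(4L)
    p[x] <- p[x] + (1 - r) / 2
    p[y] <- p[y] + (1 - r) / 2
    rec1 <- gam_idx(al[x, 1L], al[y, 2L])
    rec2 <- gam_idx(al[y, 1L], al[x, 2L])
    p[rec1] <- p[rec1] + r / 2
    p[rec2] <- p[rec2] + r / 2
    G[x, y, ] <- p
  }
  f0 <- c(0.25 + D_init, 0.25 - D_init, 0.25 - D_init, 0.25 + D_init)
  if (any(f0 < -1e-12)) stop_validation("D_init incompatible with gamete frequencies")
  FF <- outer(f0, f0)                      # HWE diplotype frequencies
  for (it in seq_len(max_iter)) {
    if (1 - sum(diag(FF)) < tol) {
      fg <- diag(FF) / sum(diag(FF))
      return(fg[1L] - (fg[1L] + fg[2L]) * (fg[1L] + fg[3L]))
    }
    Fn <- matrix(0, 4L, 4L)
    for (x in 1:4) for (y in 1:4) {
      w <- FF[x, y]
      if (w > 0) Fn <- Fn + w * tcrossprod(G[x, y, ])
    }
    FF <- Fn
  }
  stop_numerical("selfing recursion did not fix within ", max_iter, " iterations")
}
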