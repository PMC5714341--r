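#' Define a mating system for line derivation
#'
#' A mating scheme describes how fully homozygous lines are derived from the
#' cross of two homozygous parents: either as doubled haploids (`"dh"`) taken
#' from gametes of the F1 (or of the population obtained after `t` generations
#' of random intermating of the F1), or as single-seed-descent inbreds
#' (`"ssd"`) derived by repeated selfing starting from the F2-equivalent stage
#' of that population.
#'
#' @param kind `"dh"` (doubled haploid) or `"ssd"` (single-seed descent).
#' @param t integer >= 0; generations of random intermating before line
#'   derivation (`t = 0` is the plain F1-DH / F2-SSD case).
#' @return An object of class `mating_scheme`.
#' @examples
#' mating_scheme("dh", t = 0)
#' mating_scheme("ssd", t = 2)
#' @export
mating_scheme <- function(kind = c("dh", "ssd"), t = 0L) {
  if (is.character(kind)) kind <- tolower(kind)
  kind <- match.arg(kind)
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0 || t != round(t))
    stop_validation("`t` must be a single integer >= 0, got: ", format(t))
  structure(list(kind = kind, t = as.integer(t)), class = "mating_scheme")
}

#' @export
print.mating_scheme <- function(x, ...) {
  lab <- if (x$kind == "dh") "(F1)^t-DH" else "(F2)^t-SSD"
  cat(sprintf("mating scheme: %s, %s with t = %d intermating generation(s)\n",
              toupper(x$kind), lab, x$t))
  invisible(x)
}

#' Haldane mapping function
#'
#' Converts a map distance into a recombination frequency assuming no
#' crossover interference: r = (1 - exp(-2 d)) / 2 with d in Morgans.
#' Distances are supplied in centiMorgans and divided by 100 internally;
#' this is the only place where the cM -> Morgan conversion happens.
#'
#' @param distance_cM nonnegative numeric vector of map distances in cM.
#' @return Recombination frequencies in `[0, 0.5)`.
#' @examples
#' haldane_r(0)    # 0
#' haldane_r(50)   # (1 - exp(-1)) / 2
#' @export
haldane_r <- function(distance_cM) {
  if (!is.numeric(distance_cM) || any(!is.finite(distance_cM)) || any(distance_cM < 0))
    stop_validation("map distances must be finite and >= 0 (in cM)")
  (1 - exp(-2 * distance_cM / 100)) / 2
}

#' Expected LD among doubled-haploid lines
#'
#' Expected linkage disequilibrium `D` between the parental-origin indicators
#' at two loci with recombination frequency `r`, among DH lines derived after
#' `t` generations of random intermating of the F1:
#' `D = (1 - 2 r) / 4 * (1 - r)^t`. The F1 value `(1 - 2r)/4` is reduced by
#' the factor `(1 - r)^t` per intermating generation.
#'
#' @param r recombination frequency in `[0, 0.5]` (vectorised).
#' @param t integer >= 0, intermating generations.
#' @return `D` in `[0, 0.25]`.
#' @export
ld_dh <- function(r, t = 0L) {
  check_r_t(r, t)
  (1 - 2 * r) / 4 * (1 - r)^t
}

#' Expected LD among single-seed-descent lines
#'
#' As [ld_dh()], but for fully inbred SSD lines derived from the
#' F2-equivalent population: the initial LD is additionally reduced by the
#' Haldane-Waddington factor `1 / (1 + 2 r)` accumulated over the selfing
#' generations, giving `D = (1 - 2 r) / (4 (1 + 2 r)) * (1 - r)^t`.
#'
#' @inheritParams ld_dh
#' @return `D` in `[0, 0.25]`; always `<=` [ld_dh()] with equality only at r = 0.
#' @export
ld_ssd <- function(r, t = 0L) {
  check_r_t(r, t)
  (1 - 2 * r) / 4 * (1 - r)^t / (1 + 2 * r)
}

check_r_t <- function(r, t) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < 0) || any(r > 0.5))
    stop_validation("recombination frequency r must lie in [0, 0.5]")
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0 || t != round(t))
    stop_validation("`t` must be a single integer >= 0")
  invisible(TRUE)
}

#' Conditional parental-origin probability from an LD coefficient
#'
#' `q = 1/2 + 2 D`: the probability that a locus carries the maternal allele
#' given that a second locus carries the maternal allele, expressed through
#' the expected LD `D` between the two parental-origin indicators (whose
#' marginal frequencies are 1/2 in a biparental cross).
#'
#' @param D LD coefficient in `[-0.25, 0.25]` (vectorised).
#' @return `q` in `[0, 1]`.
#' @export
q_from_ld <- function(D) {
  if (!is.numeric(D) || any(!is.finite(D)) || any(D < -0.25 - 1e-12) || any(D > 0.25 + 1e-12))
    stop_validation("LD coefficient D must lie in [-0.25, 0.25]")
  0.5 + 2 * D
}

#' Conditional parental-origin probability for a marker pair
#'
#' Composes the mapping function, the scheme-specific expected-LD formula and
#' `q = 1/2 + 2 D` to give the probability that two loci a given map distance
#' apart both carry the maternal allele in a derived line, conditional on the
#' first doing so. Loci on different chromosomes assort independently
#' (`D = 0`, `q = 1/2`); pass `distance_cM = Inf` or use [cross_variance()]
#' which handles chromosomes explicitly.
#'
#' @param scheme a [mating_scheme()].
#' @param distance_cM nonnegative map distance(s) in cM.
#' @param map_fun distance -> recombination-frequency function; Haldane's
#'   mapping function by default. Any function mapping cM to `[0, 0.5]`
#'   may be plugged in.
#' @return `q` in `[0.5, 1]` for the supported schemes.
#' @export
q_jk <- function(scheme, distance_cM, map_fun = haldane_r) {
  if (!inherits(scheme, "mating_scheme"))
    stop_validation("`scheme` must be a mating_scheme object")
  d <- as.vector(distance_cM)
  r <- numeric(length(d))
  inf <- is.infinite(d)
  r[inf] <- 0.5
  r[!inf] <- map_fun(d[!inf])
  D <- switch(scheme$kind, dh = ld_dh(r, scheme$t), ssd = ld_ssd(r, scheme$t))
  q <- q_from_ld(D)
  dim(q) <- dim(distance_cM)
  q
}
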