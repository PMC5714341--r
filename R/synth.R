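# Synthetic data generator: linkage maps, training panels with realistic
# marker-marker LD, phenotypes of known architecture, and homozygous
# candidate parents. Everything downstream is testable without external
# data.

#' Configuration for the synthetic data generator
#'
#' @param n_chromosomes number of chromosomes.
#' @param chr_length_cM length of each chromosome in cM.
#' @param n_markers_per_chr markers per chromosome; scalar or one value per
#'   chromosome.
#' @param n_training number of training lines.
#' @param n_parents number of homozygous candidate parents.
#' @param n_qtl number of markers given a nonzero true effect.
#' @param effect_sd standard deviation of the normal true-effect
#'   distribution (per allele dose, trait units).
#' @param beta0 trait intercept (trait units).
#' @param h2 heritability of the training phenotypes in `(0, 1]`; residual
#'   noise is scaled to match.
#' @param missing_rate fraction of training genotype cells set missing, in
#'   `[0, 1)`.
#' @param n_founders founder haplotypes the panel descends from.
#' @param n_mating_generations rounds of random mating applied to the
#'   founder pool before lines are derived (induces marker-marker LD).
#' @param n_pool size of the randomly mating pool.
#' @param seed integer RNG seed.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_chromosomes = 3L, chr_length_cM = 120, n_markers_per_chr = 20L,
                         n_training = 120L, n_parents = 8L, n_qtl = 15L,
                         effect_sd = 0.5, beta0 = 100, h2 = 0.8, missing_rate = 0.02,
                         n_founders = 16L, n_mating_generations = 3L, n_pool = 200L,
                         seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chr_length_cM = chr_length_cM,
              n_markers_per_chr = as.integer(n_markers_per_chr),
              n_training = as.integer(n_training), n_parents = as.integer(n_parents),
              n_qtl = as.integer(n_qtl), effect_sd = effect_sd, beta0 = beta0,
              h2 = h2, missing_rate = missing_rate,
              n_founders = as.integer(n_founders),
              n_mating_generations = as.integer(n_mating_generations),
              n_pool = as.integer(n_pool), seed = as.integer(seed))
  counts <- c(cfg$n_chromosomes, cfg$n_markers_per_chr, cfg$n_training,
              cfg$n_parents, cfg$n_qtl, cfg$n_founders, cfg$n_pool)
  if (any(counts < 1L)) stop_validation("all synth_config counts must be >= 1")
  if (cfg$n_mating_generations < 0L) stop_validation("n_mating_generations must be >= 0")
  if (!is.numeric(cfg$h2) || cfg$h2 <= 0 || cfg$h2 > 1)
    stop_validation("h2 must lie in (0, 1]")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop_validation("missing_rate must lie in [0, 1)")
  if (cfg$chr_length_cM <= 0) stop_validation("chr_length_cM must be > 0")
  if (length(cfg$n_markers_per_chr) != 1L &&
      length(cfg$n_markers_per_chr) != cfg$n_chromosomes)
    stop_validation("n_markers_per_chr must be scalar or one value per chromosome")
  if (cfg$n_qtl > sum(rep_len(cfg$n_markers_per_chr, cfg$n_chromosomes)))
    stop_validation("n_qtl exceeds the total marker count")
  structure(cfg, class = "synth_config")
}

#' A desk-scale mimic of the maize NAM dimensions
#'
#' 10 chromosomes of 140 cM (1400 cM genome), 325 markers (average spacing
#' ~4.3 cM), 258 training lines and 26 homozygous parents — the dimensions
#' of the maize nested-association-mapping setting in which one common
#' parent is crossed with 25 diverse lines.
#'
#' @param seed integer RNG seed stored in the config.
#' @return A `synth_config`.
#' @export
nam_like_preset <- function(seed = 1L) {
  synth_config(n_chromosomes = 10L, chr_length_cM = 140,
               n_markers_per_chr = c(rep(33L, 5L), rep(32L, 5L)),
               n_training = 258L, n_parents = 26L,
               n_qtl = 40L, effect_sd = 0.5, beta0 = 100, h2 = 0.8,
               missing_rate = 0.03, n_founders = 16L,
               n_mating_generations = 3L, n_pool = 200L, seed = seed)
}

#' Generate a complete synthetic dataset
#'
#' Markers are placed uniformly at random (then sorted) on each chromosome.
#' Founder haplotypes carry alleles at per-marker frequencies drawn from
#' Uniform(0.1, 0.9); a pool of individuals built from random founder
#' haplotype pairs is randomly mated for a few generations (using the
#' package's own meiosis simulator) so the panel carries realistic
#' marker-marker LD; training lines and candidate parents are then derived
#' as doubled haploids from the pool, hence fully homozygous. True effects
#' are normal at `n_qtl` randomly chosen markers; phenotypes are
#' `beta0 + Z u + e` with the residual variance set from `h2`. Missing
#' cells are introduced into the training genotypes only. Fully
#' reproducible from the config seed.
#'
#' @param config a [synth_config()].
#' @return List with `map` (`linkage_map`), `training` (dosage matrix),
#'   `pheno` (data frame `line`, `value`), `parents` (dosage matrix) and
#'   `true_effects` ([marker_effects()]).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  nmk <- rep_len(config$n_markers_per_chr, config$n_chromosomes)
  M <- sum(nmk)
  chrom <- rep(as.character(seq_len(config$n_chromosomes)), nmk)
  pos <- unlist(lapply(nmk, function(k) sort(stats::runif(k, 0, config$chr_length_cM))))
  markers <- sprintf("M%04d", seq_len(M))
  map <- linkage_map(markers, chrom, pos)
  # markers were generated sorted per chromosome, so map order == markers
  blocks <- chr_blocks(map, markers)

  p_allele <- stats::runif(M, 0.1, 0.9)
  founders <- matrix(stats::rbinom(config$n_founders * M, 1L, rep(p_allele, each = config$n_founders)),
                     config$n_founders, M, dimnames = list(NULL, markers))
  pool <- list(A = founders[sample.int(config$n_founders, config$n_pool, TRUE), , drop = FALSE],
               B = founders[sample.int(config$n_founders, config$n_pool, TRUE), , drop = FALSE])
  for (g in seq_len(config$n_mating_generations)) {
    mo <- sample.int(config$n_pool, config$n_pool, TRUE)
    fa <- sample.int(config$n_pool, config$n_pool, TRUE)
    pool <- list(A = draw_gametes(pool$A[mo, , drop = FALSE], pool$B[mo, , drop = FALSE], blocks),
                 B = draw_gametes(pool$A[fa, , drop = FALSE], pool$B[fa, , drop = FALSE], blocks))
  }
  derive_dh <- function(n, prefix) {
    rows <- sample.int(config$n_pool, n, TRUE)
    gam <- draw_gametes(pool$A[rows, , drop = FALSE], pool$B[rows, , drop = FALSE], blocks)
    out <- 2 * gam
    rownames(out) <- sprintf("%s%03d", prefix, seq_len(n))
    out
  }
  training <- derive_dh(config$n_training, "T")
  parents <- derive_dh(config$n_parents, "P")

  u <- stats::setNames(numeric(M), markers)
  qtl <- sample.int(M, config$n_qtl)
  u[qtl] <- stats::rnorm(config$n_qtl, 0, config$effect_sd)
  true_effects <- marker_effects(config$beta0, u, NA_real_)
  gval <- drop(training %*% u)
  var_g <- stats::var(gval)
  var_e <- if (var_g > 0) var_g * (1 - config$h2) / config$h2 else 1
  y <- config$beta0 + gval + stats::rnorm(config$n_training, 0, sqrt(var_e))
  pheno <- data.frame(line = rownames(training), value = y, stringsAsFactors = FALSE)

  if (config$missing_rate > 0) {
    drop_cells <- which(stats::runif(length(training)) < config$missing_rate)
    training[drop_cells] <- NA
  }
  list(map = map, training = training, pheno = pheno, parents = parents,
       true_effects = true_effects)
}
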