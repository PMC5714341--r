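# Comparison of analytical predictions with simulation estimates.

#' Compare analytical and simulated cross parameters
#'
#' Matches crosses by their parent pair and reports Pearson correlations
#' between the analytical and simulated means and variances, together with
#' the slopes of the simulated-on-analytical regressions (a slope away from
#' 1 flags systematic over- or under-estimation).
#'
#' @param analytical data frame with columns `parent1`, `parent2`, `mu`,
#'   `sigma2` (e.g. from [predict_all_crosses()] or
#'   [read_cross_predictions()]).
#' @param simulated data frame with columns `parent1`, `parent2`, `mu_sim`,
#'   `sigma2_sim` (e.g. read from a `simulate` output file).
#' @return A `cross_comparison`: list with `n_crosses`, `cor_mean`,
#'   `cor_variance`, `slope_mean`, `slope_variance` and the merged `table`.
#' @export
compare_predictions <- function(analytical, simulated) {
  need_a <- c("parent1", "parent2", "mu", "sigma2")
  need_s <- c("parent1", "parent2", "mu_sim", "sigma2_sim")
  if (!all(need_a %in% names(analytical)))
    stop_validation("analytical table lacks columns: ",
                    paste(setdiff(need_a, names(analytical)), collapse = ", "))
  if (!all(need_s %in% names(simulated)))
    stop_validation("simulated table lacks columns: ",
                    paste(setdiff(need_s, names(simulated)), collapse = ", "))
  key <- function(df) paste(pmin(df$parent1, df$parent2),
                            pmax(df$parent1, df$parent2), sep = " x ")
  ka <- key(analytical); ks <- key(simulated)
  extra_a <- setdiff(ka, ks); extra_s <- setdiff(ks, ka)
  if (length(extra_a) || length(extra_s))
    stop_validation("cross sets differ; only analytical: ",
                    paste(utils::head(extra_a, 3L), collapse = ", "),
                    "; only simulated: ",
                    paste(utils::head(extra_s, 3L), collapse = ", "))
  if (anyDuplicated(ka) || anyDuplicated(ks))
    stop_validation("duplicated crosses in input tables")
  m <- match(ka, ks)
  tab <- data.frame(cross = ka,
                    mu = analytical$mu, mu_sim = simulated$mu_sim[m],
                    sigma2 = analytical$sigma2, sigma2_sim = simulated$sigma2_sim[m],
                    stringsAsFactors = FALSE)
  slope <- function(x, y) {
    if (stats::var(x) == 0) return(NA_real_)
    stats::cov(x, y) / stats::var(x)
  }
  safe_cor <- function(x, y)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  structure(list(n_crosses = nrow(tab),
                 cor_mean = safe_cor(tab$mu, tab$mu_sim),
                 cor_variance = safe_cor(tab$sigma2, tab$sigma2_sim),
                 slope_mean = slope(tab$mu, tab$mu_sim),
                 slope_variance = slope(tab$sigma2, tab$sigma2_sim),
                 table = tab),
            class = "cross_comparison")
}

#' @export
print.cross_comparison <- function(x, ...) {
  cat(sprintf("cross comparison over %d crosses\n", x$n_crosses))
  cat(sprintf("  correlation of means:     %.4f (slope %.3f)\n", x$cor_mean, x$slope_mean))
  cat(sprintf("  correlation of variances: %.4f (slope %.3f)\n", x$cor_variance, x$slope_variance))
  invisible(x)
}

#' Write a comparison report (TSV table + text summary)
#' @param cmp a `cross_comparison`.
#' @param path output TSV path; a `.txt` summary is written alongside.
#' @export
write_comparison <- function(cmp, path) {
  stopifnot(inherits(cmp, "cross_comparison"))
  tab <- cmp$table
  for (num in c("mu", "mu_sim", "sigma2", "sigma2_sim")) tab[[num]] <- fmt10(tab[[num]])
  write_tsv_checked(tab, path)
  txt <- sub("\\.tsv$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  writeLines(c(sprintf("crosses: %d", cmp$n_crosses),
               sprintf("cor_mean: %.6f", cmp$cor_mean),
               sprintf("cor_variance: %.6f", cmp$cor_variance),
               sprintf("slope_mean: %.6f", cmp$slope_mean),
               sprintf("slope_variance: %.6f", cmp$slope_variance)), txt)
  invisible(path)
}

#' End-to-end validation of the closed formulas against simulation
#'
#' Generates the NAM-like synthetic dataset ([nam_like_preset()]), runs QC
#' and RR-BLUP effect estimation on the training panel, predicts the mean
#' and segregation variance of the crosses of the first candidate parent
#' with every other parent analytically (F1-DH by default), estimates the
#' same quantities by Monte Carlo simulation of derived progeny with the
#' identical marker effects, and reports the correlations between the two
#' routes across crosses.
#'
#' @param seed integer seed driving the dataset and all simulations.
#' @param scheme a [mating_scheme()] (default F1-DH, t = 0).
#' @param n_progeny progeny per simulated replicate (default 200).
#' @param n_reps replicate populations per cross (default 25).
#' @param lambda_policy passed to [choose_lambda()] (default REML).
#' @param config optional [synth_config()] overriding the NAM-like preset
#'   (its own seed field is replaced by `seed`).
#' @return A `cross_comparison` (see [compare_predictions()]) with the
#'   fitted effects attached as attribute `effects`.
#' @export
validate_against_simulation <- function(seed = 1L, scheme = mating_scheme("dh", 0L),
                                        n_progeny = 200L, n_reps = 25L,
                                        lambda_policy = "reml", config = NULL) {
  cfg <- if (is.null(config)) nam_like_preset(seed = seed) else {
    config$seed <- as.integer(seed); config
  }
  dat <- generate_dataset(cfg)
  lines_qc <- filter_lines(dat$training)
  markers_qc <- filter_markers(lines_qc$geno)
  geno <- impute_missing(markers_qc$geno)
  pheno <- dat$pheno[dat$pheno$line %in% rownames(geno), ]
  lambda <- choose_lambda(geno, pheno, lambda_policy)
  eff <- rrblup_solve(geno, pheno, lambda)

  ids <- rownames(dat$parents)
  others <- ids[-1L]
  ana <- sim <- vector("list", length(others))
  for (k in seq_along(others)) {
    pmat <- dat$parents[c(ids[1L], others[k]), , drop = FALSE]
    cpe <- cross_parent_effects(pmat[1L, ], pmat[2L, ], eff,
                                p1_id = ids[1L], p2_id = others[k])
    mu <- cross_mean(cpe)
    s2 <- cross_variance(cpe, dat$map, scheme)
    ana[[k]] <- data.frame(parent1 = ids[1L], parent2 = others[k],
                           mu = mu, sigma2 = s2, stringsAsFactors = FALSE)
    pops <- simulate_cross_replicates(pmat, dat$map, scheme,
                                      n_progeny = n_progeny, n_reps = n_reps,
                                      seed = seed + 1000L * k)
    est <- mc_variance_estimate(pops, eff)
    sim[[k]] <- data.frame(parent1 = ids[1L], parent2 = others[k],
                           mu_sim = est$mean, sigma2_sim = est$variance,
                           stringsAsFactors = FALSE)
  }
  cmp <- compare_predictions(do.call(rbind, ana), do.call(rbind, sim))
  attr(cmp, "effects") <- eff
  cmp
}
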