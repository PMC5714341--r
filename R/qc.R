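# Marker/line quality control for the training panel.

#' Gene diversity (expected heterozygosity)
#'
#' `1 - sum(p_i^2)` for a vector of allele frequencies. For a biallelic
#' marker this is `2 p (1 - p)`, maximal (0.5) at p = 0.5.
#'
#' @param allele_freqs numeric vector of allele frequencies in `[0, 1]`
#'   summing to 1 (within 1e-9).
#' @return Gene diversity in `[0, 1 - 1/k]` for `k` alleles.
#' @examples
#' gene_diversity(c(0.5, 0.5))  # 0.5
#' gene_diversity(c(0.9, 0.1))  # 0.18
#' @export
gene_diversity <- function(allele_freqs) {
  if (!is.numeric(allele_freqs) || any(!is.finite(allele_freqs)) ||
      any(allele_freqs < 0) || any(allele_freqs > 1))
    stop_validation("allele frequencies must lie in [0, 1]")
  if (abs(sum(allele_freqs) - 1) > 1e-9)
    stop_validation("allele frequencies must sum to 1 (got ",
                    format(sum(allele_freqs)), ")")
  1 - sum(allele_freqs^2)
}

# allele frequency of the counted allele per marker column (dosage / 2),
# from non-missing cells; heterozygous calls contribute one allele of each type
marker_allele_freq <- function(geno) colMeans(geno, na.rm = TRUE) / 2

marker_gene_diversity <- function(geno) {
  p <- marker_allele_freq(geno)
  2 * p * (1 - p)
}

#' Filter markers of a training panel
#'
#' Keeps markers that are (in this order of precedence when reporting the
#' reason for removal): polymorphic, have a missing fraction strictly below
#' `max_missing` ("less than 10%"), and have a gene diversity of at least
#' `min_gene_diversity`. A marker failing several filters is counted once,
#' under the first failed filter. Gene diversity is computed from non-missing
#' dosages with allele frequency `p = mean(dosage) / 2`.
#'
#' @param geno numeric lines x markers dosage matrix (0/1/2/NA).
#' @param max_missing markers with missing fraction `>= max_missing` are
#'   removed (strict "less than" retention); default 0.10.
#' @param min_gene_diversity minimum gene diversity to retain; default 0.1.
#' @return List with `geno` (the filtered matrix) and `report` (a
#'   `qc_report`).
#' @export
filter_markers <- function(geno, max_missing = 0.10, min_gene_diversity = 0.1) {
  if (is.null(geno) || nrow(geno) == 0L || ncol(geno) == 0L)
    stop_validation("empty genotype matrix")
  p <- marker_allele_freq(geno)
  gd <- 2 * p * (1 - p)
  miss <- colMeans(is.na(geno))
  mono <- p <= 0 | p >= 1 | !is.finite(p)
  too_missing <- !mono & miss >= max_missing
  low_div <- !mono & !too_missing & gd < min_gene_diversity
  keep <- !(mono | too_missing | low_div)
  report <- qc_report(
    stage = "markers", n_in = ncol(geno), n_out = sum(keep),
    removed = c(monomorphic = sum(mono), missingness = sum(too_missing),
                diversity = sum(low_div)),
    gene_diversity = gd)
  if (!any(keep))
    stop_validation("all markers removed by QC (",
                    paste(names(report$removed), report$removed,
                          sep = "=", collapse = ", "), ")")
  list(geno = geno[, keep, drop = FALSE], report = report)
}

#' Filter lines of a training panel
#'
#' Keeps lines whose fraction of missing marker calls is at most
#' `max_missing`; a line at exactly the threshold is kept (removal requires
#' "more than 10%" missing data).
#'
#' @inheritParams filter_markers
#' @param max_missing lines with missing fraction `> max_missing` are
#'   removed; default 0.10.
#' @return List with `geno` and `report` as in [filter_markers()].
#' @export
filter_lines <- function(geno, max_missing = 0.10) {
  if (is.null(geno) || nrow(geno) == 0L || ncol(geno) == 0L)
    stop_validation("empty genotype matrix")
  miss <- rowMeans(is.na(geno))
  keep <- miss <= max_missing
  report <- qc_report(stage = "lines", n_in = nrow(geno), n_out = sum(keep),
                      removed = c(missingness = sum(!keep)))
  if (!any(keep)) stop_validation("all lines removed by QC")
  list(geno = geno[keep, , drop = FALSE], report = report)
}

qc_report <- function(stage, n_in, n_out, removed, gene_diversity = NULL) {
  if (n_in - n_out != sum(removed))
    stop_numerical("inconsistent QC report: removals do not sum to in - out")
  structure(list(stage = stage, n_in = n_in, n_out = n_out,
                 removed = removed, gene_diversity = gene_diversity),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC [%s]: %d in, %d out (%d removed)\n",
              x$stage, x$n_in, x$n_out, x$n_in - x$n_out))
  for (nm in names(x$removed))
    cat(sprintf("  removed, %s: %d\n", nm, x$removed[[nm]]))
  invisible(x)
}

#' Serialize a QC report as key/value TSV rows
#' @param report a `qc_report`.
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  rows <- data.frame(
    key = c("stage", "n_in", "n_out",
            paste0("removed_", names(report$removed))),
    value = c(report$stage, report$n_in, report$n_out,
              unname(report$removed)),
    stringsAsFactors = FALSE)
  write_tsv_checked(rows, path)
}
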