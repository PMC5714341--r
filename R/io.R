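# Tabular file formats. All files are tab-separated UTF-8; `NA` is the
# missing-value sentinel and `.` is also accepted on read.

#' Read a linkage map
#'
#' Reads a TSV with columns `marker`, `chrom`, `pos_cM`. Markers are
#' re-sorted by position within each chromosome (stable sort); the order in
#' which chromosomes first appear in the file is preserved. Chromosome labels
#' are opaque strings, so labels like `"1A"` are fine.
#'
#' @param path path to the map file.
#' @return A `linkage_map`: a data frame with columns `marker` (unique),
#'   `chrom` and `pos_cM` (finite, >= 0), sorted within chromosome.
#' @export
read_linkage_map <- function(path) {
  if (!file.exists(path)) stop_io("linkage map file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric"))
  need <- c("marker", "chrom", "pos_cM")
  if (!identical(names(df)[seq_along(need)], need))
    stop_io("map file must have header `marker\tchrom\tpos_cM`, got: ",
            paste(names(df), collapse = ", "))
  linkage_map(df$marker, df$chrom, df$pos_cM)
}

#' Construct and validate a linkage map
#'
#' @param marker character vector of unique marker names.
#' @param chrom character vector of chromosome labels.
#' @param pos_cM numeric positions in centiMorgans, finite and >= 0.
#' @return A `linkage_map` data frame (see [read_linkage_map()]).
#' @export
linkage_map <- function(marker, chrom, pos_cM) {
  marker <- as.character(marker); chrom <- as.character(chrom)
  if (length(chrom) == 1L) chrom <- rep(chrom, length(marker))
  if (length(chrom) != length(marker) || length(pos_cM) != length(marker))
    stop_validation("marker, chrom and pos_cM must have equal lengths")
  if (anyDuplicated(marker))
    stop_validation("duplicated marker name(s) in map: ",
                    paste(unique(marker[duplicated(marker)]), collapse = ", "))
  if (!is.numeric(pos_cM) || any(!is.finite(pos_cM)) || any(pos_cM < 0))
    stop_validation("map positions must be finite and >= 0 (cM)")
  if (length(marker) == 0L) stop_validation("empty linkage map")
  chrom_order <- unique(chrom)
  ord <- order(match(chrom, chrom_order), pos_cM)
  df <- data.frame(marker = marker[ord], chrom = chrom[ord], pos_cM = pos_cM[ord],
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  class(df) <- c("linkage_map", "data.frame")
  df
}

#' Write a linkage map to TSV
#' @param map a `linkage_map`.
#' @param path output path.
#' @export
write_linkage_map <- function(map, path) {
  stopifnot(inherits(map, "linkage_map"))
  write_tsv_checked(data.frame(marker = map$marker, chrom = map$chrom,
                               pos_cM = fmt10(map$pos_cM)), path)
}

#' Read a genotype matrix
#'
#' Reads a TSV whose first column is `line` and whose remaining columns are
#' marker names; cells are allele dosages in `{0, 1, 2}` with `NA` or `.` for
#' missing. Marker columns are reordered to follow the linkage-map order.
#' Markers in the file but absent from the map are an error; map markers
#' absent from the file are dropped from downstream use with a warning.
#'
#' @param path path to the genotype file.
#' @param map a `linkage_map` the markers must belong to.
#' @return Numeric matrix, lines x markers, `rownames` = line ids,
#'   `colnames` = marker names in map order; entries 0/1/2/NA.
#' @export
read_genotypes <- function(path, map) {
  if (!file.exists(path)) stop_io("genotype file not found: ", path)
  stopifnot(inherits(map, "linkage_map"))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE)
  if (names(df)[1L] != "line")
    stop_io("first column of a genotype file must be `line`")
  lines <- df[[1L]]
  if (anyDuplicated(lines))
    stop_validation("duplicated line id(s): ",
                    paste(unique(lines[duplicated(lines)]), collapse = ", "))
  markers <- names(df)[-1L]
  unknown <- setdiff(markers, map$marker)
  if (length(unknown))
    stop_validation("genotype file contains markers absent from the map: ",
                    paste(utils::head(unknown, 5L), collapse = ", "))
  absent <- setdiff(map$marker, markers)
  if (length(absent))
    warning(sprintf("%d map marker(s) absent from genotype file are dropped downstream (e.g. %s)",
                    length(absent), paste(utils::head(absent, 3L), collapse = ", ")),
            call. = FALSE)
  cells <- as.matrix(df[, -1L, drop = FALSE])
  cells[cells %in% c(".", "", "NA")] <- NA_character_
  bad <- !is.na(cells) & !(cells %in% c("0", "1", "2"))
  if (any(bad))
    stop_validation("invalid genotype cell value(s): ",
                    paste(utils::head(unique(cells[bad]), 5L), collapse = ", "),
                    " (allowed: 0, 1, 2, NA, .)")
  geno <- matrix(as.numeric(cells), nrow = nrow(cells),
                 dimnames = list(lines, markers))
  keep <- intersect(map$marker, markers)   # map order
  geno[, keep, drop = FALSE]
}

#' Write a genotype matrix to TSV
#' @param geno numeric matrix, lines x markers, entries 0/1/2/NA.
#' @param path output path.
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(line = rownames(geno), geno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_checked(df, path)
}

#' Read a phenotype table
#'
#' TSV with columns `line` and `value`; one finite value per line.
#'
#' @param path path to the phenotype file.
#' @return Data frame with character `line` and numeric `value`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop_io("phenotype file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric"))
  if (!identical(names(df)[1:2], c("line", "value")))
    stop_io("phenotype file must have header `line\tvalue`")
  if (anyDuplicated(df$line))
    stop_validation("duplicated line id(s) in phenotype table")
  if (any(!is.finite(df$value)))
    stop_validation("phenotype values must be finite")
  df[, c("line", "value")]
}

#' Write a phenotype table to TSV
#' @param pheno data frame with columns `line`, `value`.
#' @param path output path.
#' @export
write_phenotypes <- function(pheno, path) {
  write_tsv_checked(data.frame(line = pheno$line, value = fmt10(pheno$value)), path)
}

#' Construct a marker-effects object
#'
#' @param intercept the additive-model intercept (beta0).
#' @param effects named numeric vector of per-marker additive effects
#'   (effect per allele dose; dosage coding 0/1/2).
#' @param lambda_used the ridge shrinkage parameter the effects were
#'   estimated with (`NA` if unknown, e.g. external effects).
#' @return Object of class `marker_effects`.
#' @export
marker_effects <- function(intercept, effects, lambda_used = NA_real_) {
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept))
    stop_validation("intercept must be a single finite number")
  if (is.null(names(effects)) || anyDuplicated(names(effects)))
    stop_validation("effects must be a named vector with unique marker names")
  if (any(!is.finite(effects))) stop_validation("marker effects must be finite")
  if (!is.na(lambda_used) && lambda_used <= 0)
    stop_validation("lambda_used must be > 0")
  structure(list(intercept = unname(intercept), effects = effects,
                 lambda_used = lambda_used, coding = "dosage {0,1,2}"),
            class = "marker_effects")
}

#' @export
print.marker_effects <- function(x, ...) {
  cat(sprintf("marker_effects: %d markers, intercept %.6g, lambda %s\n",
              length(x$effects), x$intercept,
              if (is.na(x$lambda_used)) "NA" else format(x$lambda_used)))
  invisible(x)
}

#' Read marker effects from TSV
#'
#' Columns `marker`, `effect`. The intercept is stored as the reserved row
#' `__intercept__`; an optional reserved row `__lambda__` carries the ridge
#' parameter so a write/read round trip preserves it.
#'
#' @param path path to effects file.
#' @return A [marker_effects()] object.
#' @export
read_effects <- function(path) {
  if (!file.exists(path)) stop_io("effects file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric"))
  if (!identical(names(df)[1:2], c("marker", "effect")))
    stop_io("effects file must have header `marker\teffect`")
  i <- match("__intercept__", df$marker)
  if (is.na(i)) stop_validation("effects file lacks the reserved `__intercept__` row")
  l <- match("__lambda__", df$marker)
  lambda <- if (is.na(l)) NA_real_ else df$effect[l]
  keep <- setdiff(seq_len(nrow(df)), c(i, l))
  eff <- stats::setNames(df$effect[keep], df$marker[keep])
  marker_effects(df$effect[i], eff, lambda)
}

#' Write marker effects to TSV
#' @param effects a [marker_effects()] object.
#' @param path output path.
#' @export
write_effects <- function(effects, path) {
  stopifnot(inherits(effects, "marker_effects"))
  rows <- data.frame(
    marker = c("__intercept__",
               if (!is.na(effects$lambda_used)) "__lambda__",
               names(effects$effects)),
    effect = fmt10(c(effects$intercept,
                     if (!is.na(effects$lambda_used)) effects$lambda_used,
                     unname(effects$effects))),
    stringsAsFactors = FALSE)
  write_tsv_checked(rows, path)
}

#' Write cross predictions to TSV
#'
#' One row per cross with header
#' `parent1 parent2 scheme t mu sigma2 sigma s U`; floats are rendered with
#' 10 significant digits; the input row order is preserved.
#'
#' @param predictions a `cross_prediction` data frame from
#'   [predict_all_crosses()] (or any data frame with those columns).
#' @param path output path.
#' @export
write_cross_predictions <- function(predictions, path) {
  if (is.null(predictions) || nrow(predictions) == 0L)
    stop_validation("no cross predictions to write")
  cols <- c("parent1", "parent2", "scheme", "t", "mu", "sigma2", "sigma", "s", "U")
  if (!all(cols %in% names(predictions)))
    stop_validation("predictions lack required columns: ",
                    paste(setdiff(cols, names(predictions)), collapse = ", "))
  out <- predictions[, cols]
  for (num in c("mu", "sigma2", "sigma", "s", "U")) out[[num]] <- fmt10(out[[num]])
  write_tsv_checked(out, path)
}

#' Read cross predictions written by [write_cross_predictions()]
#' @param path path to a crosses TSV.
#' @return Data frame with the prediction columns, numeric where appropriate.
#' @export
read_cross_predictions <- function(path) {
  if (!file.exists(path)) stop_io("cross-prediction file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "character",
                                         "integer", rep("numeric", 5L)))
  need <- c("parent1", "parent2", "scheme", "t", "mu", "sigma2", "sigma", "s", "U")
  if (!all(need %in% names(df)))
    stop_io("not a cross-prediction file: ", path)
  df[, need]
}

#' Read a YAML run configuration
#'
#' Recognised keys: `scheme` ("dh"/"ssd"), `t`, `p` (selected fraction),
#' `h2` (heritability; its square root is used in the usefulness criterion),
#' `lambda` (positive number or the string "reml"), `seed`, and input/output
#' paths (`map`, `geno`, `pheno`, `effects`, `out`). Missing keys fall back
#' to the defaults shown below.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(scheme = "dh", t = 0L, p = 0.05, h2 = 1.0, lambda = "reml",
                   seed = 1L, map = NULL, geno = NULL, pheno = NULL,
                   effects = NULL, out = NULL)
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop_io("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (!is.list(user)) stop_io("config file must be a YAML mapping")
  utils::modifyList(defaults, user)
}

# -- internal helpers ---------------------------------------------------------

fmt10 <- function(x) sprintf("%.10g", x)

write_tsv_checked <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_io("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}
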