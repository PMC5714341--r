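# Ridge-regression BLUP of additive marker effects.
#
# Model: y = 1 beta0 + Z u + e, with Z the lines x markers dosage matrix
# (raw 0/1/2 dosages; the explicit intercept absorbs the column means) and a
# common ridge penalty lambda = sigma_e^2 / sigma_u^2 on u. The estimates
# solve the symmetric mixed-model equations
#   [ 1'1   1'Z        ] [beta0]   [1'y]
#   [ Z'1   Z'Z + l I  ] [  u  ] = [Z'y].

#' Mean-impute missing dosages
#'
#' Replaces each missing cell by the marker's mean dosage over non-missing
#' lines. Intended for the residual missingness left after QC.
#'
#' @param geno numeric lines x markers dosage matrix (0/1/2/NA).
#' @return The matrix with no missing cells.
#' @export
impute_missing <- function(geno) {
  if (!anyNA(geno)) return(geno)
  mu <- colMeans(geno, na.rm = TRUE)
  dead <- !is.finite(mu)
  if (any(dead))
    stop_validation("marker(s) with no observed dosage (should have been filtered): ",
                    paste(utils::head(colnames(geno)[dead], 5L), collapse = ", "))
  idx <- which(is.na(geno), arr.ind = TRUE)
  geno[idx] <- mu[idx[, 2L]]
  geno
}

#' Estimate marker effects by RR-BLUP
#'
#' Solves the mixed-model equations exactly (direct symmetric solve of the
#' (m+1)-dimensional system, or the equivalent n-dimensional dual form for
#' wide panels; both give identical answers). Deterministic for fixed input.
#'
#' @param geno numeric lines x markers dosage matrix without missing cells
#'   (run [impute_missing()] first); rownames are line ids.
#' @param pheno data frame with columns `line`, `value`; every phenotyped
#'   line must be genotyped.
#' @param lambda positive ridge parameter (`sigma_e^2 / sigma_u^2`); see
#'   [choose_lambda()].
#' @param method `"auto"` picks the direct solve when markers do not
#'   heavily outnumber lines, otherwise the dual (n x n) solve.
#' @return A [marker_effects()] object.
#' @export
rrblup_solve <- function(geno, pheno, lambda,
                         method = c("auto", "direct", "dual")) {
  method <- match.arg(method)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) || lambda <= 0)
    stop_validation("lambda must be a single positive number")
  if (anyNA(geno))
    stop_validation("genotype matrix contains missing dosages; run impute_missing() first")
  missing_lines <- setdiff(pheno$line, rownames(geno))
  if (length(missing_lines))
    stop_validation("phenotyped line(s) without genotypes: ",
                    paste(utils::head(missing_lines, 5L), collapse = ", "))
  if (nrow(pheno) < 2L) stop_validation("need at least 2 phenotyped lines")
  Z <- geno[pheno$line, , drop = FALSE]
  y <- pheno$value
  n <- nrow(Z); m <- ncol(Z)
  if (method == "auto") method <- if (m > 2L * n) "dual" else "direct"
  sol <- switch(method,
    direct = {
      C <- rbind(c(n, colSums(Z)),
                 cbind(colSums(Z), crossprod(Z) + lambda * diag(m)))
      rhs <- c(sum(y), crossprod(Z, y))
      tryCatch(drop(solve(C, rhs)),
               error = function(e)
                 stop_numerical("mixed-model equations are singular: ",
                                conditionMessage(e)))
    },
    dual = {
      # ridge on centered data; the intercept absorbs the means
      Zc <- sweep(Z, 2L, colMeans(Z))
      yc <- y - mean(y)
      K <- tcrossprod(Zc) + lambda * diag(n)
      a <- tryCatch(solve(K, yc),
                    error = function(e)
                      stop_numerical("dual system is singular: ",
                                     conditionMessage(e)))
      u <- drop(crossprod(Zc, a))
      b0 <- mean(y) - sum(colMeans(Z) * u)
      c(b0, u)
    })
  marker_effects(sol[1L], stats::setNames(sol[-1L], colnames(Z)), lambda)
}

#' Choose the ridge parameter
#'
#' `policy = list(kind = "fixed", value = x)` returns `x` unchanged (exact
#' reproducibility). `policy = list(kind = "reml")` (or the string `"reml"`)
#' estimates `lambda = sigma_e^2 / sigma_u^2` by restricted maximum
#' likelihood for the equivalent random-effects model, profiling the REML
#' criterion over `log(lambda)` in `[-10, 10]` (tolerance 1e-8) via the
#' eigendecomposition of the intercept-projected `Z Z'`.
#'
#' @inheritParams rrblup_solve
#' @param policy `"reml"`, `list(kind = "reml")`, or
#'   `list(kind = "fixed", value = <positive number>)`.
#' @return A positive lambda. A REML optimum pinned at a bracket end is
#'   returned with a warning (it signals essentially zero genetic or
#'   residual variance).
#' @export
choose_lambda <- function(geno, pheno, policy = "reml") {
  if (is.character(policy)) policy <- list(kind = policy)
  kind <- tolower(policy$kind %||% "reml")
  if (kind == "fixed") {
    v <- policy$value
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop_validation("fixed lambda policy needs a single positive `value`")
    return(v)
  }
  if (kind != "reml") stop_validation("unknown lambda policy: ", kind)
  if (anyNA(geno))
    stop_validation("genotype matrix contains missing dosages; run impute_missing() first")
  missing_lines <- setdiff(pheno$line, rownames(geno))
  if (length(missing_lines))
    stop_validation("phenotyped line(s) without genotypes: ",
                    paste(utils::head(missing_lines, 5L), collapse = ", "))
  Z <- geno[pheno$line, , drop = FALSE]
  y <- pheno$value
  n <- nrow(Z)
  if (n < 3L) stop_validation("REML needs at least 3 lines")
  # basis orthogonal to the intercept
  Q <- qr.Q(qr(matrix(1, n, 1L)), complete = TRUE)[, -1L, drop = FALSE]
  Zs <- crossprod(Q, Z)
  ee <- eigen(tcrossprod(Zs), symmetric = TRUE)
  th <- pmax(ee$values, 0)
  w2 <- drop(crossprod(ee$vectors, crossprod(Q, y)))^2
  nr <- n - 1L
  nll <- function(loglam) {
    d <- th + exp(loglam)
    s2u <- sum(w2 / d) / nr
    0.5 * (nr * log(s2u) + sum(log(d)))
  }
  lo <- -10; hi <- 10
  opt <- stats::optimize(nll, c(lo, hi), tol = 1e-8)
  if (!is.finite(opt$objective))
    stop_numerical("REML criterion non-finite over log(lambda) in [", lo, ", ", hi, "]")
  if (opt$minimum < lo + 1e-4 || opt$minimum > hi - 1e-4)
    warning(sprintf("REML optimum at the log(lambda) bracket end [%g, %g]; variance ratio poorly identified", lo, hi),
            call. = FALSE)
  exp(opt$minimum)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
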