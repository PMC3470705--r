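#' Single-locus logistic regression scores
#'
#' The traditional GWAS benchmark: each SNP is tested alone in a logistic
#' regression against an intercept-only model with a 1-df likelihood ratio
#' test, and scored as -log10 of the chi-squared p-value.  Individuals
#' missing the SNP's genotype are dropped for that SNP only
#' (per-SNP complete cases).
#'
#' @param X genotype matrix (missing entries allowed).
#' @param y binary 0/1 response.
#' @param max_logp cap on the score under (quasi-)separation, where the
#'   p-value underflows; capped SNPs are reported in a message.
#' @return a [score_table()] with method \code{"single-locus"}.
#' @export
single_locus_scores <- function(X, y, max_logp = 300) {
  y <- as_case_control(y)
  Xm <- unclass(X)
  scores <- vapply(seq_len(ncol(Xm)), function(j) {
    xj <- Xm[, j]
    ok <- !is.na(xj)
    yj <- y[ok]; xj <- xj[ok]
    if (length(unique(xj)) < 2L || length(unique(yj)) < 2L) return(0)
    fit <- suppressWarnings(
      stats::glm(yj ~ xj, family = stats::binomial()))
    lr <- max(0, fit$null.deviance - fit$deviance)
    -stats::pchisq(lr, df = 1, lower.tail = FALSE, log.p = TRUE) / log(10)
  }, numeric(1))
  capped <- scores > max_logp
  if (any(capped))
    message(sum(capped), " SNP(s) at or beyond separation; logP capped at ",
            max_logp)
  scores[capped] <- max_logp
  score_table(colnames(Xm) %||% paste0("snp_", seq_len(ncol(Xm))),
              scores, method = "single-locus", positions = positions(X))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stability selection over a shared global penalty grid
#'
#' The global-penalty competitor: one penalty grid is computed from the
#' full data's [lambda_max()], every subsample's LASSO path is fit on that
#' shared grid, and for each grid value the RMIP of SNP j is the fraction
#' of the K subsamples in which its coefficient is active.  The result is
#' the "stability path": RMIPs as a function of the free global penalty.
#'
#' @inheritParams llarrma
#' @param nlambda,min_ratio grid construction from the full-data
#'   \code{lambda_max}.
#' @return object of class \code{"stability_path"}: list with
#'   \code{lambda} (the shared grid) and \code{rmip} (grid_length x m
#'   matrix of selection frequencies, multiples of 1/K).
#' @export
stability_selection <- function(X, y, K = 100L, phi = 0.5,
                                nlambda = 100L, min_ratio = 0.001,
                                thresh = 1e-12, seed = 1L) {
  y <- as_case_control(y)
  if (anyNA(unclass(X)))
    stop("genotype matrix has missing entries; impute first")
  cc <- center_columns(X)
  lmax <- lambda_max(cc$centered, y)
  if (lmax <= 0) stop("response carries no signal at any penalty")
  grid <- lambda_grid(lmax, nlambda, min_ratio)
  m <- ncol(X)
  counts <- matrix(0L, length(grid), m)
  for (k in seq_len(K)) {
    set.seed(subsample_seed(seed, k))
    sub <- draw_subsample(y, phi)
    ys <- as.numeric(y)[sub$indices]
    cck <- center_columns(unclass(X)[sub$indices, , drop = FALSE])
    path <- fit_lasso_path(cck$centered, ys, grid, thresh = thresh)
    counts <- counts + t(abs(path$beta) > 1e-8)
  }
  ids <- colnames(X) %||% paste0("snp_", seq_len(m))
  structure(list(lambda = grid, rmip = counts / K, K = K, phi = phi,
                 seed = seed, snp_ids = ids, positions = positions(X)),
            class = "stability_path")
}

#' @export
print.stability_path <- function(x, ...) {
  cat(sprintf(
    "stability_path: %d SNPs, %d grid penalties, K = %d subsamples\n",
    ncol(x$rmip), length(x$lambda), x$K))
  invisible(x)
}

#' Oracle calibration of the stability-selection penalty
#'
#' Stability selection leaves its global penalty free; for benchmarking,
#' the "oracle" calibration picks the grid penalty whose RMIPs maximize a
#' truth-dependent criterion -- by default the initial AUC (windowed ROC
#' area over false-positive rates in [0, 0.05]) against the known true
#' signals.  This deliberately unfair calibration requires foreknowledge
#' of the truth and gives stability selection its best possible showing.
#' Constant RMIP rows score 0 by convention; ties go to the largest
#' penalty.
#'
#' @param path a [stability_selection()] result.
#' @param truth binary m-vector, 1 for true signal SNPs (at least one of
#'   each class).
#' @param window false-positive-rate window of the AUC criterion;
#'   \code{c(0, 1)} gives the full-AUC oracle.
#' @return list with \code{lambda} (the selected penalty), \code{rmip}
#'   (its RMIP vector), \code{criterion} (the per-grid-row criterion
#'   values) and \code{index}.
#' @export
oracle_lambda <- function(path, truth, window = c(0, 0.05)) {
  stopifnot(inherits(path, "stability_path"))
  truth <- as.integer(truth)
  if (sum(truth == 1L) < 1L || sum(truth == 0L) < 1L)
    stop("truth needs at least one true signal and one background SNP")
  crit <- vapply(seq_along(path$lambda), function(g) {
    r <- path$rmip[g, ]
    if (length(unique(r)) < 2L) return(0)
    trial_auc(r, truth, a = window[1L], b = window[2L])
  }, numeric(1))
  best <- which(crit == max(crit))[1L]  # grid decreasing: first = largest
  list(lambda = path$lambda[best], rmip = path$rmip[best, ],
       criterion = crit, index = best)
}
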