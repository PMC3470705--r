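#' Permutation selection of the local penalty
#'
#' The discovery-calibrated criterion: a penalty that would tend to select
#' no SNPs were the response unrelated to the genotypes.  For each of S
#' permutations of the subsample's response, the smallest all-zeroing
#' penalty [lambda_max()] of the subsample's centered design is computed;
#' the selected penalty is the median of the S values (for even S, the
#' mean of the two central values).
#'
#' @param X complete genotype matrix (full data; the subsample rows are
#'   extracted internally).
#' @param y binary 0/1 response for all individuals.
#' @param sub a [draw_subsample()] result.
#' @param S number of response permutations (>= 1).
#' @return list with \code{lambda} (the selected penalty) and
#'   \code{samples} (the S per-permutation zeroing penalties).
#' @export
select_lambda_perm <- function(X, y, sub, S = 25L) {
  if (S < 1L) stop("S must be at least 1")
  ys <- as.numeric(y)[sub$indices]
  cc <- center_columns(unclass(X)[sub$indices, , drop = FALSE])
  lams <- vapply(seq_len(S), function(s)
    lambda_max(cc$centered, permute_response(ys)), numeric(1))
  list(lambda = stats::median(lams), samples = lams)
}

#' Complement deviance selection of the local penalty
#'
#' The predictive criterion: fit the LASSO path on the subsample, then
#' pick the penalty minimizing the binomial deviance
#' \deqn{-2 \sum_{i \in \bar k}\left[y_i \log \hat p_i + (1 - y_i)
#' \log(1 - \hat p_i)\right]} over the complement of the subsample, where
#' \eqn{\hat p_i} applies the subsample-fit intercept and coefficients to
#' complement rows centered by the subsample's column means.  Ties go to
#' the largest (sparsest) penalty.
#'
#' @inheritParams select_lambda_perm
#' @param nlambda,min_ratio path grid construction (see [lambda_grid()]).
#' @param thresh solver convergence threshold (see [fit_lasso_path()]).
#' @return list with \code{lambda}, \code{grid}, \code{deviance} (the
#'   complement-deviance curve over the grid) and the fitted \code{path}.
#' @export
select_lambda_cdev <- function(X, y, sub, nlambda = 100L,
                               min_ratio = 0.001, thresh = 1e-12) {
  if (length(sub$complement) == 0L)
    stop("complement deviance selection needs a nonempty complement; ",
         "phi = 1 leaves no held-out individuals")
  X <- unclass(X)
  y <- as.numeric(y)
  ys <- y[sub$indices]
  cc <- center_columns(X[sub$indices, , drop = FALSE])
  lmax <- lambda_max(cc$centered, ys)
  if (lmax <= 0) stop("degenerate subsample: all-zero score at every penalty")
  grid <- lambda_grid(lmax, nlambda, min_ratio)
  path <- fit_lasso_path(cc$centered, ys, grid, thresh = thresh)
  Xcomp <- sweep(X[sub$complement, , drop = FALSE], 2L, cc$means, "-")
  ycomp <- y[sub$complement]
  dev <- vapply(seq_along(grid), function(g) {
    p <- stats::plogis(path$a0[g] + drop(Xcomp %*% path$beta[, g]))
    binomial_deviance(ycomp, p)
  }, numeric(1))
  best <- which(dev == min(dev))[1L]  # grid decreasing: first = largest lambda
  list(lambda = grid[best], grid = grid, deviance = dev, path = path)
}

# -2 log-likelihood of independent Bernoulli outcomes; probabilities are
# clamped away from 0/1 so saturated wrong predictions stay finite
binomial_deviance <- function(y, p, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

#' LASSO local automatic regularization resample model averaging
#'
#' Fits the core SNP-reprioritization model: K stratified case-control
#' subsamples are drawn without replacement; within each, an L1-penalized
#' logistic regression path is fit to the column-centered genotypes and a
#' subsample-specific (local) penalty is chosen automatically, by
#' permutation selection or complement-deviance selection; the SNPs active
#' at that penalty form one row of the K x m inclusion matrix; each SNP's
#' resample model inclusion probability (RMIP) is its column mean.
#'
#' With an ensemble of sampled imputations (\code{imputations}), subsample
#' k is drawn from the k-th imputed genotype matrix, so the RMIPs also
#' integrate over imputation uncertainty (multiple imputation).  With a
#' single complete matrix (observed, hard- or dosage-imputed) the same
#' matrix is used for every subsample.
#'
#' The per-subsample RNG contract is public: subsample k runs under
#' \code{set.seed(subsample_seed(seed, k))} and consumes randomness in the
#' order [draw_subsample()] then (for permutation selection)
#' [select_lambda_perm()], so a hand-rolled loop over the exported
#' operations reproduces the fit exactly.
#'
#' @param X complete [genotype_matrix()] (or plain matrix); ignored in
#'   favour of \code{imputations} when the latter is supplied.
#' @param y binary 0/1 case-control response.
#' @param K number of subsamples (default 100).
#' @param phi subsampling proportion in (0, 1); default 0.5.
#' @param criterion \code{"perm"} (permutation selection, default) or
#'   \code{"cdev"} (complement deviance selection).
#' @param S permutations per subsample for \code{criterion = "perm"}.
#' @param imputations optional list of >= K complete genotype matrices
#'   (one posterior draw each) for multiple-imputation mode.
#' @param nlambda,min_ratio penalty grid construction.
#' @param thresh solver convergence threshold passed to
#'   [fit_lasso_path()]; the tight default keeps the KKT conditions to
#'   ~1e-6 along every path.  Large resampling studies may relax it (e.g.
#'   1e-8): the binary inclusion calls are insensitive well before the
#'   coefficients stop moving.
#' @param seed master seed; per-subsample streams are derived with
#'   [subsample_seed()].
#' @return object of class \code{"llarrma"}: list with \code{rmip} (named
#'   m-vector, each entry a multiple of 1/K), \code{Gamma} (K x m
#'   inclusion matrix), \code{lambda} (the K selected penalties),
#'   \code{diagnostics} (per-subsample criterion output), and the run
#'   settings.
#' @seealso [stability_selection()] for the global-penalty competitor,
#'   [single_locus_scores()] for marginal logistic scores.
#' @examples
#' set.seed(1)
#' dat <- sim_study2(q = 2, n = 120, blocks = list(
#'   ld_block_spec(6, pool_size = 4, mutation_rate = 0.05),
#'   ld_block_spec(6, pool_size = 4, mutation_rate = 0.05)))
#' fit <- llarrma(dat$genotypes, dat$y, K = 10, S = 5, seed = 1)
#' head(sort(coef(fit), decreasing = TRUE))
#' @export
llarrma <- function(X, y, K = 100L, phi = 0.5,
                    criterion = c("perm", "cdev"), S = 25L,
                    imputations = NULL, nlambda = 100L,
                    min_ratio = 0.001, thresh = 1e-12, seed = 1L) {
  criterion <- match.arg(criterion)
  y <- as_case_control(y)
  if (K < 1L) stop("K must be at least 1")
  multiple <- !is.null(imputations)
  if (multiple) {
    if (length(imputations) < K)
      stop("multiple-imputation mode needs at least K = ", K,
           " imputed matrices; got ", length(imputations))
    X <- imputations[[1L]]
  }
  if (anyNA(unclass(X)))
    stop("genotype matrix has missing entries; impute first or supply ",
         "an imputation ensemble")
  m <- ncol(X)
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("snp_", seq_len(m))
  Gamma <- matrix(0L, K, m, dimnames = list(NULL, ids))
  lambda_k <- numeric(K)
  diags <- vector("list", K)
  for (k in seq_len(K)) {
    Xk <- if (multiple) imputations[[k]] else X
    if (anyNA(unclass(Xk))) stop("imputation ", k, " has missing entries")
    set.seed(subsample_seed(seed, k))
    res <- fit_one_subsample(Xk, y, phi, criterion, S, nlambda, min_ratio,
                             thresh)
    Gamma[k, ] <- res$gamma
    lambda_k[k] <- res$lambda
    diags[[k]] <- res$diag
  }
  structure(list(rmip = colMeans(Gamma), Gamma = Gamma,
                 lambda = lambda_k, diagnostics = diags,
                 K = K, phi = phi, criterion = criterion,
                 S = if (criterion == "perm") S else NA_integer_,
                 seed = seed, multiple_imputation = multiple,
                 snp_ids = ids, positions = positions(X),
                 call = match.call()),
            class = "llarrma")
}

# one subsample under the current RNG state: draw, select lambda, fit,
# extract the active set
fit_one_subsample <- function(X, y, phi, criterion, S, nlambda, min_ratio,
                              thresh = 1e-12, max_retry = 10L) {
  for (try in seq_len(max_retry)) {
    sub <- draw_subsample(y, phi)
    ys <- as.numeric(y)[sub$indices]
    if (length(unique(ys)) >= 2L) break
    if (try == max_retry)
      stop("degenerate subsample (constant response) after ",
           max_retry, " retries")
    message("degenerate subsample; redrawing")
  }
  if (criterion == "perm") {
    sel <- select_lambda_perm(X, y, sub, S)
    cc <- center_columns(unclass(X)[sub$indices, , drop = FALSE])
    lmax <- lambda_max(cc$centered, ys)
    if (lmax <= 0 || sel$lambda >= lmax) {
      # the calibrated penalty already zeroes this subsample's path
      gamma <- integer(ncol(X))
    } else {
      grid <- lambda_grid(lmax, nlambda, min_ratio)
      target <- snap_to_grid(grid, max(sel$lambda, min(grid)))
      if (target == 1L) {
        gamma <- integer(ncol(X))  # grid head is lambda_max: all zero
      } else {
        # warm-started path solutions at a grid point do not depend on
        # the later (smaller) penalties, so fitting stops at the target
        path <- fit_lasso_path(cc$centered, ys, grid[seq_len(target)],
                               thresh = thresh)
        gamma <- active_set(path, grid[target])
      }
    }
    list(gamma = gamma, lambda = sel$lambda,
         diag = list(criterion = "perm", samples = sel$samples,
                     subsample = sub$indices))
  } else {
    sel <- select_lambda_cdev(X, y, sub, nlambda, min_ratio, thresh)
    gamma <- active_set(sel$path, sel$lambda)
    list(gamma = gamma, lambda = sel$lambda,
         diag = list(criterion = "cdev", grid = sel$grid,
                     deviance = sel$deviance, subsample = sub$indices))
  }
}

#' @export
print.llarrma <- function(x, ...) {
  cat("LLARRMA fit (", x$criterion, " selection)\n", sep = "")
  cat(sprintf("  K = %d subsamples, phi = %g%s, seed = %s\n", x$K, x$phi,
              if (x$criterion == "perm") paste0(", S = ", x$S) else "",
              format(x$seed)))
  if (x$multiple_imputation) cat("  multiple imputation: yes\n")
  top <- sort(x$rmip, decreasing = TRUE)
  cat("  top RMIPs:\n")
  print(utils::head(round(top, 3), 5))
  invisible(x)
}

#' @export
summary.llarrma <- function(object, threshold = 0.5, ...) {
  ord <- order(object$rmip, decreasing = TRUE)
  tab <- data.frame(snp_id = object$snp_ids[ord],
                    rmip = object$rmip[ord],
                    selected = object$rmip[ord] >= threshold,
                    row.names = NULL)
  structure(list(table = tab, threshold = threshold, K = object$K,
                 criterion = object$criterion,
                 mean_model_size = mean(rowSums(object$Gamma))),
            class = "summary.llarrma")
}

#' @export
print.summary.llarrma <- function(x, ...) {
  cat(sprintf("LLARRMA (%s): mean per-subsample model size %.1f SNPs\n",
              x$criterion, x$mean_model_size))
  cat(sprintf("SNPs with RMIP >= %g: %d\n", x$threshold,
              sum(x$table$selected)))
  print(utils::head(x$table, 10))
  invisible(x)
}

#' @export
coef.llarrma <- function(object, ...) object$rmip

#' Plot RMIPs along the hit region
#'
#' @param x an [llarrma()] fit.
#' @param ... passed to [plot()].
#' @export
plot.llarrma <- function(x, ...) {
  xs <- if (!is.null(x$positions)) x$positions else seq_along(x$rmip)
  plot(xs, x$rmip, type = "h", ylim = c(0, 1),
       xlab = if (!is.null(x$positions)) "position (bp)" else "SNP index",
       ylab = "RMIP", ...)
  invisible(x)
}

#' Score table from a fitted model
#'
#' @param fit an [llarrma()] fit.
#' @return a [score_table()] of RMIPs.
#' @export
as_score_table <- function(fit) {
  stopifnot(inherits(fit, "llarrma"))
  score_table(fit$snp_ids, fit$rmip,
              method = paste0("llarrma-", fit$criterion),
              positions = fit$positions, K = fit$K, phi = fit$phi,
              criterion = fit$criterion, seed = fit$seed)
}
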