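#' Column-center a complete genotype matrix
#'
#' The LASSO model is fit to the column-centered design matrix; the column
#' means are retained so that held-out (complement) individuals can be
#' centered in the same frame.
#'
#' @param X complete numeric matrix (no missing entries).
#' @return list with \code{centered} (matrix whose columns have mean 0)
#'   and \code{means} (the m column means).
#' @export
center_columns <- function(X) {
  X <- unclass(as.matrix(X))
  if (anyNA(X))
    stop("genotype matrix has missing entries; impute before centering ",
         "(see hard_impute / dosage_impute / sample_imputation)")
  mu <- colMeans(X)
  list(centered = sweep(X, 2L, mu, "-"), means = mu)
}

#' Smallest penalty that zeroes out all predictors
#'
#' For the 1/n-normalized L1-penalized logistic objective with an
#' unpenalized intercept, every coefficient is zero at penalties at or
#' above \deqn{\lambda_{max} = \frac{1}{n} \max_j |\langle x_j,\,
#' y - \bar y \rangle|,} where \eqn{x_j} are the columns of the centered
#' design matrix.  This is the anchor of the penalty grid and the
#' statistic behind permutation selection.
#'
#' @param Xc column-centered design matrix.
#' @param y_vec binary 0/1 response vector.
#' @return the penalty value; 0 when \code{y_vec} is constant.
#' @export
lambda_max <- function(Xc, y_vec) {
  y_vec <- as.numeric(y_vec)
  n <- length(y_vec)
  if (nrow(Xc) != n) stop("Xc and y_vec dimensions disagree")
  r <- y_vec - mean(y_vec)
  if (all(r == 0)) return(0)
  max(abs(crossprod(Xc, r))) / n
}

#' Log-spaced penalty grid
#'
#' Standard path convention: \code{nlambda} log-spaced values from
#' \code{lmax} down to \code{min_ratio * lmax}.
#'
#' @param lmax largest penalty (usually [lambda_max()]).
#' @param nlambda grid length (default 100).
#' @param min_ratio ratio of smallest to largest penalty (default 0.001).
#' @return strictly decreasing positive vector.
#' @export
lambda_grid <- function(lmax, nlambda = 100L, min_ratio = 0.001) {
  if (lmax <= 0) stop("lmax must be positive")
  exp(seq(log(lmax), log(min_ratio * lmax), length.out = nlambda))
}

#' Fit an L1-penalized logistic regression path
#'
#' Minimizes \deqn{-\frac{1}{n}\,\ell(\mu, \beta) + \lambda \sum_j
#' |\beta_j|} over a decreasing penalty grid, where \eqn{\ell} is the
#' log-likelihood of the additive multi-SNP logistic model and the
#' intercept \eqn{\mu} is unpenalized.  Fitting is by coordinate descent
#' (glmnet) at a tight convergence threshold so that the KKT conditions
#' hold to ~1e-6 along the path.
#'
#' @param Xc column-centered complete design matrix.
#' @param y binary 0/1 response with at least one case and one control.
#' @param grid strictly decreasing positive penalty vector (see
#'   [lambda_grid()]).
#' @param thresh glmnet convergence threshold.
#' @return object of class \code{"lasso_path"}: list with
#'   \code{lambda} (the grid), \code{beta} (m x grid_length coefficient
#'   matrix), \code{a0} (intercepts) and \code{means} if supplied.
#' @export
fit_lasso_path <- function(Xc, y, grid, thresh = 1e-12) {
  y <- as.numeric(y)
  if (anyNA(Xc) || any(!is.finite(Xc))) stop("design matrix must be finite")
  if (anyNA(y)) stop("response must not contain missing values")
  if (length(unique(y)) < 2L)
    stop("response is constant (no cases or no controls)")
  if (any(grid <= 0) || is.unsorted(rev(grid), strictly = TRUE))
    stop("penalty grid must be positive and strictly decreasing")
  m <- ncol(Xc)
  pad <- m < 2L
  Xfit <- if (pad) cbind(Xc, 0) else Xc   # glmnet needs >= 2 columns
  fit <- glmnet::glmnet(Xfit, y, family = "binomial", lambda = grid,
                        standardize = FALSE, intercept = TRUE,
                        thresh = thresh, maxit = 1e6)
  beta <- as.matrix(fit$beta)
  if (pad) beta <- beta[1L, , drop = FALSE]
  if (ncol(beta) != length(grid))  # glmnet may stop early; extend flat
    stop("path solver returned fewer solutions than grid points")
  structure(list(lambda = grid, beta = beta, a0 = as.numeric(fit$a0),
                 nobs = nrow(Xc)),
            class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf("lasso_path: %d SNPs, %d penalties in [%.4g, %.4g]\n",
              nrow(x$beta), length(x$lambda),
              min(x$lambda), max(x$lambda)))
  invisible(x)
}

#' Binary inclusion vector at a penalty
#'
#' Snaps \code{lam} to the nearest grid value of the path (ties toward
#' the larger, i.e. sparser, penalty) and reports which coefficients are
#' active there (|coefficient| > 1e-8).
#'
#' @param path a [fit_lasso_path()] result.
#' @param lam penalty value, within the path's grid range.
#' @param tol activity threshold on |coefficient|.
#' @return integer 0/1 vector of length m.
#' @export
active_set <- function(path, lam, tol = 1e-8) {
  grid <- path$lambda
  if (lam > max(grid) || lam < min(grid))
    stop(sprintf("lambda %.4g outside grid range [%.4g, %.4g]",
                 lam, min(grid), max(grid)))
  g <- snap_to_grid(grid, lam)
  as.integer(abs(path$beta[, g]) > tol)
}

# index of the grid value nearest lam; ties toward the larger (sparser)
# penalty, i.e. the smaller index of the decreasing grid
snap_to_grid <- function(grid, lam) {
  d <- abs(grid - lam)
  which(d == min(d))[1L]
}

# KKT stationarity residuals of a fitted path; used by tests
kkt_violation <- function(path, Xc, y) {
  y <- as.numeric(y)
  n <- length(y)
  worst <- 0
  for (g in seq_along(path$lambda)) {
    p <- stats::plogis(path$a0[g] + drop(Xc %*% path$beta[, g]))
    grad <- abs(drop(crossprod(Xc, y - p))) / n
    act <- abs(path$beta[, g]) > 1e-8
    if (any(!act)) worst <- max(worst, grad[!act] - path$lambda[g])
    if (any(act)) worst <- max(worst, abs(grad[act] - path$lambda[g]))
  }
  worst
}
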