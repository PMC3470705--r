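#' Hard (maximum a posteriori) imputation
#'
#' Replaces each missing genotype with the argmax of its posterior triple.
#' Ties are broken toward the larger expected dosage (i.e. the larger
#' genotype index), a fixed deterministic rule.
#'
#' @param X [genotype_matrix()] with missing entries.
#' @param post [genotype_posterior()] covering every missing entry of
#'   \code{X}.
#' @return complete genotype matrix; observed entries untouched.
#' @export
hard_impute <- function(X, post) {
  p <- check_posterior_cover(X, post)
  g <- max.col(p, ties.method = "last") - 1L
  fill_missing(X, post, g)
}

#' Dosage (posterior-mean) imputation
#'
#' Replaces each missing genotype with its expected allele count
#' \code{0*p0 + 1*p1 + 2*p2}, a fractional value in [0, 2] that feeds the
#' LASSO and single-locus models directly.
#'
#' @inheritParams hard_impute
#' @return complete genotype matrix with fractional imputed entries.
#' @export
dosage_impute <- function(X, post) {
  p <- check_posterior_cover(X, post)
  fill_missing(X, post, p[, 2L] + 2 * p[, 3L], dosage = TRUE)
}

#' Sampled imputation (one posterior draw)
#'
#' Draws each missing genotype independently from its posterior triple.
#' Repeated calls (under different RNG states) give the ensemble of
#' complete matrices consumed by [llarrma()] in multiple-imputation mode.
#'
#' @inheritParams hard_impute
#' @return complete genotype matrix, one random imputation.
#' @export
sample_imputation <- function(X, post) {
  p <- check_posterior_cover(X, post)
  u <- stats::runif(nrow(p))
  g <- (u > p[, 1L]) + (u > p[, 1L] + p[, 2L])
  fill_missing(X, post, as.numeric(g))
}

check_posterior_cover <- function(X, post) {
  stopifnot(inherits(post, "genotype_posterior"))
  mis <- which(is.na(unclass(X)), arr.ind = TRUE)
  if (nrow(mis) > 0L) {
    key_mis <- paste(mis[, 1L], mis[, 2L])
    key_post <- paste(post$i, post$j)
    lack <- setdiff(key_mis, key_post)
    if (length(lack) > 0L)
      stop("missing entries without posterior: (i,j) = ",
           paste(utils::head(lack, 5L), collapse = "; "),
           if (length(lack) > 5L) " ..." else "")
  }
  as.matrix(post[, c("p0", "p1", "p2")])
}

fill_missing <- function(X, post, values, dosage = FALSE) {
  out <- unclass(X)
  idx <- cbind(post$i, post$j)
  use <- is.na(out[idx])  # only fill entries that are actually missing
  out[idx[use, , drop = FALSE]] <- values[use]
  genotype_matrix(out, snp_ids = colnames(X), sample_ids = rownames(X),
                  positions = positions(X), dosage = TRUE)
}

#' Naive LD-neighbor genotype posteriors
#'
#' A built-in posterior estimator so the imputation pipeline can run
#' without external phasing software.  For a missing entry (i, j) the
#' posterior over genotypes g is proportional to the empirical joint
#' frequency (with a pseudocount of 0.5 per cell) of genotype g at SNP j
#' together with individual i's observed genotypes at the
#' \code{neighbors} SNPs most correlated with j; when none of those
#' neighbors is observed for i, the SNP's marginal genotype frequencies
#' are used.  This is a testing stand-in, not a competitor to
#' haplotype-based imputation (fastPHASE, IMPUTE, MACH), whose output
#' should be preferred on real data.
#'
#' @param X [genotype_matrix()] with missing entries.
#' @param neighbors number of most-correlated SNPs conditioned on
#'   (default 2).
#' @param min_obs minimum observed genotypes per SNP; below it the SNP
#'   falls back to marginal frequencies with a warning.
#' @param pseudocount added to every cell of the joint genotype table.
#' @return a [genotype_posterior()] with one triple per missing entry.
#' @export
naive_posterior <- function(X, neighbors = 2L, min_obs = 20L,
                            pseudocount = 0.5) {
  Xm <- unclass(X)
  n <- nrow(Xm); m <- ncol(Xm)
  mis <- which(is.na(Xm), arr.ind = TRUE)
  if (nrow(mis) == 0L)
    return(genotype_posterior(integer(0), integer(0),
                              numeric(0), numeric(0), numeric(0)))
  suppressWarnings(
    cors <- stats::cor(Xm, use = "pairwise.complete.obs"))
  out_i <- mis[, 1L]; out_j <- mis[, 2L]
  probs <- matrix(NA_real_, nrow(mis), 3L)
  for (j in unique(out_j)) {
    rows <- which(out_j == j)
    obs_j <- !is.na(Xm[, j])
    marg <- tabulate(Xm[obs_j, j] + 1L, 3L) + pseudocount
    marg <- marg / sum(marg)
    if (sum(obs_j) < min_obs) {
      warning("SNP ", j, " has fewer than ", min_obs,
              " observed genotypes; using marginal frequencies")
      probs[rows, ] <- matrix(marg, length(rows), 3L, byrow = TRUE)
      next
    }
    cj <- abs(cors[, j]); cj[j] <- NA
    nb <- order(cj, decreasing = TRUE, na.last = TRUE)
    nb <- nb[!is.na(cj[nb])][seq_len(min(neighbors, sum(!is.na(cj))))]
    if (length(nb) == 0L) {
      probs[rows, ] <- matrix(marg, length(rows), 3L, byrow = TRUE)
      next
    }
    # joint counts over (g_j, neighbors), pseudocount per cell
    cols <- c(j, nb)
    complete <- rowSums(is.na(Xm[, cols, drop = FALSE])) == 0L
    tab <- array(pseudocount, dim = rep(3L, length(cols)))
    if (any(complete)) {
      cells <- Xm[complete, cols, drop = FALSE] + 1L
      for (r in seq_len(nrow(cells)))
        tab[matrix(cells[r, ], 1L)] <- tab[matrix(cells[r, ], 1L)] + 1
    }
    for (r in rows) {
      i <- out_i[r]
      gnb <- Xm[i, nb]
      keep <- !is.na(gnb)
      if (!any(keep)) { probs[r, ] <- marg; next }
      # marginalize the table over neighbors unobserved for this individual
      sub <- apply(tab, c(1L, 1L + which(keep)), sum)
      idx <- cbind(1:3, matrix(rep(gnb[keep] + 1L, each = 3L), nrow = 3L))
      p <- sub[idx]
      probs[r, ] <- p / sum(p)
    }
  }
  genotype_posterior(out_i, out_j, probs[, 1L], probs[, 2L], probs[, 3L])
}
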