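#' Stratified case-control subsample
#'
#' Draws \code{ceiling(phi * n1)} cases and \code{ceiling(phi * n0)}
#' controls at random without replacement; everything not drawn is the
#' subsample's complement.  Ceiling rounding guarantees at least one
#' individual of each class for any valid \code{phi}.
#'
#' @param y binary 0/1 response (see [as_case_control()]).
#' @param phi subsampling proportion in (0, 1].
#' @param k optional subsample number, carried as metadata.
#' @return object of class \code{"subsample"}: list with \code{indices}
#'   (sorted), \code{complement}, \code{k}, \code{phi}.
#' @export
draw_subsample <- function(y, phi, k = NA_integer_) {
  if (!is.numeric(phi) || length(phi) != 1L || phi <= 0 || phi > 1)
    stop("phi must lie in (0, 1]")
  y <- as_case_control(y)
  n <- length(y)
  cases <- which(y == 1L)
  controls <- which(y == 0L)
  n1k <- ceiling(phi * length(cases))
  n0k <- ceiling(phi * length(controls))
  idx <- sort(c(cases[sample.int(length(cases), n1k)],
                controls[sample.int(length(controls), n0k)]))
  structure(list(indices = idx,
                 complement = setdiff(seq_len(n), idx),
                 k = as.integer(k), phi = phi),
            class = "subsample")
}

#' @export
print.subsample <- function(x, ...) {
  cat(sprintf("subsample%s: %d selected, %d in complement (phi = %g)\n",
              if (is.na(x$k)) "" else paste0(" ", x$k),
              length(x$indices), length(x$complement), x$phi))
  invisible(x)
}

#' Uniform random permutation of a response vector
#'
#' @param y_vec any vector.
#' @return a uniformly random rearrangement of \code{y_vec}; the multiset
#'   of values is preserved.
#' @export
permute_response <- function(y_vec) {
  y_vec[sample.int(length(y_vec))]
}

#' Per-subsample RNG stream seed
#'
#' Derives a deterministic seed for subsample \code{k} from one master
#' seed, so that increasing the number of subsamples K never reshuffles
#' earlier subsamples and a rerun with the same master seed reproduces the
#' inclusion matrix exactly.
#'
#' @param seed master seed (integer).
#' @param k subsample number (>= 1).
#' @return an integer seed below 2^31.
#' @export
subsample_seed <- function(seed, k) {
  # affine counter scheme; doubles are exact well past 2^31 * small k
  s <- (abs(as.double(seed)) %% 2147483647) + 1000003 * as.double(k)
  as.integer(s %% 2147483647)
}
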