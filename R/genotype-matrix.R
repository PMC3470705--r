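#' Construct a genotype matrix
#'
#' A genotype matrix holds additively coded SNP genotypes for one hit
#' region: rows are individuals, columns are SNPs, and each entry is the
#' count of the coded (alternate) allele, i.e. 0, 1 or 2 for called
#' genotypes, a value in \code{[0, 2]} for dosage-imputed genotypes, or
#' \code{NA} where the genotype is missing.
#'
#' @param values numeric matrix, n individuals x m SNPs.
#' @param snp_ids character vector of m unique SNP labels.  Defaults to
#'   existing column names or \code{"snp_1"} ... \code{"snp_m"}.
#' @param sample_ids character vector of n unique sample labels.
#' @param positions optional integer vector of m base-pair coordinates
#'   (1-based, as in VCF).
#' @param dosage logical; if \code{TRUE} entries may be fractional in
#'   \code{[0, 2]}, otherwise non-missing entries must be 0, 1 or 2.
#'
#' @return A numeric matrix of class \code{"genotype_matrix"} with
#'   \code{snp_ids} as column names, \code{sample_ids} as row names and a
#'   \code{"positions"} attribute.
#' @export
genotype_matrix <- function(values, snp_ids = NULL, sample_ids = NULL,
                            positions = NULL, dosage = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  m <- ncol(values)
  if (n < 2L) stop("a genotype matrix needs at least 2 individuals")
  if (m < 1L) stop("a genotype matrix needs at least 1 SNP")
  if (is.null(snp_ids)) {
    snp_ids <- colnames(values)
    if (is.null(snp_ids)) snp_ids <- paste0("snp_", seq_len(m))
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("ind_", seq_len(n))
  }
  if (anyDuplicated(snp_ids)) stop("snp_ids must be unique")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (length(snp_ids) != m || length(sample_ids) != n)
    stop("id lengths do not match matrix dimensions")
  obs <- values[!is.na(values)]
  if (any(obs < 0 | obs > 2))
    stop("genotype values must lie in [0, 2]")
  if (!dosage && any(obs != round(obs)))
    stop("non-integer genotype found; use dosage = TRUE for dosage data")
  if (!is.null(positions)) {
    if (length(positions) != m) stop("positions must have one entry per SNP")
    positions <- as.integer(positions)
  }
  dimnames(values) <- list(as.character(sample_ids), as.character(snp_ids))
  structure(values, positions = positions,
            class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nmis <- sum(is.na(x))
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%.2f%% missing)\n",
              nrow(x), ncol(x), 100 * nmis / length(x)))
  invisible(x)
}

# subsetting keeps the class and the positions attribute in step
#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  pos <- attr(x, "positions")
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    if (!is.null(pos) && !missing(j)) pos <- pos[j]
    out <- structure(out, positions = pos,
                     class = c("genotype_matrix", "matrix", "array"))
  }
  out
}

#' SNP identifiers, sample identifiers and positions
#'
#' @param x a \code{genotype_matrix}.
#' @return character (or integer, for \code{positions}) vector.
#' @export
snp_ids <- function(x) colnames(x)

#' @rdname snp_ids
#' @export
sample_ids <- function(x) rownames(x)

#' @rdname snp_ids
#' @export
positions <- function(x) attr(x, "positions")

#' Missingness mask of a genotype matrix
#'
#' @param x a \code{genotype_matrix}.
#' @return logical matrix, \code{TRUE} where the genotype is missing.
#' @export
missing_mask <- function(x) is.na(unclass(x))

#' Validate a case-control response
#'
#' Checks that a phenotype vector is binary with at least one case and one
#' control, and returns it as an integer vector.
#'
#' @param y vector of 0 (control) / 1 (case) phenotypes.
#' @return integer vector of 0/1 with attributes \code{n1} (cases) and
#'   \code{n0} (controls).
#' @export
as_case_control <- function(y) {
  y <- as.integer(y)
  if (anyNA(y)) stop("phenotype contains missing values; drop those rows first")
  if (!all(y %in% c(0L, 1L))) stop("phenotype must be coded 0/1")
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 < 1L || n0 < 1L)
    stop("phenotype needs at least one case and one control")
  structure(y, n1 = n1, n0 = n0)
}
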