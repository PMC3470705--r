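#' Read a genotype matrix from standard formats
#'
#' Supports biallelic VCF (genotypes coded as the count of the ALT allele),
#' PLINK additive-coded \code{.raw} files (as produced by
#' \code{plink --recode A}) and plain delimited matrices with one row per
#' sample.  SNP (column) order always follows file order.
#'
#' @param path path to the genotype file.
#' @param format one of \code{"vcf"}, \code{"plink_raw"}, \code{"csv"}.
#'   Guessed from the file extension when missing.
#' @return a [genotype_matrix()].
#' @details Missing genotypes (\code{./.} in VCF, \code{NA} in
#'   \code{.raw}, empty/NA cells in CSV) become \code{NA}.  Multi-allelic
#'   VCF records are an error; split them (e.g. \code{bcftools norm -m-})
#'   before reading.
#' @export
read_genotypes <- function(path, format = c("csv", "vcf", "plink_raw")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(format)) {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf"
              else if (grepl("\\.raw$", path)) "plink_raw"
              else "csv"
  }
  format <- match.arg(format)
  switch(format,
         vcf = read_genotypes_vcf(path),
         plink_raw = read_genotypes_raw(path),
         csv = read_genotypes_csv(path))
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix  # character matrix: CHROM POS ID REF ALT QUAL FILTER INFO
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    stop("multi-allelic VCF site at line(s) ",
         paste(which(multi), collapse = ", "),
         "; pre-split multi-allelic records (e.g. bcftools norm -m-)")
  gt <- vcfR::extract.gt(v, element = "GT")
  # count ALT alleles; any missing allele call makes the genotype missing
  count_alt <- function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == "." | al == "")) return(NA_real_)
    sum(al == "1")
  }
  vals <- t(apply(gt, c(1, 2), count_alt))
  ids <- fix[, "ID"]
  bad <- is.na(ids) | ids == "."
  ids[bad] <- paste0(fix[bad, "CHROM"], "_", fix[bad, "POS"])
  genotype_matrix(vals, snp_ids = ids, sample_ids = colnames(gt),
                  positions = as.integer(fix[, "POS"]))
}

read_genotypes_raw <- function(path) {
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, check.names = FALSE,
                      na.strings = c("NA", "-9")),
    error = function(e) stop("malformed PLINK .raw file '", path, "': ",
                             conditionMessage(e)))
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta %in% names(tab)[seq_along(meta)]))
    stop("not a PLINK .raw file: expected header starting FID IID PAT MAT SEX PHENOTYPE")
  vals <- as.matrix(tab[, setdiff(names(tab), meta), drop = FALSE])
  # .raw columns are "<rsid>_<counted allele>"; strip the allele suffix
  ids <- sub("_[ACGTacgt0-9]+$", "", colnames(vals))
  genotype_matrix(vals, snp_ids = ids, sample_ids = as.character(tab$IID))
}

read_genotypes_csv <- function(path) {
  tab <- tryCatch(utils::read.csv(path, check.names = FALSE),
                  error = function(e) stop("malformed CSV '", path, "': ",
                                           conditionMessage(e)))
  if (ncol(tab) < 2L)
    stop("CSV genotype file needs a sample_id column plus at least one SNP")
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(tab[-1L], is.numeric, logical(1)))[1L]
    stop("non-numeric genotype column '", names(tab)[-1L][bad],
         "' in ", path)
  }
  genotype_matrix(vals, snp_ids = colnames(vals),
                  sample_ids = as.character(tab[[1L]]),
                  dosage = TRUE)
}

#' Write a genotype matrix as CSV
#'
#' Writes the row-per-sample delimited format read back by
#' \code{read_genotypes(..., format = "csv")}; the numeric matrix and
#' missingness mask round-trip exactly.
#'
#' @param x a [genotype_matrix()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), unclass(x),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a case-control phenotype file
#'
#' Expects a two-column delimited file \code{sample_id,status} with status
#' 0 (control) or 1 (case).  Rows with missing status are dropped with a
#' warning before analysis.
#'
#' @param path path to the phenotype file.
#' @return named integer 0/1 vector (names are sample ids).
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.csv(path)
  if (ncol(tab) < 2L) stop("phenotype file needs columns sample_id,status")
  status <- tab[[2L]]
  drop <- is.na(status)
  if (any(drop)) {
    warning(sum(drop), " individual(s) with missing phenotype dropped")
    tab <- tab[!drop, , drop = FALSE]
    status <- status[!drop]
  }
  if (!all(status %in% c(0, 1))) stop("phenotype status must be 0 or 1")
  stats::setNames(as.integer(status), as.character(tab[[1L]]))
}

#' Build a per-SNP score table
#'
#' The common output container of all scoring methods: one score per SNP
#' (an RMIP in \code{[0, 1]} or a single-locus logP in \code{[0, Inf)}),
#' with ranks assigned so that rank 1 is the best score and ties share the
#' minimum rank.
#'
#' @param snp_ids character vector of SNP labels.
#' @param score numeric score vector, one per SNP; larger is better.
#' @param method method label (e.g. \code{"llarrma-perm"}).
#' @param positions optional base-pair coordinates.
#' @param K,phi,criterion,seed optional run metadata recorded as
#'   attributes.
#' @return data.frame of class \code{"score_table"} with columns
#'   \code{snp_id}, \code{position}, \code{score}, \code{method},
#'   \code{rank}.
#' @export
score_table <- function(snp_ids, score, method, positions = NULL,
                        K = NULL, phi = NULL, criterion = NULL,
                        seed = NULL) {
  if (length(snp_ids) != length(score))
    stop("need exactly one score per SNP")
  if (anyNA(score)) stop("scores must not be missing")
  out <- data.frame(
    snp_id = as.character(snp_ids),
    position = if (is.null(positions)) NA_integer_ else as.integer(positions),
    score = as.numeric(score),
    method = method,
    rank = rank(-score, ties.method = "min"),
    stringsAsFactors = FALSE)
  structure(out, K = K, phi = phi, criterion = criterion, seed = seed,
            class = c("score_table", "data.frame"))
}

#' Write a score table
#'
#' Tab-delimited output with columns snp_id, position, score, method,
#' rank.
#'
#' @param table a [score_table()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_scores <- function(table, path) {
  stopifnot(inherits(table, "score_table"))
  ok <- tryCatch({
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write scores to '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Construct genotype posteriors
#'
#' Per-(individual, SNP) probability triples over the genotypes
#' \{0, 1, 2\}, typically covering the missing entries of a genotype
#' matrix.  Triples are renormalized to sum to one; negative or all-zero
#' triples are an error.
#'
#' @param i,j integer indices (individual, SNP) of each entry.
#' @param p0,p1,p2 probabilities of genotypes 0, 1, 2.
#' @return data.frame of class \code{"genotype_posterior"} with columns
#'   \code{i, j, p0, p1, p2}; every triple sums to 1 within 1e-6.
#' @export
genotype_posterior <- function(i, j, p0, p1, p2) {
  p <- cbind(p0, p1, p2)
  if (any(p < 0)) stop("negative genotype probability")
  s <- rowSums(p)
  if (any(s <= 0)) stop("genotype probability triple sums to zero")
  p <- p / s
  structure(
    data.frame(i = as.integer(i), j = as.integer(j),
               p0 = p[, 1L], p1 = p[, 2L], p2 = p[, 3L]),
    class = c("genotype_posterior", "data.frame"))
}

#' Read genotype posteriors or sampled-imputation ensembles
#'
#' Two formats are supported.  \code{triple_table}: a delimited file with
#' columns \code{i, j, p0, p1, p2} (or \code{sample_id, snp_id, p0, p1,
#' p2} resolved against \code{genotypes}) giving the posterior genotype
#' probabilities of each missing entry.  \code{fastphase_samples}: the
#' post-processed sampled-genotype output of a haplotype-based imputation
#' run (e.g. fastPHASE with per-sample draws): one n x m block of
#' whitespace-separated genotypes 0/1/2 per posterior draw, blocks
#' separated by blank lines, comment lines starting with \code{#} ignored.
#'
#' @param path input path.
#' @param format \code{"triple_table"} or \code{"fastphase_samples"}.
#' @param genotypes optional [genotype_matrix()] used to resolve
#'   sample/SNP identifiers to indices (triple_table) or to supply ids
#'   (fastphase_samples).
#' @return a [genotype_posterior()] (triple_table) or a list of complete
#'   [genotype_matrix()] objects, one per posterior draw
#'   (fastphase_samples).
#' @export
read_posteriors <- function(path, format = c("triple_table", "fastphase_samples"),
                            genotypes = NULL) {
  format <- match.arg(format)
  if (format == "triple_table") {
    tab <- utils::read.table(path, header = TRUE)
    need <- c("p0", "p1", "p2")
    if (!all(need %in% names(tab)))
      stop("triple_table needs columns p0, p1, p2")
    if (all(c("i", "j") %in% names(tab))) {
      i <- tab$i; j <- tab$j
    } else if (all(c("sample_id", "snp_id") %in% names(tab))) {
      if (is.null(genotypes))
        stop("id-based triple_table needs `genotypes` to resolve indices")
      i <- match(as.character(tab$sample_id), rownames(genotypes))
      j <- match(as.character(tab$snp_id), colnames(genotypes))
      if (anyNA(i) || anyNA(j))
        stop("posterior refers to unknown sample or SNP ids")
    } else stop("triple_table needs (i, j) or (sample_id, snp_id) columns")
    genotype_posterior(i, j, tab$p0, tab$p1, tab$p2)
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*#", lines)]
    blank <- grepl("^\\s*$", lines)
    grp <- cumsum(c(TRUE, diff(!blank) == 1) & !blank)
    grp[blank] <- 0L
    blocks <- split(lines[!blank], grp[!blank])
    lapply(unname(blocks), function(b) {
      rows <- lapply(strsplit(trimws(b), "\\s+"), as.numeric)
      len <- lengths(rows)
      if (length(unique(len)) != 1L)
        stop("ragged genotype block in ", path)
      vals <- do.call(rbind, rows)
      if (anyNA(vals))
        stop("sampled-imputation draws must be complete (no missing entries)")
      genotype_matrix(vals,
                      snp_ids = if (!is.null(genotypes)) colnames(genotypes),
                      sample_ids = if (!is.null(genotypes)) rownames(genotypes),
                      positions = if (!is.null(genotypes)) positions(genotypes))
    })
  }
}
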