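# shared fixtures, all generated in code

# small random case-control instance with mild correlation between SNPs
toy_instance <- function(n = 60, m = 8, seed = NULL, maf = 0.3) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rbinom(n * m, 2, maf), n, m)
  y <- rbinom(n, 1, plogis(0.4 * scale(X[, 1], scale = FALSE)))
  while (sum(y) < 2 || sum(1 - y) < 2) y <- rbinom(n, 1, 0.5)
  list(X = X, y = as.integer(y))
}

# small LD-block layout for fast end-to-end runs
toy_blocks <- function() {
  list(ld_block_spec(8, pool_size = 3, mutation_rate = 0.03),
       ld_block_spec(8, pool_size = 4, mutation_rate = 0.04),
       ld_block_spec(8, pool_size = 5, mutation_rate = 0.05))
}

# independent reference logistic fit (IRLS), used as the unpenalized oracle
irls_logistic <- function(X, y, tol = 1e-12, maxit = 200) {
  X1 <- cbind(1, X)
  b <- numeric(ncol(X1))
  for (it in seq_len(maxit)) {
    p <- plogis(drop(X1 %*% b))
    W <- p * (1 - p)
    step <- solve(crossprod(X1, X1 * W), crossprod(X1, y - p))
    b <- b + drop(step)
    if (max(abs(step)) < tol) break
  }
  b
}

# write a tiny VCF fixture; genotypes is an n x m matrix of strings
write_toy_vcf <- function(path, genotypes, positions = NULL,
                          alt = NULL) {
  n <- nrow(genotypes); m <- ncol(genotypes)
  if (is.null(positions)) positions <- 100 * seq_len(m)
  if (is.null(alt)) alt <- rep("T", m)
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", paste0("S", seq_len(n))), collapse = "\t"))
  for (j in seq_len(m)) {
    lines <- c(lines, paste(c("1", positions[j], paste0("rs", j), "A",
                              alt[j], ".", "PASS", ".", "GT",
                              genotypes[, j]), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}
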