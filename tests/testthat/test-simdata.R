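test_that("haplotype pools control within-block LD and blocks are independent", {
  set.seed(81)
  X <- simulate_genotypes(2000, list(
    ld_block_spec(4, pool_size = 2, mutation_rate = 0),
    ld_block_spec(4, pool_size = 2, mutation_rate = 0)))
  r <- cor(unclass(X))
  within1 <- abs(r[1:4, 1:4][upper.tri(diag(4))])
  expect_true(all(within1 > 0.9))
  between <- abs(r[1:4, 5:8])
  expect_lt(mean(between), 0.05)
  expect_equal(snp_blocks(X), rep(1:2, each = 4))
})

test_that("generated SNPs are polymorphic with sane frequencies", {
  set.seed(82)
  X <- simulate_genotypes(500, toy_blocks())
  freq <- colMeans(unclass(X)) / 2
  expect_true(all(freq > 0 & freq < 1))
  expect_true(all(apply(unclass(X), 2, var) > 0))
  expect_equal(dim(X), c(500L, 24L))
})

test_that("default region layouts have the printed SNP counts", {
  expect_equal(sum(vapply(blocks_region183(), `[[`, integer(1), "n_snps")),
               183L)
  expect_equal(sum(vapply(blocks_region500(), `[[`, integer(1), "n_snps")),
               500L)
})

test_that("study-1 causal placement is 2+2+1 with the r-squared constraint", {
  set.seed(83)
  X <- simulate_genotypes(400, list(
    ld_block_spec(10, pool_size = 3, mutation_rate = 0.05),
    ld_block_spec(10, pool_size = 3, mutation_rate = 0.05),
    ld_block_spec(10, pool_size = 4, mutation_rate = 0.05)))
  for (r in 1:10) {
    causal <- place_causal(X, "study1", r2_window = c(0.1, 0.95))
    expect_length(causal, 5L)
    expect_false(anyDuplicated(causal) > 0)
    bl <- snp_blocks(X)[causal]
    expect_equal(as.integer(table(factor(bl, 1:3))), c(2L, 2L, 1L))
    for (b in 1:2) {
      pair <- causal[bl == b]
      r2 <- cor(unclass(X)[, pair[1]], unclass(X)[, pair[2]])^2
      expect_gte(r2, 0.1)
      expect_lte(r2, 0.95)
    }
  }
  expect_error(place_causal(X, "study1", r2_window = c(0.9999, 1),
                            max_tries = 50), "r2")
})

test_that("study-2 placement is uniform without replacement, q = m allowed", {
  set.seed(84)
  X <- simulate_genotypes(100, toy_blocks())
  c1 <- place_causal(X, "study2", q = 3)
  expect_length(unique(c1), 3L)
  expect_equal(place_causal(X, "study2", q = ncol(X)), seq_len(ncol(X)))
  expect_error(place_causal(X, "study2", q = 0), "q")
})

test_that("moderate effects are a permutation of the printed odds-ratio set", {
  set.seed(85)
  odds_ref <- exp(seq(log(1.246), log(1.419), length.out = 5))
  for (r in 1:5) {
    beta <- assign_effects(5, "moderate")
    expect_equal(sort(exp(beta)), odds_ref, tolerance = 1e-12)
  }
  expect_equal(min(exp(assign_effects(5, "moderate"))), 1.246)
  expect_equal(max(exp(assign_effects(5, "moderate"))), 1.419)
  expect_error(assign_effects(3, "moderate"), "5")
})

test_that("small effects center near odds ratio 1.25 in magnitude with random signs", {
  set.seed(86)
  beta <- assign_effects(10000, "small")
  expect_gt(mean(exp(abs(beta))), 1.24)
  expect_lt(mean(exp(abs(beta))), 1.26)
  expect_true(abs(mean(beta > 0) - 0.5) < 0.02)
  expect_true(all(abs(beta) > 0))
})

test_that("the intercept solver hits an expected 50/50 case-control split", {
  expect_equal(compute_intercept(rep(0, 100)), 0, tolerance = 1e-7)
  expect_equal(compute_intercept(c(-2, -1, 0, 1, 2)), 0, tolerance = 1e-7)
  set.seed(87)
  eta <- rnorm(1500, 0.3, 0.8)
  mu <- compute_intercept(eta)
  expect_lt(abs(sum(plogis(mu + eta)) - 750), 1e-4 * 1500)
})

test_that("phenotypes follow the calibrated logistic model", {
  set.seed(88)
  X <- simulate_genotypes(1500, toy_blocks())
  causal <- place_causal(X, "study2", q = 3)
  model <- true_model(X, causal, assign_effects(3, "small"))
  frac <- replicate(200, mean(simulate_phenotypes(X, model)))
  expect_lt(abs(mean(frac) - 0.5), 0.02)
  # beta = 0 reduces to fair Bernoulli coin flips
  null_model <- true_model(X, causal, rep(0, 3))
  expect_equal(null_model$mu, 0, tolerance = 1e-7)
  set.seed(89)
  y1 <- simulate_phenotypes(X, model)
  set.seed(89)
  y2 <- simulate_phenotypes(X, model)
  expect_identical(y1, y2)
})

test_that("the missingness generator honors its target and eligibility rules", {
  set.seed(90)
  X <- simulate_genotypes(1493, blocks_region183())
  mg <- generate_missingness(X, missingness_spec(0.10))
  n <- nrow(X); m <- ncol(X)
  # overall deleted fraction within 0.1 percentage point of target
  expect_lt(abs(mean(mg$mask) - 0.10), 0.001)
  # only eligible individuals lose genotypes
  hit_rows <- which(rowSums(mg$mask) > 0)
  expect_true(all(hit_rows %in% mg$eligible))
  ineligible <- setdiff(seq_len(n), mg$eligible)
  expect_true(all(rowSums(mg$mask[ineligible, ]) == 0))
  expect_length(mg$eligible, floor(0.9 * n))
  # per-SNP counts follow the scaled raw proportions
  expect_equal(colSums(mg$mask), round(mg$c * mg$q * n),
               ignore_attr = TRUE)
  # p_total = 0 deletes nothing
  mg0 <- generate_missingness(X, missingness_spec(0))
  expect_false(any(mg0$mask))
})

test_that("scenario builders reproduce the printed design sizes", {
  set.seed(91)
  d1 <- sim_study1a(n = 300, blocks = list(
    ld_block_spec(12, 3, 0.04), ld_block_spec(12, 3, 0.04),
    ld_block_spec(12, 4, 0.05)), r2_window = c(0.05, 0.98))
  expect_equal(ncol(d1$genotypes), 36L)
  expect_length(d1$model$causal, 5L)
  expect_equal(sort(exp(abs(d1$model$beta)))[c(1, 5)],
               c(1.246, 1.419), tolerance = 1e-9)
  expect_equal(sum(d1$truth), 5L)

  d2 <- sim_study2(q = 4, n = 200, blocks = toy_blocks(), missing = TRUE,
                   miss_spec = missingness_spec(0.08))
  expect_equal(sum(d2$truth), 4L)
  expect_true(anyNA(d2$incomplete))
  expect_false(anyNA(d2$genotypes))
  expect_equal(is.na(unclass(d2$incomplete)), d2$mask,
               ignore_attr = TRUE)
  # default sizes match the benchmark regions
  expect_equal(formals(sim_study1a)$n, 1493L)
  expect_equal(formals(sim_study2)$n, 2199L)
})

test_that("single-locus regression finds a causal SNP near the top of study-1A draws", {
  set.seed(92)
  hits <- vapply(1:15, function(r) {
    d <- sim_study1a(n = 400, blocks = list(
      ld_block_spec(15, 3, 0.03), ld_block_spec(15, 3, 0.03),
      ld_block_spec(15, 4, 0.04)), r2_window = c(0.05, 0.98))
    tab <- single_locus_scores(d$genotypes, d$y)
    any(tab$rank[d$model$causal] <= 10)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
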