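test_that("permutation selection is the median of per-permutation zeroing penalties", {
  inst <- toy_instance(n = 60, m = 6, seed = 31)
  set.seed(1)
  sub <- draw_subsample(inst$y, 0.5)

  set.seed(7)
  sel <- select_lambda_perm(inst$X, inst$y, sub, S = 25)
  expect_length(sel$samples, 25)
  expect_equal(sel$lambda, median(sel$samples))

  # independent recomputation under the same RNG state
  set.seed(7)
  ys <- inst$y[sub$indices]
  Xc <- center_columns(inst$X[sub$indices, ])$centered
  ref <- vapply(1:25, function(s) {
    yp <- ys[sample.int(length(ys))]
    max(abs(crossprod(Xc, yp - mean(yp)))) / length(ys)
  }, numeric(1))
  expect_equal(sel$samples, ref)

  # S = 1 equals the zeroing penalty of the single permuted response
  set.seed(8)
  s1 <- select_lambda_perm(inst$X, inst$y, sub, S = 1)
  set.seed(8)
  yp <- ys[sample.int(length(ys))]
  expect_equal(s1$lambda, max(abs(crossprod(Xc, yp - mean(yp)))) / length(ys))

  # even S averages the two central values
  set.seed(9)
  s4 <- select_lambda_perm(inst$X, inst$y, sub, S = 4)
  expect_equal(s4$lambda, mean(sort(s4$samples)[2:3]))
})

test_that("the permutation-selected penalty sits at the centre of the null zeroing distribution", {
  inst <- toy_instance(n = 80, m = 6, seed = 37)
  set.seed(2)
  sub <- draw_subsample(inst$y, 0.5)
  ys <- inst$y[sub$indices]
  Xc <- center_columns(inst$X[sub$indices, ])$centered
  # the selected penalty estimates the median null zeroing penalty, so a
  # freshly permuted response should be zeroed out about half the time
  # (the band allows for the sampling error of a median of S = 25 draws)
  sel <- select_lambda_perm(inst$X, inst$y, sub, S = 25)
  empty <- vapply(1:200, function(r) {
    yp <- ys[sample.int(length(ys))]
    lambda_max(Xc, yp) <= sel$lambda  # all-zero iff zeroing penalty <= lambda
  }, logical(1))
  expect_gte(mean(empty), 0.25)
  expect_lte(mean(empty), 0.75)
  # with a large S the estimate tightens to the true median
  sel_big <- select_lambda_perm(inst$X, inst$y, sub, S = 999)
  empty_big <- vapply(1:400, function(r) {
    yp <- ys[sample.int(length(ys))]
    lambda_max(Xc, yp) <= sel_big$lambda
  }, logical(1))
  expect_gte(mean(empty_big), 0.4)
  expect_lte(mean(empty_big), 0.6)
})

test_that("complement deviance selection matches a brute-force curve", {
  inst <- toy_instance(n = 80, m = 5, seed = 41)
  set.seed(3)
  sub <- draw_subsample(inst$y, 0.5)
  sel <- select_lambda_cdev(inst$X, inst$y, sub, nlambda = 40)

  # independent recomputation of the whole deviance curve
  ys <- inst$y[sub$indices]
  cc <- center_columns(inst$X[sub$indices, ])
  path <- fit_lasso_path(cc$centered, ys, sel$grid)
  yc <- inst$y[sub$complement]
  Xcomp <- sweep(inst$X[sub$complement, ], 2, cc$means, "-")
  ref <- numeric(length(sel$grid))
  for (g in seq_along(sel$grid)) {
    p <- plogis(path$a0[g] + drop(Xcomp %*% path$beta[, g]))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ref[g] <- -2 * sum(yc * log(p) + (1 - yc) * log(1 - p))
  }
  expect_equal(sel$deviance, ref, tolerance = 1e-8)
  expect_equal(sel$lambda, sel$grid[which(ref == min(ref))[1]])

  # an intercept-only prediction at the complement's own mean recovers
  # the complement's null deviance
  pnull <- mean(yc)
  dnull <- -2 * sum(yc * log(pnull) + (1 - yc) * log(1 - pnull))
  n1 <- sum(yc)
  n0 <- sum(1 - yc)
  expect_equal(dnull, -2 * (n1 * log(pnull) + n0 * log(1 - pnull)))

  expect_error(
    select_lambda_cdev(inst$X, inst$y, draw_subsample(inst$y, 1)),
    "complement")
})

test_that("RMIPs are column means of the inclusion matrix on the 1/K grid", {
  set.seed(51)
  dat <- sim_study2(q = 2, n = 150, blocks = toy_blocks())
  fit <- llarrma(dat$genotypes, dat$y, K = 8, S = 5, seed = 4)
  expect_equal(dim(fit$Gamma), c(8L, 24L))
  expect_true(all(fit$Gamma %in% c(0L, 1L)))
  expect_equal(fit$rmip, colMeans(fit$Gamma))
  expect_true(all(fit$rmip * 8 == round(fit$rmip * 8)))
  expect_equal(unname(coef(fit)), unname(fit$rmip))
  # rerun with the same master seed is bit-identical
  fit2 <- llarrma(dat$genotypes, dat$y, K = 8, S = 5, seed = 4)
  expect_identical(fit$Gamma, fit2$Gamma)
  # a different seed gives a different inclusion matrix
  fit3 <- llarrma(dat$genotypes, dat$y, K = 8, S = 5, seed = 5)
  expect_false(identical(fit$Gamma, fit3$Gamma))
})

test_that("the engine equals a hand-composed loop over the public operations", {
  set.seed(52)
  dat <- sim_study2(q = 2, n = 150, blocks = toy_blocks())
  X <- dat$genotypes
  y <- dat$y
  K <- 5
  for (crit in c("perm", "cdev")) {
    fit <- llarrma(X, y, K = K, phi = 0.5, criterion = crit, S = 7,
                   seed = 11)
    Gamma <- matrix(0L, K, ncol(X))
    for (k in seq_len(K)) {
      set.seed(subsample_seed(11, k))
      sub <- draw_subsample(y, 0.5)
      ys <- y[sub$indices]
      cc <- center_columns(unclass(X)[sub$indices, ])
      if (crit == "perm") {
        sel <- select_lambda_perm(X, y, sub, S = 7)
        lmax <- lambda_max(cc$centered, ys)
        if (sel$lambda >= lmax) next
        grid <- lambda_grid(lmax)
        path <- fit_lasso_path(cc$centered, ys, grid)
        Gamma[k, ] <- active_set(path, max(sel$lambda, min(grid)))
      } else {
        sel <- select_lambda_cdev(X, y, sub)
        Gamma[k, ] <- active_set(sel$path, sel$lambda)
      }
    }
    expect_equal(unname(fit$rmip), colMeans(Gamma),
                 info = paste("criterion", crit))
  }
})

test_that("multiple-imputation mode with identical matrices reproduces complete-data RMIPs", {
  set.seed(53)
  dat <- sim_study2(q = 2, n = 150, blocks = toy_blocks())
  fit0 <- llarrma(dat$genotypes, dat$y, K = 6, S = 5, seed = 21)
  ens <- replicate(6, dat$genotypes, simplify = FALSE)
  fit1 <- llarrma(dat$genotypes, dat$y, K = 6, S = 5, seed = 21,
                  imputations = ens)
  expect_identical(fit0$Gamma, fit1$Gamma)
  expect_identical(fit0$rmip, fit1$rmip)
  expect_error(
    llarrma(dat$genotypes, dat$y, K = 6, imputations = ens[1:3]),
    "at least K")
})

test_that("missing genotypes are refused without an imputation ensemble", {
  set.seed(54)
  dat <- sim_study2(q = 2, n = 150, blocks = toy_blocks())
  mg <- generate_missingness(dat$genotypes, missingness_spec(0.05))
  expect_error(llarrma(mg$genotypes, dat$y, K = 2), "impute")
})

test_that("mean null RMIP shrinks as the permutation count S grows", {
  set.seed(55)
  dat <- sim_study2(q = 2, n = 200, blocks = toy_blocks())
  ynull <- permute_response(dat$y)
  means <- vapply(c(1, 5, 25), function(S) {
    fit <- llarrma(dat$genotypes, ynull, K = 50, S = S, seed = 77,
                   thresh = 1e-9)
    mean(fit$rmip)
  }, numeric(1))
  # monotone non-increasing trend in S on a fixed null dataset
  expect_true(means[1] >= means[2] && means[2] >= means[3])
  expect_lt(means[3], 0.1)
})

test_that("print, summary, plot and score-table conversion work", {
  set.seed(56)
  dat <- sim_study2(q = 2, n = 150, blocks = toy_blocks())
  fit <- llarrma(dat$genotypes, dat$y, K = 4, S = 3, seed = 1)
  expect_output(print(fit), "LLARRMA")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.llarrma")
  expect_output(print(sm), "model size")
  tab <- as_score_table(fit)
  expect_s3_class(tab, "score_table")
  expect_equal(tab$score, unname(fit$rmip))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
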