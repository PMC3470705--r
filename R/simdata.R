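#' LD block specification
#'
#' One block of the haplotype-pool genotype generator.  Each block draws a
#' small pool of founder haplotypes; every individual receives two
#' haplotypes per block, each copied from a random pool member with a
#' per-SNP mutation (allele flip) probability.  Small pools give strong
#' within-block LD; blocks are generated independently, so between-block
#' LD is negligible.
#'
#' @param n_snps number of SNPs in the block (>= 1).
#' @param pool_size number of founder haplotypes (>= 2); 2 with zero
#'   mutation gives |r| near 1 within the block.
#' @param mutation_rate per-SNP allele flip probability when copying a
#'   haplotype from the pool.
#' @return list of class \code{"ld_block_spec"}.
#' @export
ld_block_spec <- function(n_snps, pool_size = 4L, mutation_rate = 0.02) {
  stopifnot(n_snps >= 1L, pool_size >= 2L,
            mutation_rate >= 0, mutation_rate < 0.5)
  structure(list(n_snps = as.integer(n_snps),
                 pool_size = as.integer(pool_size),
                 mutation_rate = mutation_rate),
            class = "ld_block_spec")
}

#' Default block layouts emulating the two study regions
#'
#' Fixed LD-block layouts reproducing the scale and qualitative LD mix of
#' the two hit regions the method was benchmarked on: a 183-SNP region of
#' moderate LD (three signal-bearing blocks of moderate-to-high LD plus
#' mixed background blocks) and a 500-SNP contiguous run mixing many
#' small blocks of strong LD with weaker ones.
#'
#' @return list of [ld_block_spec()] objects; SNP counts sum to 183 and
#'   500 respectively.
#' @export
blocks_region183 <- function() {
  list(ld_block_spec(30, pool_size = 4L, mutation_rate = 0.02),  # block 1
       ld_block_spec(30, pool_size = 4L, mutation_rate = 0.02),  # block 2
       ld_block_spec(25, pool_size = 6L, mutation_rate = 0.03),  # block 3
       ld_block_spec(24, pool_size = 10L, mutation_rate = 0.08),
       ld_block_spec(25, pool_size = 4L, mutation_rate = 0.03),
       ld_block_spec(25, pool_size = 12L, mutation_rate = 0.10),
       ld_block_spec(24, pool_size = 6L, mutation_rate = 0.05))
}

#' @rdname blocks_region183
#' @export
blocks_region500 <- function() {
  # 50 blocks of 6-15 SNPs; small founder pools give strong within-block
  # LD, larger pools and mutation rates the interleaved weak-LD stretches
  sizes <- rep(c(12L, 8L, 15L, 6L, 10L, 9L, 14L, 7L, 11L, 8L), 5)
  pools <- rep(c(2L, 4L, 3L, 6L, 2L, 5L, 3L, 8L, 2L, 4L), 5)
  muts <- rep(c(0.02, 0.04, 0.02, 0.06, 0.03, 0.05, 0.02, 0.08, 0.03,
                0.04), 5)
  mapply(ld_block_spec, sizes, pools, muts, SIMPLIFY = FALSE)
}

#' Truncate a block layout to a smaller SNP panel
#'
#' Keeps whole blocks (trimming the last one) until \code{m_target} SNPs
#' are reached -- a reduced panel with the same LD character, used for
#' desk-scale replicated studies.
#'
#' @param blocks list of [ld_block_spec()].
#' @param m_target number of SNPs to keep.
#' @return list of [ld_block_spec()] whose SNP counts sum to
#'   \code{m_target}.
#' @export
reduce_blocks <- function(blocks, m_target) {
  sizes <- vapply(blocks, `[[`, integer(1), "n_snps")
  if (m_target > sum(sizes)) stop("m_target exceeds the layout size")
  keep <- which(cumsum(sizes) <= m_target)
  out <- blocks[keep]
  left <- m_target - sum(sizes[keep])
  if (left > 0L) {
    nxt <- blocks[[length(keep) + 1L]]
    out <- c(out, list(ld_block_spec(left, nxt$pool_size,
                                     nxt$mutation_rate)))
  }
  out
}

#' Simulate LD-block genotypes
#'
#' Haplotype-pool generator: per block, founder haplotypes are drawn with
#' per-SNP allele frequencies uniform on \code{maf_range}; each individual
#' gets two haplotypes per block, copied from random pool members with
#' per-SNP flip probability equal to the block's mutation rate; the
#' genotype is the haplotype sum.  SNPs that come out monomorphic are
#' regenerated (new pool column and copies, up to 10 retries).
#'
#' @param n number of individuals (>= 50).
#' @param blocks list of [ld_block_spec()] (e.g. [blocks_region183()]).
#' @param maf_range founder allele-frequency range.
#' @return complete [genotype_matrix()] with a \code{"blocks"} attribute
#'   (integer block membership per SNP) and evenly spaced positions.
#' @export
simulate_genotypes <- function(n, blocks, maf_range = c(0.05, 0.95)) {
  if (n < 50L) stop("need at least 50 individuals")
  stopifnot(length(blocks) >= 1L)
  cols <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    spec <- blocks[[b]]
    mb <- spec$n_snps; H <- spec$pool_size; mu <- spec$mutation_rate
    freq <- stats::runif(mb, maf_range[1L], maf_range[2L])
    pool <- matrix(stats::rbinom(H * mb, 1L, rep(freq, each = H)), H, mb)
    h1 <- sample.int(H, n, replace = TRUE)
    h2 <- sample.int(H, n, replace = TRUE)
    copy_with_mutation <- function(assign, jcols) {
      hap <- pool[assign, jcols, drop = FALSE]
      flips <- matrix(stats::rbinom(length(hap), 1L, mu),
                      nrow(hap), ncol(hap))
      abs(hap - flips)
    }
    G <- copy_with_mutation(h1, seq_len(mb)) +
      copy_with_mutation(h2, seq_len(mb))
    for (j in seq_len(mb)) {
      for (try in seq_len(10L)) {
        if (stats::var(G[, j]) > 0) break
        if (try == 10L)
          stop("SNP stayed monomorphic after 10 pool regenerations")
        freq[j] <- stats::runif(1L, maf_range[1L], maf_range[2L])
        pool[, j] <- stats::rbinom(H, 1L, freq[j])
        G[, j] <- copy_with_mutation(h1, j) + copy_with_mutation(h2, j)
      }
    }
    cols[[b]] <- G
  }
  G <- do.call(cbind, cols)
  m <- ncol(G)
  membership <- rep(seq_along(blocks),
                    vapply(blocks, `[[`, integer(1), "n_snps"))
  out <- genotype_matrix(G, snp_ids = sprintf("snp_%03d", seq_len(m)),
                         sample_ids = sprintf("ind_%04d", seq_len(n)),
                         positions = 10000L * seq_len(m))
  attr(out, "blocks") <- membership
  out
}

#' Block membership of simulated SNPs
#' @param x a [simulate_genotypes()] result.
#' @return integer vector, block index per SNP.
#' @export
snp_blocks <- function(x) attr(x, "blocks")

#' Place causal SNPs
#'
#' Two placement designs.  \code{"study1"}: two SNPs from block 1 and two
#' from block 2, each within-pair squared correlation constrained to
#' \code{r2_window} (so the pairs are confounded by LD but remain
#' distinguishable), plus one SNP at random from block 3 -- five true
#' signals in all.  \code{"study2"}: \code{q} SNPs uniform without
#' replacement from all m.
#'
#' @param X [simulate_genotypes()] result (needs block annotation for
#'   \code{"study1"}).
#' @param scenario \code{"study1"} or \code{"study2"}.
#' @param q number of causal SNPs (study2 only).
#' @param r2_window within-pair r-squared window for study1.
#' @param max_tries attempts to find a pair inside the window.
#' @return integer vector of causal column indices.
#' @export
place_causal <- function(X, scenario = c("study1", "study2"), q = NULL,
                         r2_window = c(0.3, 0.9), max_tries = 1000L) {
  scenario <- match.arg(scenario)
  m <- ncol(X)
  if (scenario == "study2") {
    if (is.null(q) || q < 1L || q > m) stop("study2 needs q in [1, m]")
    return(sort(sample.int(m, q)))
  }
  blocks <- snp_blocks(X)
  if (is.null(blocks) || max(blocks) < 3L)
    stop("study1 placement needs genotypes with at least 3 annotated blocks")
  pick_pair <- function(block) {
    idx <- which(blocks == block)
    for (try in seq_len(max_tries)) {
      pair <- sample(idx, 2L)
      r2 <- stats::cor(unclass(X)[, pair[1L]], unclass(X)[, pair[2L]])^2
      if (r2 >= r2_window[1L] && r2 <= r2_window[2L]) return(pair)
    }
    rr <- range(stats::cor(unclass(X)[, idx])^2, na.rm = TRUE)
    stop(sprintf(
      "no SNP pair in block %d with r2 in [%g, %g] after %d tries (block r2 range [%.3f, %.3f])",
      block, r2_window[1L], r2_window[2L], max_tries, rr[1L], rr[2L]))
  }
  sort(c(pick_pair(1L), pick_pair(2L),
         sample(which(blocks == 3L), 1L)))
}

#' Assign causal effect sizes
#'
#' \code{"moderate"} (requires q = 5): a uniformly random permutation of
#' five fixed odds ratios spanning 1.246 to 1.419 (log-evenly spaced
#' interior values), converted to log-odds.  \code{"small"}: each effect
#' is an independent signed draw, \code{beta_j = s_j * |z_j|} with
#' \code{s_j = +/-1} equiprobable and \code{z_j} normal with mean
#' \code{log(1.25)} and sd \code{0.05 * log(1.25)} truncated positive --
#' allelic odds ratios around 1.25 in either direction.
#'
#' @param q number of causal SNPs.
#' @param mode \code{"moderate"} or \code{"small"}.
#' @return numeric vector of q log-odds effects.
#' @export
assign_effects <- function(q, mode = c("moderate", "small")) {
  mode <- match.arg(mode)
  if (q < 1L) stop("q must be at least 1")
  if (mode == "moderate") {
    if (q != 5L) stop("moderate effects are a fixed set of 5 odds ratios")
    odds <- exp(seq(log(1.246), log(1.419), length.out = 5L))
    log(sample(odds))
  } else {
    mu <- log(1.25); sdev <- 0.05 * mu
    z <- stats::rnorm(q, mu, sdev)
    while (any(z <= 0)) z[z <= 0] <- stats::rnorm(sum(z <= 0), mu, sdev)
    sample(c(-1, 1), q, replace = TRUE) * z
  }
}

#' Intercept for an expected 50/50 case-control split
#'
#' Solves \eqn{\sum_i \mathrm{expit}(\mu + \eta_i) = n/2} for \eqn{\mu} by
#' bisection; the left side is strictly increasing in \eqn{\mu}, so the
#' solution exists and is unique.
#'
#' @param eta n-vector of linear predictor values (X beta, centered).
#' @param tol convergence tolerance on |expected cases - n/2| relative to
#'   n.
#' @return the intercept \eqn{\mu}.
#' @export
compute_intercept <- function(eta, tol = 1e-6) {
  if (any(!is.finite(eta))) stop("eta must be finite")
  n <- length(eta)
  f <- function(mu) sum(stats::plogis(mu + eta)) - n / 2
  lo <- -abs(max(abs(eta))) - 40
  hi <- -lo
  repeat {
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (abs(v) <= tol * n || (hi - lo) < 1e-14) return(mid)
    if (v > 0) hi <- mid else lo <- mid
  }
}

#' Bundle a true disease model
#'
#' Computes the intercept calibrating an expected 50/50 case-control
#' split and packages the causal structure used by
#' [simulate_phenotypes()].
#'
#' @param X complete genotype matrix.
#' @param causal integer vector of causal column indices.
#' @param beta log-odds effects, one per causal SNP.
#' @return list of class \code{"true_model"} with \code{causal},
#'   \code{beta}, \code{mu} and \code{truth} (binary m-vector).
#' @export
true_model <- function(X, causal, beta) {
  stopifnot(length(causal) == length(beta), !anyDuplicated(causal))
  Xc <- scale(unclass(X)[, causal, drop = FALSE], center = TRUE,
              scale = FALSE)
  eta <- drop(Xc %*% beta)
  truth <- integer(ncol(X))
  truth[causal] <- 1L
  structure(list(causal = causal, beta = beta,
                 mu = compute_intercept(eta), eta = eta, truth = truth),
            class = "true_model")
}

#' Simulate case-control phenotypes
#'
#' Bernoulli draws from the additive logistic model: \eqn{p_i =
#' \mathrm{expit}(\mu + \sum_j x_{ij} \beta_j)} with causal genotype
#' columns centered.
#'
#' @param X complete genotype matrix (complete at the causal SNPs).
#' @param model a [true_model()].
#' @return integer 0/1 phenotype vector.
#' @export
simulate_phenotypes <- function(X, model) {
  stopifnot(inherits(model, "true_model"))
  p <- stats::plogis(model$mu + model$eta)
  stats::rbinom(length(p), 1L, p)
}

#' Missingness specification
#'
#' Parameters of the empirical missingness generator: an overall target
#' proportion of deleted genotypes, a per-SNP raw-proportion density
#' capturing how much missingness varies from SNP to SNP, and the fraction
#' of individuals eligible to receive missing genotypes (the rest stay
#' complete).
#'
#' @param p_total overall target missing proportion in [0, 1).
#' @param eligible_fraction fraction of individuals eligible for deletion
#'   (<= 0.9, so at least 10 percent of individuals stay complete).
#' @param f_mis function(m) returning m raw per-SNP proportions; the
#'   default mixes 80 percent of SNPs uniform on (0, 0.5 p_total) with 20
#'   percent uniform on (0.5 p_total, 4 p_total).
#' @return list of class \code{"missingness_spec"}.
#' @export
missingness_spec <- function(p_total = 0.10, eligible_fraction = 0.9,
                             f_mis = NULL) {
  stopifnot(p_total >= 0, p_total < 1, eligible_fraction > 0,
            eligible_fraction <= 0.9)
  if (is.null(f_mis))
    f_mis <- function(m) {
      lowvar <- stats::runif(m) < 0.8
      ifelse(lowvar, stats::runif(m, 0, 0.5 * p_total),
             stats::runif(m, 0.5 * p_total, 4 * p_total))
    }
  structure(list(p_total = p_total, eligible_fraction = eligible_fraction,
                 f_mis = f_mis), class = "missingness_spec")
}

#' Delete genotypes by the empirical missingness algorithm
#'
#' (1) draws a raw missingness proportion \eqn{q_j} per SNP from the
#' spec's density; (2) marks a random subset of
#' \code{floor(eligible_fraction * n)} individuals eligible; (3) rescales
#' by \eqn{c = p_{total}\, m / \sum_j q_j} and deletes
#' \code{round(c * q_j * n)} genotypes per SNP uniformly among eligible
#' individuals, so the overall deleted fraction hits the target up to
#' rounding while missingness still varies considerably from SNP to SNP.
#'
#' @param X complete [genotype_matrix()].
#' @param spec a [missingness_spec()].
#' @return list with \code{genotypes} (matrix with NA deletions),
#'   \code{mask} (logical deletion mask), \code{eligible} (row indices),
#'   \code{q} (raw per-SNP proportions) and \code{c} (the scaling
#'   constant).
#' @export
generate_missingness <- function(X, spec = missingness_spec()) {
  stopifnot(inherits(spec, "missingness_spec"))
  Xm <- unclass(X)
  n <- nrow(Xm); m <- ncol(Xm)
  if (anyNA(Xm)) stop("input genotypes must be complete")
  n_elig <- floor(spec$eligible_fraction * n)
  eligible <- sort(sample.int(n, n_elig))
  if (spec$p_total == 0) {
    return(list(genotypes = X, mask = matrix(FALSE, n, m),
                eligible = eligible, q = numeric(m), c = 0))
  }
  for (try in seq_len(10L)) {
    q <- spec$f_mis(m)
    cc <- spec$p_total * m / sum(q)
    counts <- round(cc * q * n)
    if (all(counts <= n_elig)) break
    if (try == 10L)
      stop("per-SNP deletion count exceeds eligible individuals after 10 redraws")
  }
  mask <- matrix(FALSE, n, m)
  for (j in seq_len(m))
    if (counts[j] > 0L)
      mask[eligible[sample.int(n_elig, counts[j])], j] <- TRUE
  out <- Xm
  out[mask] <- NA_real_
  list(genotypes = genotype_matrix(out, snp_ids = colnames(X),
                                   sample_ids = rownames(X),
                                   positions = positions(X),
                                   dosage = TRUE),
       mask = mask, eligible = eligible, q = q, c = cc)
}

#' End-to-end scenario builders
#'
#' One call simulates a complete synthetic hit-region dataset under the
#' benchmark designs: \code{sim_study1a} -- 1,493 individuals, 183 SNPs of
#' moderate LD, 5 causal SNPs (two confounded pairs plus one) with
#' moderate effects (odds ratios 1.246-1.419); \code{sim_study1b} -- same
#' but small effects (odds ratios around 1.25); \code{sim_study2} -- 2,199
#' individuals, 500 SNPs of strong LD, q causal SNPs placed uniformly with
#' small effects.  Set \code{missing = TRUE} to also delete ~10 percent of
#' genotypes by the empirical missingness algorithm.
#'
#' @param n number of individuals.
#' @param blocks LD block layout.
#' @param q number of causal SNPs (study 2).
#' @param missing whether to generate an incomplete version.
#' @param miss_spec [missingness_spec()] used when \code{missing}.
#' @param r2_window within-pair r-squared constraint (study 1).
#' @return list with \code{genotypes} (complete), \code{y},
#'   \code{model} (the [true_model()]), \code{truth}, and, when
#'   \code{missing}, \code{incomplete} and \code{mask}.
#' @export
sim_study1a <- function(n = 1493L, blocks = blocks_region183(),
                        missing = FALSE, miss_spec = missingness_spec(),
                        r2_window = c(0.3, 0.9)) {
  sim_scenario_impl(n, blocks, placement = "study1", q = 5L,
                    effects = "moderate", missing, miss_spec, r2_window)
}

#' @rdname sim_study1a
#' @export
sim_study1b <- function(n = 1493L, blocks = blocks_region183(),
                        missing = FALSE, miss_spec = missingness_spec(),
                        r2_window = c(0.3, 0.9)) {
  sim_scenario_impl(n, blocks, placement = "study1", q = 5L,
                    effects = "small", missing, miss_spec, r2_window)
}

#' @rdname sim_study1a
#' @export
sim_study2 <- function(q, n = 2199L, blocks = blocks_region500(),
                       missing = FALSE, miss_spec = missingness_spec()) {
  sim_scenario_impl(n, blocks, placement = "study2", q = q,
                    effects = "small", missing, miss_spec)
}

sim_scenario_impl <- function(n, blocks, placement, q, effects, missing,
                              miss_spec, r2_window = c(0.3, 0.9)) {
  X <- simulate_genotypes(n, blocks)
  causal <- place_causal(X, scenario = placement, q = q,
                         r2_window = r2_window)
  beta <- assign_effects(length(causal), mode = effects)
  model <- true_model(X, causal, beta)
  y <- simulate_phenotypes(X, model)
  out <- list(genotypes = X, y = y, model = model, truth = model$truth)
  if (missing) {
    mg <- generate_missingness(X, miss_spec)
    out$incomplete <- mg$genotypes
    out$mask <- mg$mask
  }
  out
}
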