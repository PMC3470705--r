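#' Bundle one simulation trial's scores and truth
#'
#' @param scores m-vector of SNP scores (RMIP or logP); larger is better.
#' @param truth binary m-vector, 1 for true signals (at least one of each
#'   class).
#' @param method method label.
#' @param trial trial identifier.
#' @return list of class \code{"trial_result"}.
#' @export
trial_result <- function(scores, truth, method = "unknown", trial = NA) {
  truth <- as.integer(truth)
  if (length(scores) != length(truth))
    stop("scores and truth must have one entry per SNP")
  if (sum(truth == 1L) < 1L || sum(truth == 0L) < 1L)
    stop("truth needs at least one true signal and one background SNP")
  if (anyNA(scores)) stop("scores must not be missing")
  structure(list(scores = as.numeric(scores), truth = truth,
                 method = method, trial = trial),
            class = "trial_result")
}

#' Power and false-positive rate at a threshold
#'
#' Power is the proportion of the q true signal SNPs scoring at or above
#' \code{t}; the FPR is the analogous proportion of the m - q background
#' SNPs.
#'
#' @param scores,truth as in [trial_result()] (a \code{trial_result} may
#'   be passed as \code{scores}).
#' @param t score threshold.
#' @return named numeric vector \code{c(power, fpr)}.
#' @export
power_fpr <- function(scores, truth = NULL, t) {
  if (inherits(scores, "trial_result")) {
    truth <- scores$truth
    scores <- scores$scores
  }
  c(power = mean(scores[truth == 1L] >= t),
    fpr = mean(scores[truth == 0L] >= t))
}

# step-curve points of the ROC: thresholds sweep the distinct scores in
# descending order (ties enter together); starts at (0, 0), ends at (1, 1)
roc_points <- function(scores, truth) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  tr <- truth[ord]
  q <- sum(truth == 1L)
  bg <- sum(truth == 0L)
  keep <- which(c(diff(s) != 0, TRUE))  # last index of each tied group
  tp <- cumsum(tr == 1L)[keep]
  fp <- cumsum(tr == 0L)[keep]
  cbind(fpr = c(0, fp / bg), power = c(0, tp / q))
}

#' Windowed trapezium AUC of one trial
#'
#' Builds the ROC step curve by sweeping thresholds over the distinct
#' score values (descending; tied scores enter together), linearly
#' interpolates the curve at the window edges, integrates by the trapezium
#' rule over false-positive rates in \code{[a, b]} and normalizes by
#' \code{b - a} so windowed and full AUCs share the [0, 1] scale.  The
#' full-window AUC (\code{a = 0, b = 1}) equals the tie-corrected
#' Mann-Whitney statistic divided by \code{q (m - q)}.
#'
#' @inheritParams power_fpr
#' @param a,b false-positive-rate window, \code{0 <= a < b <= 1};
#'   \code{c(0, 0.05)} is the "initial AUC" emphasizing the top-ranked
#'   SNPs.
#' @return the normalized AUC in [0, 1].
#' @export
trial_auc <- function(scores, truth = NULL, a = 0, b = 1) {
  if (inherits(scores, "trial_result")) {
    truth <- scores$truth
    scores <- scores$scores
  }
  if (!(a >= 0 && a < b && b <= 1)) stop("need 0 <= a < b <= 1")
  pts <- roc_points(scores, truth)
  total <- 0
  for (i in seq_len(nrow(pts) - 1L)) {
    x1 <- pts[i, 1L]; x2 <- pts[i + 1L, 1L]
    if (x2 <= a || x1 >= b || x2 == x1) next
    lo <- max(x1, a); hi <- min(x2, b)
    y1 <- pts[i, 2L]; y2 <- pts[i + 1L, 2L]
    ylo <- y1 + (y2 - y1) * (lo - x1) / (x2 - x1)
    yhi <- y1 + (y2 - y1) * (hi - x1) / (x2 - x1)
    total <- total + (hi - lo) * (ylo + yhi) / 2
  }
  unname(total / (b - a))
}

#' Aggregate per-trial AUCs across a simulation study
#'
#' Reports the mean windowed AUC over trials and the variance of that
#' mean (cross-trial sample variance divided by the trial count), under
#' the normal approximation used for interval plotting.
#'
#' @param trials list of [trial_result()] objects (>= 2).
#' @param a,b false-positive-rate window.
#' @return list of class \code{"roc_summary"} with \code{auc} (per-trial
#'   values), \code{mean}, \code{var_mean}, \code{n}, \code{window}.
#' @export
summarize_trials <- function(trials, a = 0, b = 1) {
  if (length(trials) < 2L)
    stop("variance of the mean AUC needs at least 2 trials")
  auc <- vapply(trials, trial_auc, numeric(1), a = a, b = b)
  structure(list(auc = auc, mean = mean(auc),
                 var_mean = stats::var(auc) / length(auc),
                 n = length(auc), window = c(a, b)),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  se <- sqrt(x$var_mean)
  cat(sprintf(
    "AUC on FPR [%g, %g]: mean %.4f (SE %.4f, 95%% CI %.4f-%.4f, %d trials)\n",
    x$window[1L], x$window[2L], x$mean, se,
    x$mean - 1.96 * se, x$mean + 1.96 * se, x$n))
  invisible(x)
}

#' Threshold-averaged ROC curve
#'
#' For each threshold \code{t}, plots the mean false-positive rate against
#' the mean power across trials -- the threshold-averaging construction
#' for aggregating ROC curves whose scores share a common scale ([0, 1]
#' for RMIPs, [0, Inf) for logP).
#'
#' @param trials list of [trial_result()] objects.
#' @param thresholds vector of score thresholds.
#' @return data.frame with columns \code{threshold}, \code{fpr},
#'   \code{power}.
#' @export
threshold_average <- function(trials, thresholds) {
  pts <- vapply(thresholds, function(t) {
    per <- vapply(trials, power_fpr, numeric(2), t = t)
    c(mean(per["fpr", ]), mean(per["power", ]))
  }, numeric(2))
  data.frame(threshold = thresholds, fpr = pts[1L, ], power = pts[2L, ])
}

#' Run a replicated method-comparison study
#'
#' Loops simulate -> analyze -> score over replicates for each requested
#' method and aggregates windowed AUCs.  Replicate r of the study runs
#' under master seed \code{seed + r}, so a rerun with the same seed gives
#' identical results.  Individual trial failures are logged and skipped;
#' more than 10 percent failures aborts the study.
#'
#' @param scenario a function(seed) returning a list with
#'   \code{genotypes}, \code{y} and \code{truth} -- typically a wrapper
#'   around [sim_study1a()], [sim_study1b()] or [sim_study2()].
#' @param methods subset of \code{"single-locus"}, \code{"llarrma-perm"},
#'   \code{"llarrma-cdev"}, \code{"ss-oracle"}.
#' @param replicates number of simulation trials.
#' @param seed master seed.
#' @param K,phi,S resampling settings passed to the resample-based
#'   methods.
#' @param thresh LASSO solver convergence threshold for the resample-based
#'   methods (see [llarrma()]); replicated studies may relax it.
#' @param windows named list of FPR windows to report.
#' @param oracle_window FPR window maximized by the oracle calibration of
#'   stability selection.
#' @return list of class \code{"study_result"}: \code{results} (a tidy
#'   data.frame with method, window, mean AUC, variance of the mean,
#'   replicate count, seed) and \code{trials} (per method, the list of
#'   [trial_result()]s).
#' @export
run_study <- function(scenario, methods = c("single-locus", "llarrma-perm"),
                      replicates = 20L, seed = 1L, K = 100L, phi = 0.5,
                      S = 25L, thresh = 1e-12,
                      windows = list(initial = c(0, 0.05), full = c(0, 1)),
                      oracle_window = c(0, 0.05)) {
  known <- c("single-locus", "llarrma-perm", "llarrma-cdev", "ss-oracle")
  if (!all(methods %in% known))
    stop("unknown method(s): ", paste(setdiff(methods, known), collapse = ", "))
  trials <- stats::setNames(
    lapply(methods, function(m) vector("list", replicates)), methods)
  failures <- 0L
  for (r in seq_len(replicates)) {
    rep_seed <- seed + r
    ok <- tryCatch({
      set.seed(rep_seed)
      dat <- scenario(rep_seed)
      for (meth in methods) {
        sc <- switch(meth,
          "single-locus" = single_locus_scores(dat$genotypes, dat$y)$score,
          "llarrma-perm" = llarrma(dat$genotypes, dat$y, K = K, phi = phi,
                                   criterion = "perm", S = S,
                                   thresh = thresh, seed = rep_seed)$rmip,
          "llarrma-cdev" = llarrma(dat$genotypes, dat$y, K = K, phi = phi,
                                   criterion = "cdev", thresh = thresh,
                                   seed = rep_seed)$rmip,
          "ss-oracle" = {
            sp <- stability_selection(dat$genotypes, dat$y, K = K,
                                      phi = phi, thresh = thresh,
                                      seed = rep_seed)
            oracle_lambda(sp, dat$truth, window = oracle_window)$rmip
          })
        trials[[meth]][[r]] <- trial_result(sc, dat$truth, meth, r)
      }
      TRUE
    }, error = function(e) {
      message("trial ", r, " (seed ", rep_seed, ") failed: ",
              conditionMessage(e))
      FALSE
    })
    if (!ok) failures <- failures + 1L
    if (failures > 0.1 * replicates)
      stop("more than 10% of trials failed; aborting study")
  }
  trials <- lapply(trials, function(tl) Filter(Negate(is.null), tl))
  rows <- list()
  for (meth in methods) {
    for (w in names(windows)) {
      sm <- summarize_trials(trials[[meth]], windows[[w]][1L],
                             windows[[w]][2L])
      rows[[length(rows) + 1L]] <- data.frame(
        method = meth, window = w, mean_auc = sm$mean,
        var_mean = sm$var_mean, replicates = sm$n, seed = seed)
    }
  }
  structure(list(results = do.call(rbind, rows), trials = trials,
                 settings = list(K = K, phi = phi, S = S, seed = seed)),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("simulation study:",
      max(x$results$replicates), "replicates, K =", x$settings$K, "\n")
  print(x$results, row.names = FALSE, digits = 4)
  invisible(x)
}
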