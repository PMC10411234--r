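#' Log-likelihood-ratio statistic of the ideal observer
#'
#' The ideal observer computes Lambda = q2(x)/q1(x) and decides by
#' comparing it to a threshold; in a 2-AFC trial it calls "real" whichever
#' image has the larger value. All computation is done in log space
#' (lambda = log q2(x) - log q1(x)); the ratio itself is never formed, so
#' image-scale densities cannot underflow.
#'
#' @param q1,q2 [density_model][gaussian_model] objects of one dimension;
#'   `q1` is the synthetic class (H1), `q2` the real class (H2).
#' @param x a single image vector or an n x M matrix of images.
#' @return lambda = log q2(x) - log q1(x), one value per image.
#' @examples
#' a <- gaussian_model(0, matrix(1))
#' b <- gaussian_model(2, matrix(1))
#' log_likelihood_ratio(a, b, 1)  # 0: midpoint of the two means
#' @export
log_likelihood_ratio <- function(q1, q2, x) {
  stopifnot(inherits(q1, "density_model"), inherits(q2, "density_model"))
  if (q1$dimension != q2$dimension) {
    stop("q1 and q2 must have the same dimension", call. = FALSE)
  }
  log_density(q2, x) - log_density(q1, x)
}

new_auc_result <- function(auc, estimator, n_pairs = NULL,
                           mc_std_error = NULL, tie_fraction = NULL) {
  res <- list(auc = auc, estimator = estimator)
  if (!is.null(n_pairs)) res$n_pairs <- n_pairs
  if (!is.null(mc_std_error)) res$mc_std_error <- mc_std_error
  if (!is.null(tie_fraction)) res$tie_fraction <- tie_fraction
  structure(res, class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("<auc_result> AUC=%.6g  [%s]%s%s\n", x$auc, x$estimator,
              if (!is.null(x$mc_std_error))
                sprintf("  se=%.3g", x$mc_std_error) else "",
              if (!is.null(x$n_pairs))
                sprintf("  n_pairs=%d", x$n_pairs) else ""))
  invisible(x)
}

#' Monte-Carlo 2-AFC AUC of an observer
#'
#' Simulates the 2-AFC experiment: each trial presents one synthetic image
#' drawn from `q1` and one real image drawn from `q2`; the observer calls
#' "real" the image with the larger test statistic. The fraction of correct
#' calls, with ties scored one half, is the observer's AUC.
#'
#' @param q1,q2 [density_model][gaussian_model] objects; `q1` is the
#'   synthetic class, `q2` the real class.
#' @param statistic the observer's scalar test statistic, a function of one
#'   image vector. `NULL` (default) uses the ideal observer's
#'   log-likelihood ratio, evaluated vectorized.
#' @param n_pairs number of simulated trials.
#' @param seed integer seed.
#' @param pairing `"sequential"` (default) scores the i-th real draw
#'   against the i-th synthetic draw, the literal 2-AFC experiment;
#'   `"all_pairs"` scores every real draw against every synthetic draw,
#'   which coincides exactly with the tie-corrected rank-sum AUC
#'   ([auc_empirical_roc()]) of the same scores.
#' @return An `auc_result` with `auc`, binomial-style `mc_std_error`,
#'   `tie_fraction` and `n_pairs`.
#' @examples
#' a <- gaussian_model(c(0, 0), diag(2))
#' b <- gaussian_model(c(2, 0), diag(2))
#' auc_2afc_mc(a, b, n_pairs = 2000, seed = 1)  # about pnorm(sqrt(2))
#' @export
auc_2afc_mc <- function(q1, q2, statistic = NULL, n_pairs, seed,
                        pairing = c("sequential", "all_pairs")) {
  stopifnot(inherits(q1, "density_model"), inherits(q2, "density_model"))
  pairing <- match.arg(pairing)
  n_pairs <- as.integer(n_pairs)
  if (is.na(n_pairs) || n_pairs < 1L) stop("`n_pairs` must be >= 1",
                                           call. = FALSE)
  draws <- local_rng(seed, list(
    xs = sample_model_impl(q1, n_pairs),
    xr = sample_model_impl(q2, n_pairs)
  ))
  if (is.null(statistic)) {
    ts <- log_likelihood_ratio(q1, q2, draws$xs)
    tr <- log_likelihood_ratio(q1, q2, draws$xr)
  } else {
    ts <- apply(draws$xs, 1L, statistic)
    tr <- apply(draws$xr, 1L, statistic)
  }
  bad <- which(!is.finite(ts) | !is.finite(tr))
  if (length(bad)) {
    stop(sprintf("statistic returned a non-finite value at pair index %d",
                 bad[1L]), call. = FALSE)
  }
  if (pairing == "sequential") {
    wins <- (tr > ts) + 0.5 * (tr == ts)
    auc <- mean(wins)
    ties <- mean(tr == ts)
  } else {
    # integer win/tie counts keep the half-integer numerator exact, so
    # the result is bit-identical to the rank-sum estimator
    n_win <- sum(outer(tr, ts, `>`))
    n_tie <- sum(outer(tr, ts, `==`))
    auc <- (n_win + 0.5 * n_tie) / (as.numeric(n_pairs) * n_pairs)
    ties <- n_tie / (as.numeric(n_pairs) * n_pairs)
  }
  new_auc_result(auc, "two_afc_mc", n_pairs = n_pairs,
                 mc_std_error = sqrt(auc * (1 - auc) / n_pairs),
                 tie_fraction = ties)
}

#' Empirical (rank-sum) AUC from two score samples
#'
#' Tie-corrected Mann-Whitney AUC: the fraction of (H1, H2) score pairs
#' with the H2 score larger, ties counted one half. Computed by ranking,
#' not the O(n1 n2) double loop, but equal to it.
#'
#' @param scores_h1 scores of the synthetic-class (H1) images.
#' @param scores_h2 scores of the real-class (H2) images.
#' @return An `auc_result` with estimator `"empirical_roc"`.
#' @examples
#' auc_empirical_roc(c(0, 1), c(2, 3))$auc  # 1
#' @export
auc_empirical_roc <- function(scores_h1, scores_h2) {
  scores_h1 <- as.numeric(scores_h1)
  scores_h2 <- as.numeric(scores_h2)
  if (!length(scores_h1) || !length(scores_h2)) {
    stop("both score sequences must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(c(scores_h1, scores_h2)))) {
    stop("scores must be finite", call. = FALSE)
  }
  n1 <- length(scores_h1); n2 <- length(scores_h2)
  r <- rank(c(scores_h1, scores_h2), ties.method = "average")
  auc <- (sum(r[n1 + seq_len(n2)]) - n2 * (n2 + 1) / 2) / (n1 * n2)
  new_auc_result(auc, "empirical_roc", n_pairs = NULL)
}

#' Bhattacharyya quantities from log-likelihood-ratio samples
#'
#' Uses the identity G(0) = -4 log <Lambda^(1/2)>_1: the Bhattacharyya
#' coefficient equals the H1 expectation of exp(lambda/2), so a sample of
#' lambda values drawn under H1 yields a Monte-Carlo estimate of BC, the
#' distance D_B = -log BC and G(0) = 4 D_B. The standard error of the
#' coefficient is propagated to the distance by the delta method. An
#' estimated coefficient exceeding 1 by more than 3 standard errors sets
#' the `flagged` field (mis-specified lambda or undersampling), without
#' failing.
#'
#' @param lambda_h1 numeric vector of lambda values drawn under H1.
#' @return A `bhattacharyya_result` with method `"sample_mc"`.
#' @export
bhattacharyya_from_lr_samples <- function(lambda_h1) {
  lambda_h1 <- as.numeric(lambda_h1)
  if (!length(lambda_h1)) stop("`lambda_h1` must be non-empty",
                               call. = FALSE)
  if (any(!is.finite(lambda_h1))) {
    stop("lambda values must be finite", call. = FALSE)
  }
  w <- exp(0.5 * lambda_h1)
  bc <- mean(w)
  n <- length(w)
  se <- if (n > 1L) stats::sd(w) / sqrt(n) else 0
  new_bhattacharyya_result(coefficient = bc, method = "sample_mc",
                           mc_std_error = se, n_samples = n,
                           flagged = bc > 1 + 3 * se)
}

#' AUC approximation from the Bhattacharyya distance
#'
#' The ideal-observer AUC, to an excellent approximation (exact when the
#' log-likelihood ratio is Gaussian, as for equal-covariance Gaussian
#' classes), is
#' \deqn{AUC = 1/2 + 1/2\,\mathrm{erf}(\sqrt{2 D_B}),}
#' strictly increasing in the distance, equal to 1/2 exactly when the two
#' distributions coincide (D_B = 0) and saturating at 1.
#'
#' @param distance Bhattacharyya distance(s), >= 0.
#' @return AUC value(s) in `[0.5, 1)`.
#' @examples
#' auc_approx_from_db(0)    # 0.5
#' auc_approx_from_db(0.5)  # about 0.92135
#' @export
auc_approx_from_db <- function(distance) {
  distance <- as.numeric(distance)
  if (any(!is.finite(distance)) || any(distance < 0)) {
    stop("`distance` must be nonnegative", call. = FALSE)
  }
  0.5 + 0.5 * erf(sqrt(2 * distance))
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Monte-Carlo check of the likelihood-ratio moment identity
#'
#' The moments of Lambda under the two hypotheses are linked by
#' <Lambda^k>_2 = <Lambda^(k+1)>_1. Both sides are estimated by Monte
#' Carlo under their respective hypotheses and compared at a 3-combined-
#' standard-error tolerance.
#'
#' @param q1,q2 [density_model][gaussian_model] objects.
#' @param k moment order, 0, 1 or 2.
#' @param n Monte-Carlo sample size per side (>= 1000).
#' @param seed integer seed.
#' @return A list with `lhs`, `rhs`, their standard errors, the combined
#'   tolerance and a logical `agree`.
#' @export
moment_identity_check <- function(q1, q2, k, n, seed) {
  k <- as.integer(k)
  if (is.na(k) || k < 0L || k > 2L) stop("`k` must be 0, 1 or 2",
                                         call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 1000L) stop("`n` must be >= 1000", call. = FALSE)
  draws <- local_rng(seed, list(
    x1 = sample_model_impl(q1, n),
    x2 = sample_model_impl(q2, n)
  ))
  lam1 <- log_likelihood_ratio(q1, q2, draws$x1)
  lam2 <- log_likelihood_ratio(q1, q2, draws$x2)
  lhs_w <- exp(k * lam2)        # <Lambda^k>_2
  rhs_w <- exp((k + 1) * lam1)  # <Lambda^(k+1)>_1
  lhs <- mean(lhs_w); rhs <- mean(rhs_w)
  se_l <- stats::sd(lhs_w) / sqrt(n)
  se_r <- stats::sd(rhs_w) / sqrt(n)
  tol <- 3 * sqrt(se_l^2 + se_r^2)
  structure(list(k = k, lhs = lhs, rhs = rhs, lhs_se = se_l, rhs_se = se_r,
                 tolerance = tol, agree = abs(lhs - rhs) <= tol, n = n),
            class = "identity_report")
}

#' Monte-Carlo check of the lambda density identity
#'
#' The densities of lambda under the two hypotheses satisfy
#' p2(lambda) = exp(lambda) p1(lambda). The check draws lambda under both
#' hypotheses, histograms lambda|H2 on shared bin edges against the
#' exp(lambda)-weighted histogram of lambda|H1, and reports per-bin
#' discrepancies with a Monte-Carlo tolerance. Bins empty on both sides
#' are flagged, not failed; bins with fewer than 10 effective counts on
#' both sides are reported as sparse and likewise excluded from the
#' verdict, since the plug-in standard error is unreliable there.
#'
#' @param q1,q2 [density_model][gaussian_model] objects.
#' @param n Monte-Carlo sample size per hypothesis (>= 1e4).
#' @param bins number of histogram bins (>= 10).
#' @param seed integer seed.
#' @return A list with the bin table (`breaks`, per-bin masses, standard
#'   errors, discrepancies), `max_discrepancy`, `max_tolerance`, logical
#'   `agree` and the count of `empty_bins`.
#' @export
lambda_density_identity_check <- function(q1, q2, n, bins, seed) {
  n <- as.integer(n); bins <- as.integer(bins)
  if (is.na(n) || n < 1e4) stop("`n` must be >= 10000", call. = FALSE)
  if (is.na(bins) || bins < 10L) stop("`bins` must be >= 10", call. = FALSE)
  draws <- local_rng(seed, list(
    x1 = sample_model_impl(q1, n),
    x2 = sample_model_impl(q2, n)
  ))
  lam1 <- log_likelihood_ratio(q1, q2, draws$x1)
  lam2 <- log_likelihood_ratio(q1, q2, draws$x2)
  rng <- range(c(lam1, lam2))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)  # point mass (q1 = q2)
  breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  bin1 <- findInterval(lam1, breaks, rightmost.closed = TRUE,
                       all.inside = TRUE)
  bin2 <- findInterval(lam2, breaks, rightmost.closed = TRUE,
                       all.inside = TRUE)
  w1 <- exp(lam1)  # reweights H1 draws to the H2 law
  mass2 <- tabulate(bin2, nbins = bins) / n
  mass1w <- vapply(seq_len(bins), function(b) sum(w1[bin1 == b]),
                   numeric(1)) / n
  se2 <- sqrt(mass2 * (1 - mass2) / n)
  se1w <- vapply(seq_len(bins), function(b) {
    v <- w1 * (bin1 == b)
    stats::sd(v) / sqrt(n)
  }, numeric(1))
  tol <- 3 * sqrt(se2^2 + se1w^2)
  disc <- abs(mass2 - mass1w)
  count1 <- tabulate(bin1, nbins = bins)
  count2 <- tabulate(bin2, nbins = bins)
  empty <- count1 == 0L & count2 == 0L
  # a bin is only judged where both estimators have real support: >= 10
  # raw draws on each side (chi-square-test convention). In particular
  # the exp(lambda)-reweighted histogram cannot estimate H2 mass in
  # regions H1 never visits; such bins are reported as sparse.
  sparse <- !empty & (count1 < 10L | count2 < 10L)
  tested <- which(!empty & !sparse)
  structure(list(
    breaks = breaks, mass_h2 = mass2, mass_h1_weighted = mass1w,
    discrepancy = disc, tolerance = tol, empty_bins = sum(empty),
    sparse_bins = sum(sparse),
    max_discrepancy = max(disc[tested]),
    max_tolerance = max(tol[tested]),
    agree = all(disc[tested] <= pmax(tol[tested], 1e-12)),
    n = n
  ), class = "identity_report")
}

#' @export
print.identity_report <- function(x, ...) {
  if (!is.null(x$lhs)) {
    cat(sprintf(
      "<identity_report> <L^%d>_2 = %.6g (se %.3g) vs <L^%d>_1 = %.6g (se %.3g): %s\n",
      x$k, x$lhs, x$lhs_se, x$k + 1L, x$rhs, x$rhs_se,
      if (x$agree) "agree" else "DISAGREE"))
  } else {
    cat(sprintf(
      "<identity_report> lambda-density check: max discrepancy %.3g (tol %.3g), %d empty bins: %s\n",
      x$max_discrepancy, x$max_tolerance, x$empty_bins,
      if (x$agree) "agree" else "DISAGREE"))
  }
  invisible(x)
}
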