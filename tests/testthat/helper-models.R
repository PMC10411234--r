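# Shared fixtures and independent oracles. Oracles here never call the
# code paths they check.

# O(n1*n2) double-loop AUC with ties counted one half.
brute_force_auc <- function(s1, s2) {
  tot <- 0
  for (a in s1) {
    tot <- tot + sum(s2 > a) + 0.5 * sum(s2 == a)
  }
  tot / (length(s1) * length(s2))
}

# Random SPD matrix via A'A + eps*I.
random_spd <- function(m) {
  a <- matrix(stats::rnorm(m * m), m, m)
  crossprod(a) + diag(m) * 0.5
}

# Closed-form AUC of the ideal observer for equal-covariance Gaussians:
# Phi(d_A / sqrt(2)) with d_A^2 the Mahalanobis separation.
equal_cov_ideal_auc <- function(mu1, mu2, sigma) {
  d2 <- drop(crossprod(mu2 - mu1, solve(sigma, mu2 - mu1)))
  stats::pnorm(sqrt(d2) / sqrt(2))
}

# erf by direct quadrature of its definition.
erf_oracle <- function(x) {
  2 / sqrt(pi) * stats::integrate(function(t) exp(-t^2), 0, x,
                                  rel.tol = 1e-12)$value
}

std_gauss_2d <- function() gaussian_model(c(0, 0), diag(2))
shift_gauss_2d <- function(s = 2) gaussian_model(c(s, 0), diag(2))

# Tiny valid study setup with real files on disk.
tiny_config <- function(n = 6L, shuffle = FALSE, shuffle_seed = 1L,
                        dir = withr::local_tempdir(.local_envir =
                                                     parent.frame())) {
  ps <- file.path(dir, sprintf("s%02d.csv", seq_len(n)))
  pr <- file.path(dir, sprintf("r%02d.csv", seq_len(n)))
  for (p in c(ps, pr)) {
    utils::write.table(matrix(seq_len(4), 2, 2), p, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  study_config("tiny study", "1234",
               data.frame(synthetic = ps, real = pr,
                          stringsAsFactors = FALSE),
               shuffle = shuffle, shuffle_seed = shuffle_seed)
}
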