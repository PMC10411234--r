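test_that("two-pixel dataset delegates its math to the core modules", {
  spec <- two_pixel_spec(c(0, 0), c(2, 0))
  ds <- two_pixel_dataset(spec, n_per_class = 200, seed = 5)
  expect_equal(dim(ds$samples_h1), c(200L, 2L))
  # no duplicated math: results equal the module outputs on the same spec
  expect_equal(ds$bhattacharyya,
               bhattacharyya(gaussian_model(c(0, 0), diag(2)),
                             gaussian_model(c(2, 0), diag(2)),
                             "closed_form"))
  expect_equal(ds$auc_approx$auc,
               auc_approx_from_db(ds$bhattacharyya$distance))
  expect_identical(ds$samples_h1,
                   sample_model(gaussian_model(c(0, 0), diag(2)), 200,
                                seed = 5))
  expect_error(two_pixel_spec(c(0, 0), c(1, 0), matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("perfect overlap floors the AUC; MC agrees with the approximation", {
  same <- two_pixel_dataset(two_pixel_spec(c(1, 1), c(1, 1)), 10, seed = 1)
  expect_identical(same$bhattacharyya$distance, 0)
  expect_identical(same$auc_approx$auc, 0.5)
  ds <- two_pixel_dataset(two_pixel_spec(c(0, 0), c(2, 0)), 10, seed = 1)
  expect_equal(ds$auc_approx$auc, pnorm(sqrt(2)), tolerance = 1e-12)
  mc <- auc_2afc_mc(ds$q1, ds$q2, n_pairs = 2e4, seed = 2)
  expect_lt(abs(mc$auc - ds$auc_approx$auc), 3 * mc$mc_std_error)
})

test_that("AUC-versus-overlap sweep is monotone toward the 0.5 floor", {
  sw <- two_pixel_sweep(seq(3, 0, by = -0.5))
  expect_true(all(diff(sw$auc) < 0))
  expect_identical(sw$auc[nrow(sw)], 0.5)
  expect_identical(sw$coefficient[nrow(sw)], 1)
  expect_true(all(diff(sw$coefficient) > 0))
})

test_that("phantom generator is deterministic and honors its spec", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  spec <- phantom_spec(image_size = c(32L, 32L), psf_fwhm = 1.5)
  m1 <- phantom_pairs(spec, 2, seed = 4, dir = dir1)
  phantom_pairs(spec, 2, seed = 4, dir = dir2)
  pngs <- list.files(dir1, pattern = "\\.png$")
  expect_length(pngs, 4L)
  for (p in pngs) {
    expect_identical(readBin(file.path(dir1, p), "raw", 1e6),
                     readBin(file.path(dir2, p), "raw", 1e6))
  }
  # manifest records ground truth per image
  man <- jsonlite::fromJSON(file.path(dir1, "manifest.json"),
                            simplifyDataFrame = FALSE)
  expect_equal(man$seed, 4L)
  expect_length(man$pairs, 2L)
  expect_true(all(c("synthetic", "real") %in% names(man$pairs[[1]])))
  img <- read_image(file.path(dir1, man$pairs[[1]]$real$file))
  expect_equal(img$shape, c(32L, 32L))
  expect_equal(img$bit_depth, 16L)
  expect_error(phantom_spec(image_size = c(16L, 16L),
                            lesion_radius_range = c(5, 8)),
               "too large")
})

test_that("lesion-free unblurred phantom has Poisson interior statistics", {
  spec <- phantom_spec(image_size = c(48L, 48L), background_activity = 50,
                       lesion_count_range = c(0L, 0L), psf_fwhm = 0)
  dir <- withr::local_tempdir()
  phantom_pairs(spec, 1, seed = 8, dir = dir)
  img <- read_image(file.path(dir, "real_001.png"))
  m <- matrix(img$values, 48, 48, byrow = TRUE)
  # interior of the body ellipse (radius 0.4 * side, kept well inside)
  yy <- matrix(1:48, 48, 48); xx <- t(yy)
  core <- ((yy - 24.5) / (0.3 * 48))^2 + ((xx - 24.5) / (0.3 * 48))^2 <= 1
  vals <- m[core]
  n <- length(vals)
  expect_lt(abs(mean(vals) - 50), 3 * sqrt(50 / n))
  # Poisson variance equals the mean; chi-square-style 3-sigma band
  expect_lt(abs(var(vals) - 50), 3 * 50 * sqrt(2 / (n - 1)))
})

test_that("realism gap controls arm exchangeability", {
  # with gap 0 the arms share one generative process: a scalar image
  # statistic separates them only at chance
  spec0 <- phantom_spec(image_size = c(24L, 24L), realism_gap = 0,
                        psf_fwhm = 1)
  dir <- withr::local_tempdir()
  n <- 220L
  phantom_pairs(spec0, n, seed = 12, dir = dir)
  mean_of <- function(arm, i) {
    mean(read_image(file.path(dir, sprintf("%s_%03d.png", arm, i)))$values)
  }
  syn <- vapply(seq_len(n), function(i) mean_of("synthetic", i), 0)
  rea <- vapply(seq_len(n), function(i) mean_of("real", i), 0)
  auc0 <- auc_empirical_roc(syn, rea)$auc
  expect_lt(abs(auc0 - 0.5), 3 * sqrt((n + n + 1) / (12 * n * n)))
  # a large gap separates the arms far beyond chance
  dirg <- withr::local_tempdir()
  specg <- phantom_spec(image_size = c(24L, 24L), realism_gap = 0.5,
                        psf_fwhm = 1)
  phantom_pairs(specg, 60L, seed = 13, dir = dirg)
  sg <- vapply(1:60, function(i) {
    mean(read_image(file.path(dirg, sprintf("synthetic_%03d.png", i)))$values)
  }, 0)
  rg <- vapply(1:60, function(i) {
    mean(read_image(file.path(dirg, sprintf("real_%03d.png", i)))$values)
  }, 0)
  # synthetic arm is brighter, so real-arm scores sit below synthetic
  expect_lt(auc_empirical_roc(sg, rg)$auc, 0.2)
})

test_that("virtual readers hit their accuracy targets", {
  cfg <- tiny_config(n = 50L, shuffle = TRUE, shuffle_seed = 2L)
  ses <- build_session(cfg)
  # exact counts: 22 of 50 reproduces a 44% reader
  spec <- virtual_reader_spec(0.44, mode = "exact_counts")
  log <- virtual_reader_log(spec, ses, "vr", seed = 1)
  s <- score_responses(ses, log, "vr")
  expect_equal(s$n_correct, 22L)
  expect_equal(s$percent_accuracy_rounded, 44)
  # perfect reader
  all_right <- virtual_reader_log(virtual_reader_spec(1), ses, "vr2",
                                  seed = 2)
  expect_equal(score_responses(ses, all_right, "vr2")$n_correct, 50L)
  # stochastic mode: binomial 3-sigma band, pooled over 6 x 50 = 300
  big <- do.call(rbind, lapply(1:6, function(i) {
    virtual_reader_log(virtual_reader_spec(0.55), ses,
                       paste0("r", i), seed = 10 + i)
  }))
  pooled <- pooled_summary(lapply(1:6, function(i) {
    score_responses(ses, big, paste0("r", i))
  }))
  expect_lt(abs(pooled$n_correct - 165), 3 * sqrt(300 * 0.55 * 0.45))
  # infeasible exact counts are rejected with the required numbers
  bad <- virtual_reader_spec(0.5, mode = "exact_counts",
                             correct_counts = c(1L, 0L, 0L, 0L, 0L),
                             incorrect_counts = c(25L, 0L, 0L, 0L, 0L))
  expect_error(virtual_reader_log(bad, ses, "vr", seed = 1),
               "infeasible")
})

test_that("exact-count fixtures reproduce any target tally", {
  cfg <- tiny_config(n = 50L)
  ses <- build_session(cfg)
  target_cc <- c(3L, 4L, 5L, 6L, 4L)   # 22 correct
  target_ic <- c(10L, 8L, 6L, 3L, 1L)  # 28 incorrect
  spec <- virtual_reader_spec(0.44, mode = "exact_counts",
                              correct_counts = target_cc,
                              incorrect_counts = target_ic)
  s <- score_responses(ses, virtual_reader_log(spec, ses, "vr", 3), "vr")
  expect_equal(as.integer(s$confidence_tally["correct", ]), target_cc)
  expect_equal(as.integer(s$confidence_tally["incorrect", ]), target_ic)
})

test_that("an ideal virtual reader converges to the ideal-observer AUC", {
  # study-level equivalence: a reader choosing by the likelihood ratio
  # attains percent accuracy equal to the 2-AFC AUC
  q1 <- std_gauss_2d(); q2 <- shift_gauss_2d(1.2)
  target <- equal_cov_ideal_auc(c(0, 0), c(1.2, 0), diag(2))
  n <- 2000L
  lam_s <- log_likelihood_ratio(q1, q2, sample_model(q1, n, seed = 61))
  lam_r <- log_likelihood_ratio(q1, q2, sample_model(q2, n, seed = 62))
  acc <- mean(lam_r > lam_s)
  mc <- auc_2afc_mc(q1, q2, n_pairs = n, seed = 63)
  se <- sqrt(target * (1 - target) / n)
  expect_lt(abs(acc - mc$auc), 3 * sqrt(2) * se)
  expect_lt(abs(acc - target), 3 * se)
})
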