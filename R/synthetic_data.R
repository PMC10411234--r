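#' Two-pixel Gaussian image-pair specification
#'
#' The minimal illustration of the realism framework: "images" of two
#' pixels whose synthetic and real classes are bivariate Gaussians with a
#' shared covariance and different means. As the means approach each
#' other the Bhattacharyya distance shrinks and the ideal-observer AUC
#' falls to its floor of 0.5.
#'
#' @param mu1 mean of the synthetic class (length 2).
#' @param mu2 mean of the real class (length 2).
#' @param sigma shared 2 x 2 covariance (symmetric positive definite).
#' @return An object of class `two_pixel_spec`.
#' @export
two_pixel_spec <- function(mu1, mu2, sigma = diag(2)) {
  mu1 <- as.numeric(mu1); mu2 <- as.numeric(mu2)
  if (length(mu1) != 2L || length(mu2) != 2L) {
    stop("`mu1` and `mu2` must have length 2", call. = FALSE)
  }
  sigma <- as_spd_matrix(sigma, 2L, "sigma")
  structure(list(mu1 = mu1, mu2 = mu2, sigma = sigma),
            class = "two_pixel_spec")
}

#' Generate a labeled two-pixel dataset with its exact analysis
#'
#' Draws `n_per_class` images from each class and returns them together
#' with the closed-form Bhattacharyya result and the erf-approximation
#' AUC for the specification. The math is fully delegated to
#' [bhattacharyya()] and [auc_approx_from_db()]; nothing is recomputed
#' here.
#'
#' @param spec a [two_pixel_spec()].
#' @param n_per_class draws per class.
#' @param seed integer seed.
#' @return A list with `samples_h1`, `samples_h2` (n x 2 matrices),
#'   `q1`, `q2` (the two [gaussian_model()]s), `bhattacharyya`
#'   (closed form) and `auc_approx` (an `auc_result`).
#' @export
two_pixel_dataset <- function(spec, n_per_class, seed) {
  stopifnot(inherits(spec, "two_pixel_spec"))
  q1 <- gaussian_model(spec$mu1, spec$sigma)
  q2 <- gaussian_model(spec$mu2, spec$sigma)
  bh <- bhattacharyya(q1, q2, "closed_form")
  list(
    samples_h1 = sample_model(q1, n_per_class, seed),
    samples_h2 = sample_model(q2, n_per_class, seed + 1L),
    q1 = q1, q2 = q2,
    bhattacharyya = bh,
    auc_approx = new_auc_result(auc_approx_from_db(bh$distance),
                                "bhattacharyya_approx")
  )
}

#' AUC versus overlap sweep for the two-pixel setup
#'
#' Sweeps the mean separation of the two classes and tabulates the
#' Bhattacharyya coefficient, distance and approximate AUC, reproducing
#' the characteristic AUC-versus-overlap curve: AUC 1 at no overlap,
#' falling monotonically to 0.5 at perfect overlap.
#'
#' @param separations numeric vector of mean separations along the first
#'   pixel axis (>= 0).
#' @param sigma shared covariance.
#' @return A data frame with columns `separation`, `coefficient`,
#'   `distance`, `auc`.
#' @export
two_pixel_sweep <- function(separations, sigma = diag(2)) {
  rows <- lapply(as.numeric(separations), function(s) {
    spec <- two_pixel_spec(c(0, 0), c(s, 0), sigma)
    bh <- bhattacharyya(gaussian_model(spec$mu1, spec$sigma),
                        gaussian_model(spec$mu2, spec$sigma),
                        "closed_form")
    data.frame(separation = s, coefficient = bh$coefficient,
               distance = bh$distance,
               auc = auc_approx_from_db(bh$distance))
  })
  do.call(rbind, rows)
}

#' Virtual-reader specification
#'
#' A parameterized stand-in for a human observer, used to generate
#' response logs with controlled accuracy and confidence structure. In
#' `stochastic` mode each trial is answered correctly with probability
#' `accuracy` and the confidence is drawn from the conditional
#' distribution matching the outcome. In `exact_counts` mode the log is
#' constructed so that the tallies match round(accuracy * n) correct
#' decisions and the per-confidence counts exactly, for worked-example
#' fixtures.
#'
#' @param accuracy probability (or exact fraction) of a correct decision.
#' @param confidence_given_correct,confidence_given_incorrect probability
#'   vectors over confidence levels 1-5 (sum to 1 within 1e-12).
#' @param mode `"stochastic"` or `"exact_counts"`.
#' @param correct_counts,incorrect_counts optional length-5 integer
#'   vectors of exact per-confidence counts (`exact_counts` mode only);
#'   when supplied they override the apportionment of the probability
#'   vectors.
#' @return An object of class `virtual_reader_spec`.
#' @export
virtual_reader_spec <- function(accuracy,
                                confidence_given_correct = rep(0.2, 5),
                                confidence_given_incorrect = rep(0.2, 5),
                                mode = c("stochastic", "exact_counts"),
                                correct_counts = NULL,
                                incorrect_counts = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(accuracy) || accuracy < 0 || accuracy > 1) {
    stop("`accuracy` must be in [0, 1]", call. = FALSE)
  }
  for (v in list(confidence_given_correct, confidence_given_incorrect)) {
    if (length(v) != 5L || any(v < 0) || abs(sum(v) - 1) > 1e-12) {
      stop("confidence vectors must be length-5 probabilities summing to 1",
           call. = FALSE)
    }
  }
  structure(list(
    accuracy = accuracy,
    confidence_given_correct = confidence_given_correct,
    confidence_given_incorrect = confidence_given_incorrect,
    mode = mode,
    correct_counts = correct_counts,
    incorrect_counts = incorrect_counts
  ), class = "virtual_reader_spec")
}

#' Generate a response log from a virtual reader
#'
#' @param spec a [virtual_reader_spec()].
#' @param session a [build_session()] trial table.
#' @param reader_id text id recorded in the log.
#' @param seed integer seed.
#' @return A response-log data frame (see [read_response_log()]).
#' @export
virtual_reader_log <- function(spec, session, reader_id, seed) {
  stopifnot(inherits(spec, "virtual_reader_spec"))
  n <- nrow(session)
  if (spec$mode == "stochastic") {
    draws <- local_rng(seed, {
      correct <- stats::runif(n) < spec$accuracy
      conf <- integer(n)
      conf[correct] <- sample.int(5L, sum(correct), replace = TRUE,
                                  prob = spec$confidence_given_correct)
      conf[!correct] <- sample.int(5L, sum(!correct), replace = TRUE,
                                   prob = spec$confidence_given_incorrect)
      list(correct = correct, conf = conf)
    })
  } else {
    n_correct <- round(spec$accuracy * n)
    cc <- spec$correct_counts
    ic <- spec$incorrect_counts
    if (is.null(cc)) cc <- apportion(spec$confidence_given_correct,
                                     n_correct)
    if (is.null(ic)) ic <- apportion(spec$confidence_given_incorrect,
                                     n - n_correct)
    if (sum(cc) != n_correct || sum(ic) != n - n_correct) {
      stop(sprintf(
        "exact_counts infeasible: need %d correct and %d incorrect, counts sum to %d and %d",
        n_correct, n - n_correct, sum(cc), sum(ic)), call. = FALSE)
    }
    which_correct <- local_rng(seed, sample.int(n, n_correct))
    correct <- seq_len(n) %in% which_correct
    conf <- integer(n)
    conf[correct] <- rep(1:5, times = cc)
    conf[!correct] <- rep(1:5, times = ic)
    draws <- list(correct = correct, conf = conf)
  }
  chose_left <- draws$correct == session$left_is_real
  data.frame(
    reader_id = reader_id,
    trial_id = session$trial_id,
    chosen_side = ifelse(chose_left, "left", "right"),
    confidence = draws$conf,
    comment = "",
    stringsAsFactors = FALSE
  )
}

# Largest-remainder apportionment of `total` among 5 bins with target
# probabilities `p`.
apportion <- function(p, total) {
  exact <- p * total
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Worked-example fixture logs for a six-reader PET realism study
#'
#' Builds an entirely synthetic 50-trial session and two sets of
#' exact-count response logs mirroring the published summaries of a
#' 2-AFC study in which six expert readers (five PET physicians and one
#' PET physicist) judged 50 real/synthetic FDG-PET image pairs:
#'
#' * `reader_logs`: per-reader accuracies 44, 58, 50, 58, 44, 58 percent
#'   with median confidence levels 2, 4, 2, 3, 4, 4 — each reader's
#'   confidences are constant at the reported median.
#' * `pooled_logs`: a six-reader fixture totalling 164/300 correct
#'   decisions, 71 of the correct ones at confidence >= 4 and 34 of the
#'   136 incorrect ones at confidence >= 4. The full five-bin confidence
#'   split is not published; the split used here is one synthetic
#'   apportionment consistent with those printed marginals. (The printed
#'   per-reader accuracies imply 156/300, not 164/300; the two fixture
#'   sets are therefore kept separate and no reconciliation is
#'   attempted.)
#'
#' @param dir directory in which placeholder image files are created
#'   (defaults to a temporary directory).
#' @return A list with `config`, `session`, `reader_logs` (list of 6
#'   data frames), `pooled_logs` (list of 6 data frames).
#' @export
paper_worked_example <- function(dir = tempfile("afc-fixture-")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- 50L
  paths_s <- file.path(dir, sprintf("synthetic_%02d.csv", seq_len(n)))
  paths_r <- file.path(dir, sprintf("real_%02d.csv", seq_len(n)))
  for (p in c(paths_s, paths_r)) {
    utils::write.table(matrix(0, 2, 2), p, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  config <- study_config(
    "PET realism worked example", "0000",
    data.frame(synthetic = paths_s, real = paths_r,
               stringsAsFactors = FALSE),
    shuffle = FALSE, shuffle_seed = 20230321L)
  session <- build_session(config)

  reader_ids <- c(paste0("PET physician ", 1:5), "PET physicist")
  correct_n <- c(22L, 29L, 25L, 29L, 22L, 29L)   # 44/58/50/58/44/58 %
  med_conf <- c(2L, 4L, 2L, 3L, 4L, 4L)
  reader_logs <- lapply(seq_along(reader_ids), function(i) {
    cc <- integer(5L); cc[med_conf[i]] <- correct_n[i]
    ic <- integer(5L); ic[med_conf[i]] <- n - correct_n[i]
    spec <- virtual_reader_spec(correct_n[i] / n, mode = "exact_counts",
                                correct_counts = cc,
                                incorrect_counts = ic)
    virtual_reader_log(spec, session, reader_ids[i], seed = 100L + i)
  })

  # Pooled fixture: 164/300 correct (71 at confidence >= 4),
  # 136 incorrect (34 at confidence >= 4).
  pooled_correct <- c(28L, 27L, 27L, 28L, 27L, 27L)          # sums to 164
  corr_conf_pool <- rep(1:5, times = c(30L, 33L, 30L, 36L, 35L))  # 164
  inc_conf_pool <- rep(1:5, times = c(40L, 32L, 30L, 20L, 14L))   # 136
  ci <- 0L; ii <- 0L
  pooled_logs <- lapply(seq_along(reader_ids), function(i) {
    nc <- pooled_correct[i]
    cc <- tabulate(corr_conf_pool[ci + seq_len(nc)], nbins = 5L)
    ic <- tabulate(inc_conf_pool[ii + seq_len(n - nc)], nbins = 5L)
    ci <<- ci + nc; ii <<- ii + (n - nc)
    spec <- virtual_reader_spec(nc / n, mode = "exact_counts",
                                correct_counts = cc,
                                incorrect_counts = ic)
    virtual_reader_log(spec, session, reader_ids[i], seed = 200L + i)
  })

  list(config = config, session = session,
       reader_logs = reader_logs, pooled_logs = pooled_logs)
}
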