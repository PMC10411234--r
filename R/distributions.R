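#' Parametric density models for image classes
#'
#' A `density_model` describes the probability law of an M-pixel image,
#' viewed as a flat numeric vector. Three families are provided:
#' multivariate Gaussian, Gaussian mixture, and independent per-pixel
#' Poisson (for count-valued images). Models support exact sampling,
#' log-density evaluation and Bhattacharyya overlap computation, which is
#' all the machinery the ideal-observer analysis needs: the synthetic image
#' class plays the role of hypothesis H1 and the real image class of H2.
#'
#' @param mean numeric mean vector (length M).
#' @param cov symmetric positive-definite M x M covariance matrix.
#' @return An object of class `density_model`.
#' @examples
#' m <- gaussian_model(c(0, 0), diag(2))
#' x <- sample_model(m, 5, seed = 1)
#' log_density(m, x[1, ])
#' @export
gaussian_model <- function(mean, cov) {
  mean <- as.numeric(mean)
  if (length(mean) < 1L || any(!is.finite(mean))) {
    stop("`mean` must be a non-empty finite numeric vector", call. = FALSE)
  }
  cov <- as_spd_matrix(cov, length(mean), "cov")
  new_density_model("gaussian", length(mean), list(mean = mean, cov = cov))
}

#' Gaussian mixture density model
#'
#' @param weights nonnegative component weights summing to 1 (within 1e-12).
#' @param means list of component mean vectors, all of one length M.
#' @param covs list of component covariance matrices (M x M, SPD).
#' @return An object of class `density_model`.
#' @export
gaussian_mixture_model <- function(weights, means, covs) {
  weights <- as.numeric(weights)
  k <- length(weights)
  if (k < 1L) stop("mixture needs at least one component", call. = FALSE)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12) {
    stop("`weights` must be nonnegative and sum to 1 within 1e-12",
         call. = FALSE)
  }
  if (!is.list(means)) means <- lapply(seq_len(nrow(means)), function(i) means[i, ])
  if (!is.list(covs)) covs <- list(covs)
  if (length(means) != k || length(covs) != k) {
    stop("`means` and `covs` must have one entry per weight", call. = FALSE)
  }
  means <- lapply(means, as.numeric)
  m <- length(means[[1L]])
  if (any(vapply(means, length, 1L) != m)) {
    stop("all component means must share one dimension", call. = FALSE)
  }
  covs <- lapply(seq_len(k), function(i) {
    as_spd_matrix(covs[[i]], m, sprintf("covs[[%d]]", i))
  })
  new_density_model("gaussian_mixture", m,
                    list(weights = weights, means = means, covs = covs))
}

#' Independent Poisson density model
#'
#' Per-pixel independent Poisson counts, the natural model for photon-count
#' images.
#'
#' @param rates strictly positive per-pixel rate vector (length M).
#' @return An object of class `density_model`.
#' @export
poisson_model <- function(rates) {
  rates <- as.numeric(rates)
  if (length(rates) < 1L || any(!is.finite(rates)) || any(rates <= 0)) {
    stop("`rates` must be finite and strictly positive", call. = FALSE)
  }
  new_density_model("independent_poisson", length(rates), list(rates = rates))
}

new_density_model <- function(family, dimension, parameters) {
  structure(
    list(family = family, dimension = dimension, parameters = parameters),
    class = c(paste0(sub("^independent_", "", family), "_density"),
              "density_model")
  )
}

as_spd_matrix <- function(x, m, name) {
  x <- as.matrix(x)
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be a finite numeric matrix", name), call. = FALSE)
  }
  if (nrow(x) != m || ncol(x) != m) {
    stop(sprintf("`%s` must be %d x %d", name, m, m), call. = FALSE)
  }
  if (max(abs(x - t(x))) > 1e-8 * max(1, max(abs(x)))) {
    stop(sprintf("`%s` must be symmetric", name), call. = FALSE)
  }
  x <- (x + t(x)) / 2
  ok <- tryCatch({chol(x); TRUE}, error = function(e) FALSE)
  if (!ok) {
    stop(sprintf("`%s` must be positive definite", name), call. = FALSE)
  }
  x
}

#' @export
print.density_model <- function(x, ...) {
  cat(sprintf("<density_model> family=%s, dimension=%d\n",
              x$family, x$dimension))
  invisible(x)
}

#' Draw images from a density model
#'
#' Sampling is bit-for-bit reproducible: the same model, `n` and `seed`
#' always produce the same draws, and the caller's RNG state is untouched.
#'
#' @param model a [density_model][gaussian_model].
#' @param n number of images to draw.
#' @param seed integer seed.
#' @return An `n` x M numeric matrix; each row is one image vector.
#' @export
sample_model <- function(model, n, seed) {
  stopifnot(inherits(model, "density_model"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1", call. = FALSE)
  local_rng(seed, sample_model_impl(model, n))
}

sample_model_impl <- function(model, n) {
  m <- model$dimension
  p <- model$parameters
  switch(model$family,
    gaussian = {
      u <- chol(p$cov)
      z <- matrix(stats::rnorm(n * m), n, m)
      sweep(z %*% u, 2L, p$mean, "+")
    },
    gaussian_mixture = {
      comp <- sample.int(length(p$weights), n, replace = TRUE,
                         prob = p$weights)
      out <- matrix(0, n, m)
      for (k in seq_along(p$weights)) {
        idx <- which(comp == k)
        if (!length(idx)) next
        u <- chol(p$covs[[k]])
        z <- matrix(stats::rnorm(length(idx) * m), length(idx), m)
        out[idx, ] <- sweep(z %*% u, 2L, p$means[[k]], "+")
      }
      out
    },
    independent_poisson = {
      vapply(p$rates, function(r) stats::rpois(n, r), numeric(n)) |>
        matrix(nrow = n, ncol = m)
    },
    stop("unknown family ", model$family, call. = FALSE)
  )
}

#' Log-density of an image under a model
#'
#' @param model a [density_model][gaussian_model].
#' @param x a single image vector of length M, or an n x M matrix of images.
#' @return Numeric log-density, one value per image.
#' @export
log_density <- function(model, x) {
  stopifnot(inherits(model, "density_model"))
  x <- as_image_matrix(x, model$dimension)
  p <- model$parameters
  switch(model$family,
    gaussian = gaussian_logdens(x, p$mean, p$cov),
    gaussian_mixture = {
      k <- length(p$weights)
      comp <- vapply(seq_len(k), function(i) {
        log(p$weights[i]) + gaussian_logdens(x, p$means[[i]], p$covs[[i]])
      }, numeric(nrow(x)))
      comp <- matrix(comp, nrow = nrow(x))
      apply(comp, 1L, log_sum_exp)
    },
    independent_poisson = {
      if (any(x < 0) || any(abs(x - round(x)) > 1e-9)) {
        stop("Poisson log-density requires nonnegative integer pixel values",
             call. = FALSE)
      }
      rowSums(matrix(
        stats::dpois(round(t(x)), p$rates, log = TRUE),
        nrow = nrow(x), byrow = TRUE))
    }
  )
}

as_image_matrix <- function(x, m) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != m) {
    stop(sprintf("image has %d pixels but the model dimension is %d",
                 ncol(x), m), call. = FALSE)
  }
  if (any(!is.finite(x))) stop("image values must be finite", call. = FALSE)
  x
}

gaussian_logdens <- function(x, mean, cov) {
  u <- chol(cov)
  m <- length(mean)
  centered <- t(x) - mean
  quad <- colSums(backsolve(u, centered, transpose = TRUE)^2)
  -0.5 * (m * log(2 * pi) + 2 * sum(log(diag(u))) + quad)
}

log_sum_exp <- function(v) {
  mx <- max(v)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(v - mx)))
}

# First two marginal moments, used to pick quadrature windows.
model_moments <- function(model) {
  p <- model$parameters
  switch(model$family,
    gaussian = list(mean = p$mean, sd = sqrt(diag(as.matrix(p$cov)))),
    gaussian_mixture = {
      mu <- Reduce(`+`, Map(`*`, p$weights, p$means))
      m2 <- Reduce(`+`, Map(function(w, m, s) {
        w * (diag(as.matrix(s)) + m^2)
      }, p$weights, p$means, p$covs))
      list(mean = mu, sd = sqrt(pmax(m2 - mu^2, 0)))
    },
    independent_poisson = list(mean = p$rates, sd = sqrt(p$rates))
  )
}

#' Bhattacharyya overlap between two density models
#'
#' Computes the Bhattacharyya coefficient BC = integral of sqrt(q1 q2), the
#' distance D_B = -log BC, and G(0) = 4 D_B, the quantity through which the
#' ideal-observer AUC is tied to the similarity of the two image
#' distributions. Three estimators are available:
#'
#' * `"closed_form"` - the exact Gaussian formula
#'   D_B = (1/8) dmu' S^-1 dmu + (1/2) log(det S / sqrt(det S1 det S2))
#'   with S = (S1 + S2)/2; Gaussian models only.
#' * `"quadrature"` - adaptive numeric integration (or exact summation for
#'   Poisson models) of sqrt(q1 q2); dimensions M <= 2 only.
#' * `"sample_mc"` - Monte Carlo: BC = <Lambda^(1/2)> under H1, estimated as
#'   the mean of exp(lambda/2) over draws from `model1`, with a standard
#'   error from the sample variance. Any family, any dimension.
#'
#' @param model1,model2 [density_model][gaussian_model] objects of equal
#'   dimension; by convention `model1` is the synthetic class (H1) and
#'   `model2` the real class (H2).
#' @param method one of `"closed_form"`, `"quadrature"`, `"sample_mc"`.
#' @param n_samples Monte-Carlo sample size (`sample_mc` only).
#' @param seed integer seed (`sample_mc` only).
#' @return A `bhattacharyya_result` with fields `coefficient`, `distance`,
#'   `g0`, `method`, and for `sample_mc` also `mc_std_error` (of the
#'   coefficient), `distance_std_error` and `n_samples`.
#' @examples
#' a <- gaussian_model(c(0, 0), diag(2))
#' b <- gaussian_model(c(2, 0), diag(2))
#' bhattacharyya(a, b, "closed_form")$distance  # 0.5
#' @export
bhattacharyya <- function(model1, model2,
                          method = c("closed_form", "quadrature", "sample_mc"),
                          n_samples = NULL, seed = NULL) {
  stopifnot(inherits(model1, "density_model"),
            inherits(model2, "density_model"))
  method <- match.arg(method)
  if (model1$dimension != model2$dimension) {
    stop("models must have the same dimension", call. = FALSE)
  }
  switch(method,
    closed_form = bhat_closed_form(model1, model2),
    quadrature = bhat_quadrature(model1, model2),
    sample_mc = {
      if (is.null(n_samples) || is.null(seed)) {
        stop("sample_mc requires `n_samples` and `seed`", call. = FALSE)
      }
      x <- sample_model(model1, n_samples, seed)
      lam <- log_density(model2, x) - log_density(model1, x)
      bhattacharyya_from_lr_samples(lam)
    }
  )
}

bhat_closed_form <- function(model1, model2) {
  if (model1$family != "gaussian" || model2$family != "gaussian") {
    stop("closed_form is only available for two gaussian models",
         call. = FALSE)
  }
  p1 <- model1$parameters; p2 <- model2$parameters
  sbar <- (p1$cov + p2$cov) / 2
  dmu <- p2$mean - p1$mean
  mean_term <- 0.125 * drop(crossprod(dmu, solve(sbar, dmu)))
  ld <- function(s) as.numeric(determinant(s, logarithm = TRUE)$modulus)
  cov_term <- 0.5 * (ld(sbar) - 0.5 * (ld(p1$cov) + ld(p2$cov)))
  dist <- mean_term + cov_term
  new_bhattacharyya_result(distance = dist, method = "closed_form")
}

bhat_quadrature <- function(model1, model2) {
  m <- model1$dimension
  if (m > 2L) {
    stop("quadrature supports dimension M <= 2 only; use sample_mc",
         call. = FALSE)
  }
  disc1 <- model1$family == "independent_poisson"
  disc2 <- model2$family == "independent_poisson"
  if (disc1 != disc2) {
    stop("cannot mix discrete and continuous families in quadrature",
         call. = FALSE)
  }
  if (disc1) {
    # exact summation over a window covering all non-negligible mass
    hi <- pmax(stats::qpois(1 - 1e-14, model1$parameters$rates),
               stats::qpois(1 - 1e-14, model2$parameters$rates)) + 2
    grids <- lapply(hi, function(h) 0:h)
    pts <- as.matrix(expand.grid(grids))
    bc <- sum(exp(0.5 * (log_density(model1, pts) +
                         log_density(model2, pts))))
    return(new_bhattacharyya_result(coefficient = bc, method = "quadrature"))
  }
  mo1 <- model_moments(model1); mo2 <- model_moments(model2)
  lo <- pmin(mo1$mean, mo2$mean) - 10 * pmax(mo1$sd, mo2$sd)
  hi <- pmax(mo1$mean, mo2$mean) + 10 * pmax(mo1$sd, mo2$sd)
  integrand <- function(pts) {
    exp(0.5 * (log_density(model1, pts) + log_density(model2, pts)))
  }
  if (m == 1L) {
    bc <- stats::integrate(function(x) integrand(matrix(x, ncol = 1L)),
                           lo, hi, abs.tol = 1e-10, rel.tol = 1e-10,
                           subdivisions = 500L)$value
  } else {
    inner <- function(x1) {
      vapply(x1, function(a) {
        stats::integrate(function(x2) integrand(cbind(a, x2)),
                         lo[2L], hi[2L], abs.tol = 1e-10, rel.tol = 1e-10,
                         subdivisions = 500L)$value
      }, numeric(1))
    }
    bc <- stats::integrate(inner, lo[1L], hi[1L],
                           abs.tol = 1e-10, rel.tol = 1e-10,
                           subdivisions = 500L)$value
  }
  new_bhattacharyya_result(coefficient = bc, method = "quadrature")
}

new_bhattacharyya_result <- function(coefficient = NULL, distance = NULL,
                                     method, mc_std_error = NULL,
                                     n_samples = NULL, flagged = FALSE) {
  if (is.null(distance)) distance <- -log(coefficient)
  if (is.null(coefficient)) coefficient <- exp(-distance)
  res <- list(
    coefficient = coefficient,
    distance = distance,
    g0 = 4 * distance,
    method = method,
    flagged = flagged
  )
  if (!is.null(mc_std_error)) {
    res$mc_std_error <- mc_std_error
    res$distance_std_error <- mc_std_error / coefficient
    res$n_samples <- n_samples
  }
  structure(res, class = "bhattacharyya_result")
}

#' @export
print.bhattacharyya_result <- function(x, ...) {
  cat(sprintf(
    "<bhattacharyya_result> BC=%.6g  D_B=%.6g  G(0)=%.6g  [%s]%s\n",
    x$coefficient, x$distance, x$g0, x$method,
    if (!is.null(x$mc_std_error))
      sprintf("  se(BC)=%.3g n=%d", x$mc_std_error, x$n_samples) else ""))
  if (isTRUE(x$flagged)) {
    cat("  warning: estimated coefficient exceeds 1 beyond 3 standard",
        "errors\n")
  }
  invisible(x)
}

#' Serialize / parse a density model as JSON
#'
#' The JSON layout is `{family, dimension, parameters}` with matrices as
#' row-major nested arrays and mixture components as a list of
#' `{weight, mean, cov}` objects. The round trip is value-exact.
#'
#' @param model a [density_model][gaussian_model].
#' @param path optional file to write to; if `NULL` the JSON string is
#'   returned.
#' @return `model_to_json`: JSON string (invisibly, if written to a file);
#'   `model_from_json`: a `density_model`.
#' @export
model_to_json <- function(model, path = NULL) {
  p <- model$parameters
  par <- switch(model$family,
    gaussian = list(mean = p$mean, cov = p$cov),
    gaussian_mixture = list(components = lapply(seq_along(p$weights),
      function(i) list(weight = p$weights[i], mean = p$means[[i]],
                       cov = p$covs[[i]]))),
    independent_poisson = list(rates = p$rates)
  )
  js <- jsonlite::toJSON(
    list(family = model$family, dimension = model$dimension,
         parameters = par),
    digits = I(17), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' @param json a JSON string or the path of a JSON file.
#' @rdname model_to_json
#' @export
model_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  if (is.null(obj$family)) stop("missing `family` in model JSON",
                                call. = FALSE)
  par <- obj$parameters
  m <- obj$dimension
  as_mat <- function(x) {
    if (is.matrix(x)) x else matrix(unlist(x), m, m, byrow = TRUE)
  }
  switch(obj$family,
    gaussian = gaussian_model(par$mean, as_mat(par$cov)),
    gaussian_mixture = gaussian_mixture_model(
      weights = vapply(par$components, `[[`, numeric(1), "weight"),
      means = lapply(par$components, function(cp) as.numeric(cp$mean)),
      covs = lapply(par$components, function(cp) as_mat(cp$cov))),
    independent_poisson = poisson_model(par$rates),
    stop("unknown family ", obj$family, call. = FALSE)
  )
}
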