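#' Lesion-phantom specification
#'
#' A deliberately simple generative model of 2D emission-like images used
#' to exercise the realism-evaluation machinery end to end: an elliptical
#' warm background with randomly placed hot disk lesions, blurred by a
#' Gaussian point-spread function and degraded by per-pixel Poisson
#' noise. It is a stand-in for real clinical synthesis techniques, not a
#' physics simulation. The "real" arm draws from the base parameters; the
#' "synthetic" arm shifts lesion contrast and background activity by the
#' factor `1 + realism_gap`, so `realism_gap = 0` makes the two arms
#' exchangeable draws from one process.
#'
#' @param image_size `(H, W)` in pixels.
#' @param background_activity mean background counts per pixel (> 0).
#' @param lesion_count_range integer interval for the number of lesions.
#' @param lesion_radius_range pixel interval for lesion radii.
#' @param lesion_contrast_range interval (> 1) for the lesion-to-background
#'   activity ratio.
#' @param psf_fwhm full width at half maximum of the Gaussian point-spread
#'   function, in pixels.
#' @param realism_gap nonnegative shift of the synthetic arm's parameters;
#'   0 gives exchangeable arms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(64L, 64L),
                         background_activity = 50,
                         lesion_count_range = c(1L, 3L),
                         lesion_radius_range = c(3, 6),
                         lesion_contrast_range = c(2, 4),
                         psf_fwhm = 2,
                         realism_gap = 0) {
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 8L)) {
    stop("`image_size` must be two integers >= 8", call. = FALSE)
  }
  if (background_activity <= 0) {
    stop("`background_activity` must be > 0", call. = FALSE)
  }
  if (any(lesion_contrast_range <= 1)) {
    stop("`lesion_contrast_range` must exceed 1", call. = FALSE)
  }
  if (realism_gap < 0) stop("`realism_gap` must be >= 0", call. = FALSE)
  if (max(lesion_radius_range) >= min(image_size) / 2 - 1) {
    stop("lesion radius too large for the image size", call. = FALSE)
  }
  structure(list(
    image_size = image_size,
    background_activity = background_activity,
    lesion_count_range = as.integer(lesion_count_range),
    lesion_radius_range = as.numeric(lesion_radius_range),
    lesion_contrast_range = as.numeric(lesion_contrast_range),
    psf_fwhm = psf_fwhm,
    realism_gap = realism_gap
  ), class = "phantom_spec")
}

runif_range <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else stats::runif(n, range[1L], range[2L])
}

sample_int_range <- function(range) {
  if (range[1L] == range[2L]) range[1L]
  else sample(seq(range[1L], range[2L]), 1L)
}

# One noiseless activity map plus its ground truth. `gap` scales
# background and lesion contrast for the synthetic arm.
phantom_activity <- function(spec, gap = 0) {
  h <- spec$image_size[1L]; w <- spec$image_size[2L]
  bg <- spec$background_activity * (1 + gap)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ry <- 0.4 * h; rx <- 0.4 * w
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  inside <- ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
  act <- matrix(0.05 * bg, h, w)  # faint out-of-body activity
  act[inside] <- bg
  n_les <- sample_int_range(spec$lesion_count_range)
  lesions <- vector("list", n_les)
  placed <- 0L
  attempts <- 0L
  while (placed < n_les && attempts < 200L) {
    attempts <- attempts + 1L
    r <- runif_range(1L, spec$lesion_radius_range)
    contrast <- runif_range(1L, spec$lesion_contrast_range) * (1 + gap)
    ly <- stats::runif(1L, 1 + r, h - r)
    lx <- stats::runif(1L, 1 + r, w - r)
    # reject lesions straddling the body boundary
    margin <- ((ly - cy) / (ry - r))^2 + ((lx - cx) / (rx - r))^2
    if (!is.finite(margin) || margin > 1) next
    placed <- placed + 1L
    disk <- (yy - ly)^2 + (xx - lx)^2 <= r^2
    act[disk] <- bg * contrast
    lesions[[placed]] <- list(center = c(ly, lx), radius = r,
                              contrast = contrast)
  }
  list(activity = act, lesions = lesions[seq_len(placed)])
}

# Separable Gaussian blur with reflective boundary handling.
gaussian_blur <- function(img, fwhm) {
  if (fwhm <= 0) return(img)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  reflect_idx <- function(i, n) {
    i <- ifelse(i < 1L, 2L - i, i)
    ifelse(i > n, 2L * n - i, i)
  }
  conv1 <- function(m) {  # along rows (first margin)
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      idx <- reflect_idx(seq_len(n) + (j - half - 1L), n)
      out <- out + k[j] * m[idx, , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(img))))
}

#' Generate paired synthetic/real phantom images
#'
#' Draws `n_pairs` image pairs: both arms follow the phantom model, the
#' synthetic arm with parameters shifted by the spec's `realism_gap`.
#' Each image is written as a 16-bit grayscale PNG, and a
#' `manifest.json` records the spec, seed and per-image ground truth
#' (lesion centers, radii, contrasts). Identical spec and seed reproduce
#' byte-identical files.
#'
#' @param spec a [phantom_spec()].
#' @param n_pairs number of image pairs.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest as a list; files are the side effect.
#' @export
phantom_pairs <- function(spec, n_pairs, seed, dir) {
  stopifnot(inherits(spec, "phantom_spec"))
  n_pairs <- as.integer(n_pairs)
  if (is.na(n_pairs) || n_pairs < 1L) stop("`n_pairs` must be >= 1",
                                           call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  images <- local_rng(seed, {
    lapply(seq_len(n_pairs), function(i) {
      lapply(c(synthetic = spec$realism_gap, real = 0), function(gap) {
        base <- phantom_activity(spec, gap)
        blurred <- gaussian_blur(base$activity, spec$psf_fwhm)
        counts <- matrix(
          stats::rpois(length(blurred), pmax(blurred, 0)),
          nrow(blurred), ncol(blurred))
        list(counts = counts, lesions = base$lesions)
      })
    })
  })
  manifest_pairs <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    entry <- list(pair_id = i)
    for (arm in c("synthetic", "real")) {
      fn <- sprintf("%s_%03d.png", arm, i)
      write_png16(images[[i]][[arm]]$counts, file.path(dir, fn))
      entry[[arm]] <- list(file = fn,
                           lesions = images[[i]][[arm]]$lesions)
    }
    manifest_pairs[[i]] <- entry
  }
  manifest <- list(
    schema_version = "1.0",
    seed = as.integer(seed),
    boundary_handling = "reflective",
    spec = unclass(spec),
    pairs = manifest_pairs
  )
  writeLines(jsonlite::toJSON(manifest, digits = I(17), auto_unbox = TRUE,
                              pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(manifest)
}
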