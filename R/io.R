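#' Read a grayscale image as a flat vector
#'
#' Supports 8/16-bit grayscale PNG and plain numeric CSV matrices.
#' Values are returned as nonnegative reals in their native integer
#' scale (0..255 or 0..65535 for PNG), flattened row-major, together
#' with the image shape. Color or malformed files are rejected, never
#' coerced.
#'
#' @param path a `.png` or `.csv` file.
#' @return A list with `values` (row-major numeric vector), `shape`
#'   `(H, W)`, and for PNG also `bit_depth`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- tryCatch(png::readPNG(path), error = function(e) {
      stop(sprintf("malformed PNG '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    })
    if (length(dim(arr)) == 3L) {
      if (dim(arr)[3L] == 1L) {
        arr <- arr[, , 1L]
      } else {
        stop(sprintf("'%s' has %d channels; only grayscale is supported",
                     path, dim(arr)[3L]), call. = FALSE)
      }
    }
    v8 <- arr * 255
    if (max(abs(v8 - round(v8))) < 1e-9) {
      vals <- round(v8); depth <- 8L
    } else {
      v16 <- arr * 65535
      if (max(abs(v16 - round(v16))) > 1e-3) {
        stop(sprintf("'%s': pixel values are not on an 8- or 16-bit grid",
                     path), call. = FALSE)
      }
      vals <- round(v16); depth <- 16L
    }
    list(values = as.vector(t(vals)), shape = dim(arr),
         bit_depth = depth)
  } else if (ext == "csv") {
    m <- tryCatch(
      as.matrix(utils::read.csv(path, header = FALSE)),
      error = function(e) {
        stop(sprintf("malformed CSV '%s': %s", path,
                     conditionMessage(e)), call. = FALSE)
      })
    if (!is.numeric(m) || anyNA(m)) {
      stop(sprintf("'%s' is not a numeric matrix", path), call. = FALSE)
    }
    list(values = as.vector(t(m)), shape = dim(m))
  } else {
    stop(sprintf("unsupported image format '%s' (PNG or CSV expected)",
                 ext), call. = FALSE)
  }
}

# Convert package result objects into plain, JSON-friendly lists.
# Where a quantity is conventionally reported rounded (percent
# accuracy), both the full-precision and the presentation value are
# included.
as_report <- function(x) UseMethod("as_report")

#' @export
as_report.default <- function(x) x

#' @export
as_report.auc_result <- function(x) unclass(x)

#' @export
as_report.bhattacharyya_result <- function(x) unclass(x)

#' @export
as_report.reader_summary <- function(x) {
  tal <- x$confidence_tally
  list(
    reader_id = x$reader_id,
    n_trials = x$n_trials,
    n_correct = x$n_correct,
    accuracy = x$n_correct / x$n_trials,
    percent_accuracy = x$percent_accuracy,
    percent_accuracy_display = sprintf("%d%%", x$percent_accuracy_rounded),
    median_confidence = x$median_confidence,
    confidence_tally = list(correct = as.integer(tal["correct", ]),
                            incorrect = as.integer(tal["incorrect", ])),
    binomial_p_vs_chance = x$binomial_p_vs_chance,
    ci95 = x$ci95,
    untrained_flag = x$untrained_flag,
    skipped_trials = x$skipped_trials
  )
}

#' @export
as_report.list <- function(x) lapply(x, as_report)

#' Write a JSON report
#'
#' Every report carries a schema version, the seed that produced it and a
#' timestamp; numbers are written at full precision. Reports round-trip
#' value-exactly through [read_report()] (the timestamp aside, reruns
#' with identical inputs and seed are byte-identical).
#'
#' @param report a result object or list of result objects.
#' @param path output file.
#' @param seed the seed used to produce the results (recorded verbatim).
#' @return The path, invisibly.
#' @export
write_report <- function(report, path, seed = NULL) {
  obj <- list(
    schema_version = "1.0",
    seed = if (!is.null(seed)) as.integer(seed),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    results = as_report(report)
  )
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                              pretty = TRUE, null = "null"), path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}
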