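# File formats: curves and T1 tables as CSV, results as JSON with sorted
# keys, rasters as ASCII portable anymaps (P2 grayscale / P3 RGB).

#' Read a tracer curve from CSV
#'
#' Expects header `time_min,value,label` and strictly increasing times;
#' format errors name the offending line.
#'
#' @param path CSV file path.
#' @return a [tracer_curve()].
#' @export
read_curve_csv <- function(path) {
  check_that(file.exists(path), sprintf("file not found: %s", path), "format_error")
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) abort_cardiact(
                   sprintf("cannot parse %s: %s", path, conditionMessage(e)),
                   "format_error"))
  check_that(all(c("time_min", "value") %in% names(df)),
             sprintf("%s: header must contain time_min,value,label", path),
             "format_error")
  check_that(nrow(df) >= 1L, sprintf("%s: no data rows", path), "format_error")
  bad <- which(diff(df$time_min) <= 0)
  if (length(bad) > 0L)
    abort_cardiact(sprintf("%s: times not strictly increasing at line %d",
                           path, bad[1L] + 2L), "format_error")  # +1 header +1 next row
  tracer_curve(df$time_min, df$value,
               if ("label" %in% names(df)) df$label[1L] else "curve")
}

#' Write a tracer curve to CSV (header `time_min,value,label`)
#' @param curve a [tracer_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  df <- data.frame(time_min = curve$time_min, value = curve$value,
                   label = curve_label(curve))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a T1 table from CSV (`time_min,t1_myo_ms,t1_blood_ms`)
#' @param path CSV file path.
#' @return a `t1_table` data.frame.
#' @export
read_t1_csv <- function(path) {
  check_that(file.exists(path), sprintf("file not found: %s", path), "format_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_that(all(c("time_min", "t1_myo_ms", "t1_blood_ms") %in% names(df)),
             sprintf("%s: header must be time_min,t1_myo_ms,t1_blood_ms", path),
             "format_error")
  check_that(nrow(df) >= 1L, sprintf("%s: no data rows", path), "format_error")
  bad <- which(diff(df$time_min) <= 0)
  if (length(bad) > 0L)
    abort_cardiact(sprintf("%s: times not strictly increasing at line %d",
                           path, bad[1L] + 2L), "format_error")
  structure(df[, c("time_min", "t1_myo_ms", "t1_blood_ms")],
            class = c("t1_table", "data.frame"))
}

#' Write a T1 table to CSV
#' @param t1_table a `t1_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_t1_csv <- function(t1_table, path) {
  utils::write.csv(as.data.frame(t1_table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

sort_keys_rec <- function(x) {
  if (is.list(x) && !is.null(names(x)) && length(x) > 0L) {
    x <- x[order(names(x))]
    lapply(x, sort_keys_rec)
  } else if (is.list(x)) {
    lapply(x, sort_keys_rec)
  } else x
}

#' Write a results object as deterministic JSON
#'
#' Keys are sorted recursively, floats carry 12 significant digits, and a
#' `version` stamp (package version) is added; identical inputs give
#' byte-identical files.
#'
#' @param results a named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(results, path) {
  check_that(is.list(results), "results must be a list", "format_error")
  results$version <- as.character(utils::packageVersion("cardiact"))
  out <- sort_keys_rec(results)
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = I(12),
                           null = "null", na = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a results JSON written by [write_results_json()]
#' @param path JSON file path.
#' @return the parsed list; errors if the version stamp is missing.
#' @export
read_results_json <- function(path) {
  check_that(file.exists(path), sprintf("file not found: %s", path), "format_error")
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE,
                                   simplifyDataFrame = FALSE,
                                   simplifyMatrix = FALSE),
                error = function(e) abort_cardiact(
                  sprintf("invalid JSON in %s", path), "format_error"))
  check_that(is.list(x) && !is.null(x$version),
             sprintf("%s: missing version stamp (not a cardiact results file)", path),
             "format_error")
  x
}

#' Write a raster as an ASCII portable anymap
#'
#' Grayscale matrices become P2 (PGM), h x w x 3 arrays become P3 (PPM).
#' Plain-text rasters keep the whole pipeline free of binary formats.
#'
#' @param pixels matrix or h x w x 3 array of non-negative integers.
#' @param path output path.
#' @param maxval maximum gray value (default: 255, or 65535 if any pixel
#'   exceeds 255).
#' @return `path`, invisibly.
#' @export
write_pnm <- function(pixels, path, maxval = NULL) {
  d <- dim(pixels)
  rgb <- length(d) == 3L && d[3L] == 3L
  check_that(rgb || length(d) == 2L, "pixels must be a matrix or h x w x 3 array",
             "format_error")
  if (is.null(maxval)) maxval <- if (max(pixels) > 255) 65535L else 255L
  h <- d[1L]; w <- d[2L]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(if (rgb) "P3" else "P2", paste(w, h), as.character(maxval)), con)
  if (rgb) {
    # interleave channels row-major: r g b per pixel
    vals <- aperm(pixels, c(3L, 2L, 1L))
  } else {
    vals <- t(pixels)
  }
  writeLines(paste(as.integer(vals), collapse = " "), con)
  invisible(path)
}

#' Read an ASCII portable anymap written by [write_pnm()]
#' @param path PGM (P2) or PPM (P3) file path.
#' @return a matrix (P2) or h x w x 3 array (P3).
#' @export
read_pnm <- function(path) {
  check_that(file.exists(path), sprintf("file not found: %s", path), "format_error")
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  magic <- toks[1L]
  check_that(magic %in% c("P2", "P3"), "only ASCII P2/P3 anymaps supported",
             "format_error")
  w <- as.integer(toks[2L]); h <- as.integer(toks[3L])
  vals <- as.numeric(toks[-(1:4)])
  if (magic == "P2") {
    check_that(length(vals) == w * h, "pixel count mismatch", "format_error")
    t(matrix(vals, nrow = w, ncol = h))
  } else {
    check_that(length(vals) == 3L * w * h, "pixel count mismatch", "format_error")
    arr <- array(vals, dim = c(3L, w, h))
    aperm(arr, c(3L, 2L, 1L))
  }
}
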