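#' Reflectance spectra objects
#'
#' A `spectra` object is a data frame whose first column, `wl`, holds a
#' strictly increasing wavelength grid in nanometres, and whose remaining
#' columns each hold one reflectance spectrum (dimensionless proportions;
#' raw instrument output may dip slightly below zero before clamping).
#'
#' @param x a data frame (or coercible object) with wavelengths in the first
#'   column and one reflectance spectrum per remaining column.
#' @return an object of class `spectra`.
#' @examples
#' sp <- as_spectra(data.frame(wl = 300:700, s1 = runif(401)))
#' spectra_ids(sp)
#' @export
as_spectra <- function(x) {
  x <- as.data.frame(x, check.names = FALSE)
  if (nrow(x) == 0L) {
    stop("spectra input has no rows", call. = FALSE)
  }
  if (ncol(x) < 2L) {
    stop("spectra need a wavelength column plus at least one reflectance column",
         call. = FALSE)
  }
  names(x)[1L] <- "wl"
  wl <- x[[1L]]
  if (!is.numeric(wl) || anyNA(wl)) {
    stop("wavelength column must be numeric with no missing values",
         call. = FALSE)
  }
  if (any(diff(wl) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  for (j in seq.int(2L, ncol(x))) {
    if (!is.numeric(x[[j]])) {
      stop("reflectance column '", names(x)[j], "' is not numeric",
           call. = FALSE)
    }
  }
  class(x) <- c("spectra", "data.frame")
  x
}

#' @export
print.spectra <- function(x, ...) {
  wl <- x$wl
  cat(sprintf("spectra: %d spectra on %d wavelengths (%g-%g nm)\n",
              ncol(x) - 1L, length(wl), min(wl), max(wl)))
  cat("ids:", paste(utils::head(spectra_ids(x), 8L), collapse = ", "),
      if (ncol(x) - 1L > 8L) "..." else "", "\n")
  invisible(x)
}

#' Spectrum identifiers and wavelengths
#'
#' @param x a `spectra` object.
#' @return `spectra_ids()` returns the character vector of spectrum column
#'   names; `wavelengths()` the numeric wavelength grid (nm).
#' @export
spectra_ids <- function(x) names(x)[-1L]

#' @rdname spectra_ids
#' @export
wavelengths <- function(x) x[["wl"]]

#' Read and write wide-format spectral CSV files
#'
#' The expected dialect is comma-separated with a mandatory header row: the
#' first column is wavelength in nm (named `wl` on write), each remaining
#' column one spectrum, header entries giving spectrum ids.
#'
#' @param path path to a CSV file.
#' @return `read_spectra()` returns a [as_spectra()] object.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("spectral file is empty: ", path, call. = FALSE)
  as_spectra(df)
}

#' @rdname read_spectra
#' @param x a `spectra` object to write.
#' @export
write_spectra <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Resample spectra onto a common wavelength grid
#'
#' Linear interpolation onto a regular grid; values at original knots are
#' preserved exactly. Extrapolation beyond the measured range is refused.
#'
#' @param x a `spectra` object.
#' @param range two-element numeric, grid limits in nm.
#' @param step grid step in nm.
#' @return a `spectra` object on the requested grid.
#' @export
resample_spectra <- function(x, range = c(300, 700), step = 1) {
  stopifnot(length(range) == 2L, range[1] < range[2], step > 0)
  wl <- x$wl
  grid <- seq(range[1], range[2], by = step)
  if (grid[1L] < wl[1L] || grid[length(grid)] > wl[length(wl)]) {
    stop(sprintf(
      "requested grid %g-%g nm extends beyond the measured range %g-%g nm",
      grid[1L], grid[length(grid)], wl[1L], wl[length(wl)]), call. = FALSE)
  }
  out <- data.frame(wl = grid)
  for (id in spectra_ids(x)) {
    out[[id]] <- stats::approx(wl, x[[id]], xout = grid)$y
  }
  as_spectra(out)
}

#' Smooth spectra by local polynomial regression
#'
#' Locally weighted quadratic regression (tricube weights) with the given
#' span, evaluated back onto the input wavelengths, as used to clean raw
#' spectrometer output before analysis. The output grid is identical to the
#' input grid.
#'
#' @param x a `spectra` object with at least 10 wavelengths.
#' @param span fraction of points in each local fit; default 0.15.
#' @return a `spectra` object, same grid, smoothed values.
#' @export
smooth_spectra <- function(x, span = 0.15) {
  if (!is.numeric(span) || length(span) != 1L || span <= 0 || span > 1) {
    stop("span must be a single value in (0, 1]", call. = FALSE)
  }
  wl <- x$wl
  n <- length(wl)
  if (n < 10L) stop("need at least 10 wavelengths to smooth", call. = FALSE)
  # a local quadratic needs >= 3 points in every window
  if (floor(n * span) < 3L) {
    stop(sprintf(
      "span = %g leaves local windows of %d point(s); a quadratic needs 3",
      span, floor(n * span)), call. = FALSE)
  }
  out <- x
  for (id in spectra_ids(x)) {
    fit <- stats::loess(y ~ w, data = data.frame(w = wl, y = x[[id]]),
                        span = span, degree = 2, family = "gaussian",
                        surface = "direct")
    out[[id]] <- as.numeric(stats::predict(fit, data.frame(w = wl)))
  }
  out
}

#' Zero spurious negative reflectance values
#'
#' Instrument noise around dark stimuli can push measured reflectance
#' slightly below zero; those values are clamped to zero pointwise.
#' Idempotent.
#'
#' @param x a `spectra` object.
#' @return a `spectra` object with all reflectance values >= 0.
#' @export
zero_negatives <- function(x) {
  for (id in spectra_ids(x)) x[[id]] <- pmax(x[[id]], 0)
  x
}

#' Combine spectra objects on a shared grid
#'
#' @param ... `spectra` objects measured on identical wavelength grids.
#' @return a single `spectra` object holding all spectra.
#' @export
merge_spectra <- function(...) {
  xs <- list(...)
  if (length(xs) == 0L) stop("no spectra supplied", call. = FALSE)
  wl <- xs[[1L]]$wl
  for (x in xs[-1L]) {
    if (length(x$wl) != length(wl) || any(x$wl != wl)) {
      stop("wavelength grids differ; resample onto a common grid first",
           call. = FALSE)
    }
  }
  out <- do.call(cbind, c(list(data.frame(wl = wl)),
                          lapply(xs, function(x) as.data.frame(x)[-1L])))
  as_spectra(out)
}

#' Average replicate spectra
#'
#' Pointwise arithmetic mean of replicate measurements sharing a grid. With
#' `by = NULL` all spectra are averaged into one, its id the concatenation of
#' the input ids; otherwise `by` assigns each spectrum to a group and one
#' averaged spectrum per group is returned.
#'
#' @param x a `spectra` object.
#' @param by `NULL`, or a character/factor vector with one group label per
#'   spectrum.
#' @return a `spectra` object of group means.
#' @export
average_spectra <- function(x, by = NULL) {
  ids <- spectra_ids(x)
  if (length(ids) == 0L) stop("no spectra to average", call. = FALSE)
  m <- as.matrix(as.data.frame(x)[-1L])
  if (is.null(by)) {
    out <- data.frame(wl = x$wl, mean = rowMeans(m))
    names(out)[2L] <- paste(ids, collapse = ".")
    return(as_spectra(out))
  }
  if (length(by) != length(ids)) {
    stop("'by' must supply one group label per spectrum", call. = FALSE)
  }
  by <- as.character(by)
  out <- data.frame(wl = x$wl)
  for (g in unique(by)) {
    out[[g]] <- rowMeans(m[, by == g, drop = FALSE])
  }
  as_spectra(out)
}

#' Standard spectral pre-processing pipeline
#'
#' Applies, in order: local-regression smoothing, clamping of negative
#' values, and (optionally) replicate averaging — the order in which raw
#' field spectra are cleaned before visual modelling.
#'
#' @inheritParams smooth_spectra
#' @inheritParams average_spectra
#' @return a processed `spectra` object.
#' @export
process_spectra <- function(x, span = 0.15, by = NULL) {
  x <- smooth_spectra(x, span = span)
  x <- zero_negatives(x)
  if (!is.null(by)) x <- average_spectra(x, by = by)
  x
}
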