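#' Visual pigment absorbance template
#'
#' Govardovskii et al. (2000) A1 rhodopsin template: an alpha band described
#' by a log-normal-like sum of exponentials plus a Gaussian beta band, both
#' parameterised solely by the pigment's wavelength of peak absorbance.
#' Curves are normalised to a maximum of 1.
#'
#' @param lambda_max wavelength of peak absorbance (nm).
#' @param wl wavelength grid (nm) on which to evaluate the template.
#' @return numeric vector of relative sensitivities on `wl`, max 1.
#' @export
pigment_template <- function(lambda_max, wl = 300:700) {
  stopifnot(is.numeric(lambda_max), length(lambda_max) == 1L,
            lambda_max > 0)
  x <- lambda_max / wl
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lambda_max
  bbw <- -40.5 + 0.195 * lambda_max
  beta <- 0.26 * exp(-((wl - lmb) / bbw)^2)
  s <- alpha + beta
  s / max(s)
}

# default rhodopsin peak absorbances (nm) for the four chromatic receptor
# classes of the fly retina: R7p/R7y inner receptors of pale and yellow
# ommatidia, R8p/R8y their partners
FLY_LAMBDA_MAX <- c(R7p = 331, R8p = 442, R7y = 355, R8y = 515)

#' Fly photoreceptor spectral sensitivities
#'
#' Returns the four chromatic receptor classes of the dipteran retina
#' (R7p, R8p, R7y, R8y) on a common wavelength grid. By default the curves
#' are generated from the visual-pigment template at the documented
#' Drosophila rhodopsin peaks; `source = "asset"` instead loads the bundled
#' tabulated file (itself template-generated, i.e. a synthetic stand-in for
#' measured in vivo sensitivities, which also reflect screening and
#' sensitising pigments).
#'
#' @param wl wavelength grid (nm).
#' @param lambda_max named numeric vector of peak absorbances for exactly the
#'   classes R7p, R8p, R7y, R8y.
#' @param source `"template"` (compute from [pigment_template()]) or
#'   `"asset"` (read the bundled CSV and interpolate onto `wl`).
#' @return a `receptor_set`: a `spectra`-like data frame with columns
#'   `wl`, `R7p`, `R8p`, `R7y`, `R8y`, and a `provenance` attribute.
#' @export
fly_receptors <- function(wl = 300:700, lambda_max = FLY_LAMBDA_MAX,
                          source = c("template", "asset")) {
  source <- match.arg(source)
  classes <- c("R7p", "R8p", "R7y", "R8y")
  if (source == "template") {
    if (!setequal(names(lambda_max), classes)) {
      stop("lambda_max must name exactly the classes R7p, R8p, R7y, R8y",
           call. = FALSE)
    }
    out <- data.frame(wl = wl)
    for (cl in classes) out[[cl]] <- pigment_template(lambda_max[[cl]], wl)
    provenance <- "Govardovskii A1 template at Drosophila rhodopsin peaks"
  } else {
    path <- system.file("extdata", "receptors_drosophila_synthetic.csv",
                        package = "lureprox", mustWork = TRUE)
    tab <- utils::read.csv(path)
    out <- data.frame(wl = wl)
    for (cl in classes) {
      out[[cl]] <- stats::approx(tab$wl, tab[[cl]], xout = wl)$y
    }
    provenance <- "bundled synthetic tabulation (template-generated)"
  }
  x <- as_spectra(out)
  class(x) <- c("receptor_set", class(x))
  attr(x, "provenance") <- provenance
  validate_receptor_set(x)
  x
}

validate_receptor_set <- function(x) {
  classes <- c("R7p", "R8p", "R7y", "R8y")
  if (!identical(spectra_ids(x), classes)) {
    stop("a receptor set holds exactly the four classes R7p, R8p, R7y, R8y",
         call. = FALSE)
  }
  for (cl in classes) {
    v <- x[[cl]]
    if (any(v < 0) || anyNA(v) || max(v) <= 0) {
      stop("receptor sensitivities must be >= 0 with a positive maximum",
           call. = FALSE)
    }
  }
  invisible(x)
}

#' Daylight illuminant
#'
#' The CIE D65 standard daylight spectrum (relative spectral power), bundled
#' at 10-nm resolution over 300-700 nm and linearly interpolated onto the
#' working grid. Overall scaling is irrelevant downstream because colour loci
#' are built from relative quantum catches.
#'
#' @param wl wavelength grid (nm), within 300-700.
#' @return a data frame with columns `wl` and `energy`, class `illuminant`.
#' @export
illuminant_d65 <- function(wl = 300:700) {
  path <- system.file("extdata", "illuminant_d65.csv",
                      package = "lureprox", mustWork = TRUE)
  tab <- utils::read.csv(path)
  if (min(wl) < min(tab$wl) || max(wl) > max(tab$wl)) {
    stop("requested grid outside the tabulated D65 range", call. = FALSE)
  }
  out <- data.frame(wl = wl, energy = stats::approx(tab$wl, tab$energy,
                                                    xout = wl)$y)
  class(out) <- c("illuminant", "data.frame")
  attr(out, "name") <- "D65"
  out
}

#' Spectrally flat illuminant
#'
#' Equal-energy white; useful as a neutral reference in tests and examples.
#'
#' @inheritParams illuminant_d65
#' @export
illuminant_flat <- function(wl = 300:700) {
  out <- data.frame(wl = wl, energy = rep(1, length(wl)))
  class(out) <- c("illuminant", "data.frame")
  attr(out, "name") <- "flat"
  out
}

# composite trapezoid quadrature weights for an ascending grid
trapezoid_weights <- function(wl) {
  n <- length(wl)
  if (n < 2L) stop("need at least two wavelengths to integrate", call. = FALSE)
  w <- numeric(n)
  w[1L] <- (wl[2L] - wl[1L]) / 2
  w[n] <- (wl[n] - wl[n - 1L]) / 2
  if (n > 2L) w[2:(n - 1L)] <- (wl[3:n] - wl[1:(n - 2L)]) / 2
  w
}

#' Photoreceptor quantum catches
#'
#' For each stimulus spectrum, the catch of receptor class i is the
#' trapezoidal integral over 300-700 nm of reflectance x illuminant x
#' sensitivity: Q_i = integral R(lambda) I(lambda) S_i(lambda) dlambda.
#' Relative catches q_i = Q_i / sum_j Q_j remove overall intensity; they are
#' undefined (NA, with a warning) for a stimulus whose total catch is zero.
#'
#' @param x a `spectra` object of stimuli.
#' @param receptors a [fly_receptors()] set on the same grid.
#' @param illum an illuminant on the same grid.
#' @return a `quantum_catch` object: list with matrices `Q` (absolute) and
#'   `q` (relative), one row per stimulus, columns R7p, R8p, R7y, R8y.
#' @export
quantum_catch <- function(x, receptors = fly_receptors(),
                          illum = illuminant_d65()) {
  wl <- x$wl
  if (!identical(as.numeric(receptors$wl), as.numeric(wl)) ||
      !identical(as.numeric(illum$wl), as.numeric(wl))) {
    stop("stimuli, receptors and illuminant must share one wavelength grid",
         call. = FALSE)
  }
  if (any(illum$energy < 0) || all(illum$energy == 0)) {
    stop("illuminant must be nonnegative and not identically zero",
         call. = FALSE)
  }
  validate_receptor_set(receptors)
  refl <- as.matrix(as.data.frame(x)[-1L])          # n_wl x n_stim
  sens <- as.matrix(as.data.frame(receptors)[-1L])  # n_wl x 4
  wgt <- trapezoid_weights(wl) * illum$energy
  Q <- t(refl) %*% (sens * wgt)                     # n_stim x 4
  rownames(Q) <- spectra_ids(x)
  tot <- rowSums(Q)
  q <- Q / tot
  if (any(tot == 0)) {
    warning("zero total catch for: ",
            paste(rownames(Q)[tot == 0], collapse = ", "),
            "; relative catches undefined", call. = FALSE)
    q[tot == 0, ] <- NA_real_
  }
  structure(list(Q = Q, q = q), class = "quantum_catch")
}

#' @export
print.quantum_catch <- function(x, ...) {
  cat("quantum catches for", nrow(x$Q), "stimuli\n")
  print(utils::head(cbind(x$Q, x$q), 6L))
  invisible(x)
}

#' Position in the fly opponent colourspace
#'
#' The fly colourspace is spanned by two opponent mechanisms computed from
#' relative quantum catches: x = q_R7p - q_R8p and y = q_R7y - q_R8y. Loci
#' therefore lie in the square \[-1, 1\]^2 and are invariant to any positive
#' scaling of the stimulus spectrum or the illuminant.
#'
#' @param qc a [quantum_catch()] object (or a matrix of relative catches
#'   with columns R7p, R8p, R7y, R8y).
#' @return a data frame with columns `x` and `y`, one row per stimulus,
#'   row names the stimulus ids; class `colour_locus`.
#' @export
colour_locus <- function(qc) {
  q <- if (inherits(qc, "quantum_catch")) qc$q else as.matrix(qc)
  if (anyNA(q)) {
    stop("relative quantum catches undefined (zero total catch); ",
         "no colour locus exists", call. = FALSE)
  }
  out <- data.frame(x = q[, "R7p"] - q[, "R8p"],
                    y = q[, "R7y"] - q[, "R8y"],
                    row.names = rownames(q))
  class(out) <- c("colour_locus", "data.frame")
  out
}

#' Euclidean colour distance between loci
#'
#' The continuous measure of perceptual proximity: straight-line distance in
#' the fly opponent colourspace. Smaller values mean a closer colour match.
#'
#' @param a,b colour loci: data frames with columns `x`, `y` (recycled
#'   row-wise to a common length) or length-2 numerics.
#' @return numeric vector of nonnegative distances.
#' @export
colour_distance <- function(a, b) {
  a <- locus_xy(a)
  b <- locus_xy(b)
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
}

locus_xy <- function(z) {
  if (is.numeric(z) && length(z) == 2L) {
    return(data.frame(x = z[[1L]], y = z[[2L]]))
  }
  z <- as.data.frame(z)
  stopifnot(all(c("x", "y") %in% names(z)))
  z[, c("x", "y")]
}

#' Perceptual proximity for spider-flower pairings
#'
#' Runs stimuli through the fly visual model and attaches the colour
#' distance of each listed pairing.
#'
#' @param x a processed `spectra` object containing all stimuli.
#' @param pairs a data frame with columns `spider_id` and `flower_id`
#'   naming spectra in `x`.
#' @inheritParams quantum_catch
#' @return `pairs` with an added `colour_distance` column.
#' @export
pair_distances <- function(x, pairs, receptors = fly_receptors(),
                           illum = illuminant_d65()) {
  stopifnot(all(c("spider_id", "flower_id") %in% names(pairs)))
  missing <- setdiff(unique(c(pairs$spider_id, pairs$flower_id)),
                     spectra_ids(x))
  if (length(missing)) {
    stop("pairs reference spectra not present: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  loci <- colour_locus(quantum_catch(x, receptors, illum))
  pairs$colour_distance <- colour_distance(loci[pairs$spider_id, ],
                                           loci[pairs$flower_id, ])
  pairs
}
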