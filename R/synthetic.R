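#' Configuration for the synthetic-data generators
#'
#' Bundles generating coefficients, noise levels, sample sizes and the
#' master seed. All randomness in the generators flows from `seed` through
#' fixed per-stage substreams (spectra, assignment, noise), so partial
#' pipelines are independently reproducible.
#'
#' Defaults emulate the study conditions: 45 observational spiders (the
#' residual df of the observational model imply n = 45), physical distances
#' spanning 0-500 cm, a factorial design of 24 spiders per cell, and
#' factorial generating coefficients equal to the fitted treatment effects
#' (1.79, 1.69, 0.02, -0.96 prey/h) with residual SD 1.15 prey/h, the scale
#' implied by the reported standard errors. Observational generating betas
#' are round numbers on natural scales (cm; unitless colour distance).
#'
#' @param seed integer master seed (mandatory).
#' @param n_observational spiders in the observational assay.
#' @param beta named generating coefficients `intercept`, `physical`
#'   (per cm), `colour` (per unit colour distance), `interaction`.
#' @param sigma_obs residual SD of observational rates (prey/h).
#' @param distance_range range of spider-flower distances (cm).
#' @param n_per_cell spiders per factorial treatment cell.
#' @param factorial_beta treatment-coded generating coefficients
#'   `intercept`, `near`, `mismatched`, `interaction` (prey/h).
#' @param sigma_factorial residual SD of factorial rates (prey/h).
#' @param spectrum_noise_sd additive noise SD on generated reflectance.
#' @param floor_rates truncate simulated rates at zero (default off, keeping
#'   the Gaussian model well specified).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_observational = 45,
                       beta = c(intercept = 3.5, physical = -0.003,
                                colour = -2.0, interaction = 0.005),
                       sigma_obs = 1.0,
                       distance_range = c(0, 500),
                       n_per_cell = 24,
                       factorial_beta = c(intercept = 1.79, near = 1.69,
                                          mismatched = 0.02,
                                          interaction = -0.96),
                       sigma_factorial = 1.15,
                       spectrum_noise_sd = 0.005,
                       floor_rates = FALSE) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      is.na(seed)) {
    stop("a single integer master seed is mandatory", call. = FALSE)
  }
  stopifnot(n_observational > 4, sigma_obs >= 0, sigma_factorial >= 0,
            n_per_cell >= 1, length(distance_range) == 2L,
            distance_range[1] >= 0, distance_range[2] > distance_range[1],
            spectrum_noise_sd >= 0)
  stopifnot(setequal(names(beta),
                     c("intercept", "physical", "colour", "interaction")))
  stopifnot(setequal(names(factorial_beta),
                     c("intercept", "near", "mismatched", "interaction")))
  structure(list(seed = as.integer(seed),
                 n_observational = as.integer(n_observational),
                 beta = beta, sigma_obs = sigma_obs,
                 distance_range = distance_range,
                 n_per_cell = as.integer(n_per_cell),
                 factorial_beta = factorial_beta,
                 sigma_factorial = sigma_factorial,
                 spectrum_noise_sd = spectrum_noise_sd,
                 floor_rates = floor_rates),
            class = "sim_config")
}

# bank of sigmoidal reflectance curves with optional Gaussian peak; one
# column per parameter set, clipped to [0, 1]
sigmoid_bank <- function(wl, lambda0, steepness, base, plateau,
                         peak_centre = NULL, peak_width = NULL,
                         peak_height = NULL) {
  nw <- length(wl)
  n <- length(lambda0)
  W <- matrix(wl, nw, n)
  R <- rep(base, each = nw) +
    rep(plateau - base, each = nw) *
    stats::plogis((W - rep(lambda0, each = nw)) / rep(steepness, each = nw))
  if (!is.null(peak_centre)) {
    R <- R + rep(peak_height, each = nw) *
      exp(-(W - rep(peak_centre, each = nw))^2 /
            (2 * rep(peak_width, each = nw)^2))
  }
  matrix(pmin(pmax(R, 0), 1), nw, n)
}

bank_to_spectra <- function(wl, m, ids) {
  colnames(m) <- ids
  as_spectra(cbind(data.frame(wl = wl), as.data.frame(m)))
}

#' Generate spider dorsum reflectance spectra
#'
#' Yellow-morph dorsa reflect little below ~500 nm and rise sigmoidally to a
#' high plateau; white-morph dorsa are broadly and highly reflective across
#' the grid. Values are clipped to \[0, 1\]; reproducible under `seed`.
#'
#' @param morph `"yellow"` or `"white"`.
#' @param n number of spectra.
#' @param noise_sd additive Gaussian noise SD on reflectance.
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @param wl wavelength grid (nm).
#' @return a `spectra` object with ids `<morph>_1 ...`.
#' @export
sim_spider_spectra <- function(morph = c("yellow", "white"), n = 1,
                               noise_sd = 0.005, seed = NULL,
                               wl = 300:700) {
  morph <- match.arg(morph)
  if (!is.null(seed)) set.seed(seed)
  if (morph == "yellow") {
    m <- sigmoid_bank(wl,
                      lambda0 = stats::rnorm(n, 505, 5),
                      steepness = stats::runif(n, 15, 22),
                      base = stats::runif(n, 0.03, 0.07),
                      plateau = stats::runif(n, 0.5, 0.7))
  } else {
    m <- sigmoid_bank(wl,
                      lambda0 = stats::rnorm(n, 345, 8),
                      steepness = stats::runif(n, 20, 30),
                      base = stats::runif(n, 0.15, 0.25),
                      plateau = stats::runif(n, 0.55, 0.75))
  }
  if (noise_sd > 0) {
    m <- pmin(pmax(m + stats::rnorm(length(m), 0, noise_sd), 0), 1)
  }
  bank_to_spectra(wl, m, paste0(morph, "_", seq_len(n)))
}

# random flower parameter family: sigmoidal long-pass curves of varied
# inflection and height, half carrying an extra Gaussian peak
random_flower_bank <- function(n, wl) {
  has_peak <- stats::runif(n) < 0.5
  sigmoid_bank(wl,
               lambda0 = stats::runif(n, 380, 560),
               steepness = stats::runif(n, 10, 30),
               base = stats::runif(n, 0.02, 0.10),
               plateau = stats::runif(n, 0.3, 0.9),
               peak_centre = ifelse(has_peak, stats::runif(n, 350, 650), 0),
               peak_width = stats::runif(n, 20, 60),
               peak_height = ifelse(has_peak, stats::runif(n, 0.1, 0.4), 0))
}

#' Generate flower reflectance spectra
#'
#' Without a target, draws random inflorescence spectra from a sigmoid-plus-
#' peak family spanning a wide range of fly-colourspace positions. With a
#' target locus, tunes the family parameters by coarse-then-fine grid search
#' until the flower's locus lies within `tol` of the target (an error
#' reporting the best achieved distance if it cannot).
#'
#' @param n number of random spectra (ignored when `target` is given).
#' @param target optional target locus: length-2 numeric `c(x, y)` or a
#'   one-row `colour_locus`.
#' @param tol maximum accepted colour distance to the target.
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @param wl wavelength grid (nm).
#' @param receptors,illum visual model components for target matching.
#' @return a `spectra` object; for matched flowers the achieved distance is
#'   attached as attribute `achieved_distance`.
#' @export
sim_flower_spectra <- function(n = 1, target = NULL, tol = 0.02,
                               seed = NULL, wl = 300:700,
                               receptors = fly_receptors(wl),
                               illum = illuminant_d65(wl)) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(target)) {
    m <- random_flower_bank(n, wl)
    return(bank_to_spectra(wl, m, paste0("flower_", seq_len(n))))
  }
  tgt <- as.numeric(locus_xy(target)[1L, ])
  search <- function(lambda0, steepness, base, plateau) {
    grid <- expand.grid(lambda0 = lambda0, steepness = steepness,
                        base = base, plateau = plateau)
    m <- sigmoid_bank(wl, grid$lambda0, grid$steepness, grid$base,
                      grid$plateau)
    loci <- colour_locus(quantum_catch(
      bank_to_spectra(wl, m, paste0("c", seq_len(nrow(grid)))),
      receptors, illum))
    dist <- colour_distance(loci, tgt)
    list(grid = grid, m = m, dist = dist, best = which.min(dist))
  }
  coarse <- search(seq(320, 640, by = 8), c(10, 18, 28),
                   c(0.02, 0.06, 0.12), seq(0.25, 0.95, by = 0.1))
  bp <- coarse$grid[coarse$best, ]
  fine <- search(seq(bp$lambda0 - 8, bp$lambda0 + 8, by = 1),
                 seq(max(bp$steepness - 4, 2), bp$steepness + 4, by = 2),
                 bp$base,
                 seq(max(bp$plateau - 0.1, 0.05),
                     min(bp$plateau + 0.1, 1), by = 0.02))
  achieved <- fine$dist[fine$best]
  if (achieved > tol) {
    stop(sprintf(
      "could not reach the target locus within %g; best achieved %g",
      tol, achieved), call. = FALSE)
  }
  out <- bank_to_spectra(wl, fine$m[, fine$best, drop = FALSE],
                         "flower_matched")
  attr(out, "achieved_distance") <- achieved
  out
}

#' Simulate the observational assay
#'
#' Spiders of both morphs paired with random flowers: physical distances
#' uniform over the configured range, colour distances computed through the
#' fly visual model from generated spider and flower spectra, and hourly
#' interception rates from the linear model
#' rate = b0 + b_p d_phys + b_c d_col + b_pc d_phys d_col + e,
#' e ~ Normal(0, sigma).
#'
#' @param cfg a [sim_config()].
#' @param wl wavelength grid (nm).
#' @param receptors,illum visual model components.
#' @return a data frame of proximity records: `spider_id`, `morph`,
#'   `flower_id`, `physical_distance_cm`, `colour_distance`,
#'   `interception_rate`.
#' @export
sim_observational <- function(cfg, wl = 300:700,
                              receptors = fly_receptors(wl),
                              illum = illuminant_d65(wl)) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_observational
  # substream 1: morphs and spider spectra
  set.seed(cfg$seed + 1L)
  morph <- sample(c("yellow", "white"), n, replace = TRUE)
  spiders <- matrix(0, length(wl), n)
  for (mo in c("yellow", "white")) {
    sel <- morph == mo
    if (any(sel)) {
      sp <- sim_spider_spectra(mo, sum(sel), noise_sd = cfg$spectrum_noise_sd,
                               wl = wl)
      spiders[, sel] <- as.matrix(as.data.frame(sp)[-1L])
    }
  }
  # substream 2: flower spectra
  set.seed(cfg$seed + 2L)
  flowers <- random_flower_bank(n, wl)
  all_spec <- bank_to_spectra(wl, cbind(spiders, flowers),
                              c(sprintf("sp_%03d", seq_len(n)),
                                sprintf("fl_%03d", seq_len(n))))
  loci <- colour_locus(quantum_catch(all_spec, receptors, illum))
  colour_d <- colour_distance(loci[seq_len(n), ], loci[n + seq_len(n), ])
  # substream 3: web placement
  set.seed(cfg$seed + 3L)
  phys <- stats::runif(n, cfg$distance_range[1], cfg$distance_range[2])
  # substream 4: capture noise
  set.seed(cfg$seed + 4L)
  b <- cfg$beta
  mu <- b[["intercept"]] + b[["physical"]] * phys +
    b[["colour"]] * colour_d + b[["interaction"]] * phys * colour_d
  rate <- mu + stats::rnorm(n, 0, cfg$sigma_obs)
  if (cfg$floor_rates) rate <- pmax(rate, 0)
  data.frame(spider_id = sprintf("sp_%03d", seq_len(n)),
             morph = morph,
             flower_id = sprintf("fl_%03d", seq_len(n)),
             physical_distance_cm = phys,
             colour_distance = colour_d,
             interception_rate = rate)
}

#' Simulate the 2 x 2 factorial experiment
#'
#' A balanced design of `n_per_cell` spiders per proximity x colour-match
#' cell (yellow spiders are the colour-matched pairing, white spiders the
#' mismatched one), with rates drawn as cell mean + Normal(0, sigma) and the
#' run order randomised under the seed.
#'
#' @param cfg a [sim_config()].
#' @return a data frame with columns `spider_id`, `morph`, `proximity`,
#'   `colour_match`, `interception_rate`.
#' @export
sim_factorial <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  design <- expand.grid(proximity = c("far", "near"),
                        colour_match = c("matched", "mismatched"),
                        rep = seq_len(cfg$n_per_cell),
                        stringsAsFactors = FALSE)
  b <- cfg$factorial_beta
  near <- design$proximity == "near"
  mis <- design$colour_match == "mismatched"
  mu <- b[["intercept"]] + b[["near"]] * near + b[["mismatched"]] * mis +
    b[["interaction"]] * near * mis
  # substream 5: run-order randomisation; substream 6: capture noise
  set.seed(cfg$seed + 5L)
  ord <- sample(nrow(design))
  set.seed(cfg$seed + 6L)
  rate <- mu[ord] + stats::rnorm(nrow(design), 0, cfg$sigma_factorial)
  if (cfg$floor_rates) rate <- pmax(rate, 0)
  data.frame(spider_id = sprintf("sp_%03d", seq_len(nrow(design))),
             morph = ifelse(mis[ord], "white", "yellow"),
             proximity = design$proximity[ord],
             colour_match = design$colour_match[ord],
             interception_rate = rate)
}
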