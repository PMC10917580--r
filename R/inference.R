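#' Term universe for the observational global model
#'
#' The global model regresses hourly interception rate on physical distance,
#' colour distance with its second- and third-order polynomials, and the
#' interactions of physical distance with all three colour terms.
#'
#' @return character vector of the seven candidate terms.
#' @export
observational_global_terms <- function() {
  c("physical", "colour", "colour2", "colour3",
    "physical:colour", "physical:colour2", "physical:colour3")
}

# terms a given term cannot appear without (one step; closure taken below)
term_parents <- function(term) {
  if (grepl(":", term, fixed = TRUE)) {
    return(strsplit(term, ":", fixed = TRUE)[[1L]])
  }
  switch(term, colour2 = "colour", colour3 = "colour2", character(0))
}

marginality_closure <- function(terms) {
  repeat {
    more <- unique(unlist(lapply(terms, term_parents)))
    grown <- union(terms, more)
    if (setequal(grown, terms)) return(terms)
    terms <- grown
  }
}

#' Marginality check for a model specification
#'
#' A specification respects marginality when every interaction is
#' accompanied by both its parents and every polynomial by all lower orders.
#'
#' @param terms character vector of model terms (may be empty).
#' @return `TRUE` or `FALSE`.
#' @export
respects_marginality <- function(terms) {
  setequal(marginality_closure(terms), terms)
}

#' Enumerate all marginality-respecting subsets of a global model
#'
#' Every subset of `global` (including the intercept-only model) that
#' respects marginality, each in the ordering of `global`.
#'
#' @param global character vector of terms in the global model.
#' @return list of character vectors.
#' @export
enumerate_subsets <- function(global = observational_global_terms()) {
  p <- length(global)
  out <- list()
  for (mask in 0:(2^p - 1L)) {
    terms <- global[bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0L]
    if (respects_marginality(terms)) out[[length(out) + 1L]] <- terms
  }
  out
}

model_label <- function(terms) {
  if (length(terms) == 0L) "1" else paste(terms, collapse = " + ")
}

# analysis frame: response `rate`, predictors `physical`, `colour` and the
# colour polynomial columns, built once per dataset
build_model_frame <- function(records, standardize = FALSE,
                              poly_basis = c("raw", "orthogonal")) {
  poly_basis <- match.arg(poly_basis)
  need <- c("interception_rate", "physical_distance_cm", "colour_distance")
  stopifnot(all(need %in% names(records)))
  d <- data.frame(rate = records$interception_rate,
                  physical = records$physical_distance_cm,
                  colour = records$colour_distance)
  if (standardize) {
    d$physical <- as.numeric(scale(d$physical))
    d$colour <- as.numeric(scale(d$colour))
  }
  if (poly_basis == "raw") {
    d$colour2 <- d$colour^2
    d$colour3 <- d$colour^3
  } else {
    pm <- stats::poly(d$colour, 3)
    d$colour <- pm[, 1L]
    d$colour2 <- pm[, 2L]
    d$colour3 <- pm[, 3L]
  }
  d
}

#' Fit a Gaussian general linear model for interception rates
#'
#' Ordinary least squares with identity link, the analysis model for both
#' assays. The fit carries its coefficient table (estimate, SE, t-based 95%
#' CI, two-sided p on the residual df), the maximum-likelihood Gaussian
#' log-likelihood, R-squared and AICc (with the residual variance counted as
#' an estimated parameter).
#'
#' @param records data frame with columns `interception_rate`,
#'   `physical_distance_cm`, `colour_distance`.
#' @param terms character vector of model terms drawn from
#'   [observational_global_terms()]; empty for the intercept-only model.
#' @param standardize centre and scale the two predictors before fitting.
#' @param poly_basis `"raw"` powers of colour distance (default) or
#'   `"orthogonal"` polynomials.
#' @return a `rate_fit` object.
#' @export
fit_rate_glm <- function(records, terms = c("physical", "colour",
                                            "physical:colour"),
                         standardize = FALSE,
                         poly_basis = c("raw", "orthogonal")) {
  if (!respects_marginality(terms)) {
    stop("model terms violate marginality: ", model_label(terms),
         call. = FALSE)
  }
  d <- build_model_frame(records, standardize = standardize,
                         poly_basis = poly_basis)
  fml <- stats::as.formula(paste("rate ~", model_label(terms)))
  fit <- stats::lm(fml, data = d)
  new_rate_fit(fit, terms = terms)
}

new_rate_fit <- function(fit, terms, subclass = character(0)) {
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("design matrix is rank deficient; collinear terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  n <- length(stats::residuals(fit))
  k <- length(cf) + 1L  # + residual variance
  if (n <= k) {
    stop("more parameters than observations support (n = ", n,
         ", k = ", k, ")", call. = FALSE)
  }
  sm <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  coef_table <- data.frame(
    term = names(cf),
    estimate = unname(cf),
    se = unname(sm$coefficients[, "Std. Error"]),
    ci_lower = unname(ci[, 1L]),
    ci_upper = unname(ci[, 2L]),
    t = unname(sm$coefficients[, "t value"]),
    p = unname(sm$coefficients[, "Pr(>|t|)"]))
  ll <- as.numeric(stats::logLik(fit))
  structure(list(model = fit, terms = terms, coefficients = coef_table,
                 n = n, k = k, logLik = ll,
                 AICc = aicc_value(ll, n, k),
                 r_squared = unname(sm$r.squared),
                 sigma = sm$sigma, df_residual = fit$df.residual),
            class = c(subclass, "rate_fit"))
}

#' @export
print.rate_fit <- function(x, digits = 3, ...) {
  cat("Gaussian linear model:", model_label(x$terms), "\n")
  print(cbind(x$coefficients[1L],
              round(x$coefficients[-1L], digits)), row.names = FALSE)
  cat(sprintf("n = %d, k = %d, logLik = %.3f, AICc = %.3f, R^2 = %.3f\n",
              x$n, x$k, x$logLik, x$AICc, x$r_squared))
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 logLik + 2k + 2k(k + 1)/(n - k - 1), where k counts every
#' estimated parameter including the residual variance. Undefined (an error)
#' when n <= k + 1.
#'
#' @param loglik maximised Gaussian log-likelihood (variance at its ML
#'   estimate).
#' @param n number of observations.
#' @param k number of estimated parameters including the residual variance.
#' @return the AICc value.
#' @export
aicc_value <- function(loglik, n, k) {
  if (n - k - 1 <= 0) {
    stop("AICc undefined: n - k - 1 = ", n - k - 1, call. = FALSE)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @rdname aicc_value
#' @param fit a `rate_fit` or `lm` object.
#' @export
aicc <- function(fit) {
  if (inherits(fit, "rate_fit")) return(fit$AICc)
  if (inherits(fit, "lm")) {
    ll <- stats::logLik(fit)
    return(aicc_value(as.numeric(ll), stats::nobs(fit), attr(ll, "df")))
  }
  stop("aicc() expects a rate_fit or lm object", call. = FALSE)
}

#' Akaike weights
#'
#' Relative support for each candidate: w_i = exp(-Delta_i/2) normalised
#' over the set, with Delta_i = AICc_i - min AICc.
#'
#' @param aiccs numeric vector of finite AICc values.
#' @return weights summing to 1.
#' @export
akaike_weights <- function(aiccs) {
  stopifnot(length(aiccs) >= 1L, all(is.finite(aiccs)))
  d <- aiccs - min(aiccs)
  w <- exp(-d / 2)
  w / sum(w)
}

#' All-subsets AICc model selection
#'
#' Fits every marginality-respecting subset of the global model (including
#' intercept-only), ranks candidates by AICc (ties broken by fewer
#' parameters, then term order) and attaches Delta-AICc and Akaike weights.
#'
#' @inheritParams fit_rate_glm
#' @param global character vector of terms in the global model.
#' @return a `candidate_set`: list with the ranking `table`, the named list
#'   of `fits`, and `best`, the label of the leading model.
#' @export
all_subsets <- function(records, global = observational_global_terms(),
                        standardize = FALSE,
                        poly_basis = c("raw", "orthogonal")) {
  poly_basis <- match.arg(poly_basis)
  specs <- enumerate_subsets(global)
  labels <- vapply(specs, model_label, character(1))
  fits <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    fits[[i]] <- tryCatch(
      fit_rate_glm(records, specs[[i]], standardize = standardize,
                   poly_basis = poly_basis),
      error = function(e) stop("fit failed for model {", labels[i], "}: ",
                               conditionMessage(e), call. = FALSE))
  }
  names(fits) <- labels
  tab <- data.frame(model = labels,
                    k = vapply(fits, function(f) f$k, numeric(1)),
                    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
                    AICc = vapply(fits, function(f) f$AICc, numeric(1)))
  ord <- order(tab$AICc, tab$k, tab$model)
  tab <- tab[ord, , drop = FALSE]
  fits <- fits[ord]
  tab$delta <- tab$AICc - tab$AICc[1L]
  tab$weight <- akaike_weights(tab$AICc)
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, best = tab$model[1L]),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, digits = 3, n = 10, ...) {
  cat("AICc model selection over", nrow(x$table), "candidates\n")
  print(utils::head(cbind(x$table[1L], round(x$table[-1L], digits)), n),
        row.names = FALSE)
  invisible(x)
}

#' @rdname all_subsets
#' @param x a `candidate_set`.
#' @return `best_model()` returns the leading `rate_fit`.
#' @export
best_model <- function(x) {
  stopifnot(inherits(x, "candidate_set"))
  x$fits[[1L]]
}

#' Conditional slope of colour distance at a physical distance
#'
#' For a fit containing `colour` and `physical:colour`, the effect of colour
#' distance at physical distance d is beta_colour + beta_interaction * d,
#' with variance Var(b_c) + d^2 Var(b_i) + 2 d Cov(b_c, b_i); the 95% CI
#' uses the residual-df t quantile. This is the curve behind the
#' interaction: how strongly colour similarity predicts capture success at
#' each spider-flower distance.
#'
#' @param fit a `rate_fit` containing both required terms.
#' @param d numeric vector of physical distances (same scale as the fitted
#'   predictor).
#' @return data frame with columns `distance`, `slope`, `se`, `lower`,
#'   `upper`.
#' @export
conditional_slope <- function(fit, d) {
  stopifnot(inherits(fit, "rate_fit"))
  if (!all(c("colour", "physical:colour") %in% fit$terms)) {
    stop("fit must contain 'colour' and 'physical:colour' terms",
         call. = FALSE)
  }
  b <- stats::coef(fit$model)
  V <- stats::vcov(fit$model)
  slope <- b[["colour"]] + b[["physical:colour"]] * d
  var <- V["colour", "colour"] +
    d^2 * V["physical:colour", "physical:colour"] +
    2 * d * V["colour", "physical:colour"]
  se <- sqrt(var)
  tcrit <- stats::qt(0.975, fit$df_residual)
  data.frame(distance = d, slope = slope, se = se,
             lower = slope - tcrit * se, upper = slope + tcrit * se)
}

#' Fit the 2 x 2 factorial capture model
#'
#' Treatment-coded Gaussian linear model of interception rate on flower
#' proximity (far/near) crossed with colour match (matched/mismatched); the
#' reference cell is (far, matched), so the coefficients are the intercept,
#' the near main effect, the mismatched main effect and the
#' near x mismatched interaction.
#'
#' @param records data frame with columns `interception_rate`, `proximity`
#'   (levels far/near) and `colour_match` (levels matched/mismatched).
#' @return a `factorial_fit` (also a `rate_fit`).
#' @export
fit_factorial <- function(records) {
  need <- c("interception_rate", "proximity", "colour_match")
  stopifnot(all(need %in% names(records)))
  d <- data.frame(rate = records$interception_rate,
                  proximity = factor(records$proximity,
                                     levels = c("far", "near")),
                  colour_match = factor(records$colour_match,
                                        levels = c("matched", "mismatched")))
  if (anyNA(d$proximity) || anyNA(d$colour_match)) {
    stop("proximity must be far/near and colour_match matched/mismatched",
         call. = FALSE)
  }
  cells <- table(d$proximity, d$colour_match)
  if (any(cells == 0L)) {
    stop("empty treatment cell(s): interaction not estimable", call. = FALSE)
  }
  fit <- stats::lm(rate ~ proximity * colour_match, data = d)
  out <- new_rate_fit(fit, terms = c("proximity", "colour_match",
                                     "proximity:colour_match"),
                      subclass = "factorial_fit")
  out$cell_counts <- cells
  out
}

#' Estimated marginal means, Tukey contrasts and letters
#'
#' Model-based cell means for the 2 x 2 design (equal to raw cell means in a
#' balanced design), all six pairwise differences with Tukey-adjusted
#' (studentised-range) p values, and a compact letter display in which cells
#' sharing a letter do not differ at `alpha`.
#'
#' @param fit a [fit_factorial()] result.
#' @param alpha significance level for the letter display.
#' @return an `emm_table`: list with data frames `cells` (emmean, SE, CI,
#'   letters) and `contrasts` (estimate, SE, t, Tukey-adjusted p).
#' @export
emmeans_and_contrasts <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "factorial_fit"))
  emm <- emmeans::emmeans(fit$model, ~ proximity * colour_match)
  cells <- as.data.frame(emm)
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "tukey"))
  labels <- paste(cells$proximity, cells$colour_match, sep = ".")
  # recover the two cell indices behind each contrast label "(a) - (b)"
  pieces <- strsplit(gsub("[()]", "", prs$contrast), " - ", fixed = TRUE)
  idx <- t(vapply(pieces, function(pc) {
    m <- match(gsub(" ", ".", trimws(pc)), labels)
    if (anyNA(m)) stop("could not match contrast labels to cells",
                       call. = FALSE)
    m
  }, integer(2)))
  sig <- idx[prs$p.value < alpha, , drop = FALSE]
  cells$letters <- letter_display(length(labels), sig)
  rownames(cells) <- labels
  structure(list(cells = cells, contrasts = prs, alpha = alpha),
            class = "emm_table")
}

#' @export
print.emm_table <- function(x, digits = 3, ...) {
  cat("estimated marginal means (letters: no difference at alpha =",
      x$alpha, ")\n")
  print(x$cells, digits = digits)
  cat("\npairwise contrasts (Tukey-adjusted)\n")
  print(x$contrasts, digits = digits)
  invisible(x)
}

#' Compact letter display from significant pairs
#'
#' Insert-and-absorb algorithm: starting from one group holding every level,
#' each significantly different pair splits any group containing both, and
#' groups contained in another are absorbed. Levels sharing a letter are not
#' significantly different.
#'
#' @param n_levels number of levels.
#' @param sig_pairs two-column matrix of level indices declared different.
#' @return character vector of letter strings, one per level.
#' @export
letter_display <- function(n_levels, sig_pairs) {
  groups <- list(seq_len(n_levels))
  for (r in seq_len(nrow(sig_pairs))) {
    i <- sig_pairs[r, 1L]
    j <- sig_pairs[r, 2L]
    new_groups <- list()
    for (g in groups) {
      if (i %in% g && j %in% g) {
        new_groups <- c(new_groups, list(setdiff(g, i)), list(setdiff(g, j)))
      } else {
        new_groups <- c(new_groups, list(g))
      }
    }
    # absorb groups that are subsets of (or equal to) an earlier/larger group
    keep <- rep(TRUE, length(new_groups))
    for (a in seq_along(new_groups)) {
      for (b in seq_along(new_groups)) {
        if (a == b || !keep[a] || !keep[b]) next
        if (all(new_groups[[a]] %in% new_groups[[b]]) &&
            (length(new_groups[[a]]) < length(new_groups[[b]]) || a > b)) {
          keep[a] <- FALSE
          break
        }
      }
    }
    groups <- new_groups[keep]
  }
  groups <- groups[order(vapply(groups, min, numeric(1)))]
  out <- character(n_levels)
  for (gi in seq_along(groups)) {
    for (lv in groups[[gi]]) {
      out[lv] <- paste0(out[lv], letters[gi])
    }
  }
  out
}
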