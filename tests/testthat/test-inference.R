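# convenience: records data frame from raw predictor/response vectors
make_records <- function(phys, col, rate) {
  data.frame(spider_id = sprintf("s%03d", seq_along(rate)),
             morph = "yellow", flower_id = sprintf("f%03d", seq_along(rate)),
             physical_distance_cm = phys, colour_distance = col,
             interception_rate = rate)
}

test_that("the Gaussian GLM recovers exact and projected solutions", {
  phys <- seq(0, 500, length.out = 20)
  rec <- make_records(phys, runif(20), 1 + 2 * phys)
  fit <- suppressWarnings(fit_rate_glm(rec, terms = "physical"))
  expect_equal(unname(coef(fit$model)), c(1, 2), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  null <- fit_rate_glm(rec, terms = character(0))
  expect_equal(unname(coef(null$model)), mean(rec$interception_rate))

  # marginality is enforced at fit time
  expect_error(fit_rate_glm(rec, terms = "physical:colour"), "marginality")
  # a constant predictor makes colour collinear with the intercept
  const <- make_records(phys, rep(0.2, 20), rnorm(20))
  expect_error(fit_rate_glm(const, terms = c("colour", "colour2")),
               "rank deficient")
})

test_that("coefficients and SEs equal the normal-equations solution", {
  set.seed(88)
  for (i in 1:5) {
    n <- 40
    rec <- make_records(runif(n, 0, 500), runif(n, 0, 0.5), rnorm(n, 2, 1))
    fit <- fit_rate_glm(rec, terms = c("physical", "colour",
                                       "physical:colour"))
    X <- cbind(1, rec$physical_distance_cm, rec$colour_distance,
               rec$physical_distance_cm * rec$colour_distance)
    ne <- normal_equations(X, rec$interception_rate)
    expect_equal(fit$coefficients$estimate, unname(ne$beta),
                 tolerance = 1e-10)
    expect_equal(fit$coefficients$se, unname(ne$se), tolerance = 1e-10)
  }
})

test_that("AICc follows the closed formula with its small-sample penalty", {
  expect_equal(aicc_value(-30, 20, 3), -2 * -30 + 2 * 3 + 2 * 3 * 4 / 16)
  # large-n limit: correction vanishes
  expect_lt(aicc_value(-100, 1e6, 3) - (2 * 100 + 2 * 3), 1e-4)
  # at fixed likelihood the penalty is monotone in k
  expect_lt(aicc_value(-30, 20, 3), aicc_value(-30, 20, 4))
  expect_error(aicc_value(-30, 5, 4), "undefined")

  # the fit's stored AICc uses the ML Gaussian likelihood and counts the
  # residual variance among the parameters
  set.seed(3)
  rec <- make_records(runif(30, 0, 500), runif(30), rnorm(30))
  fit <- fit_rate_glm(rec, terms = "physical")
  rss <- sum(residuals(fit$model)^2)
  n <- 30
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
  expect_equal(fit$logLik, ll)
  expect_equal(fit$AICc, aicc_value(ll, n, 3))
})

test_that("Akaike weights renormalise exp(-delta/2)", {
  expect_equal(akaike_weights(42), 1)
  w <- akaike_weights(c(100, 101.95))
  expect_equal(round(w, 3), c(0.726, 0.274))
  set.seed(9)
  ws <- akaike_weights(runif(12, 100, 130))
  expect_equal(sum(ws), 1, tolerance = 1e-12)
})

test_that("subset enumeration respects marginality", {
  small <- enumerate_subsets(c("A", "B", "A:B"))
  expect_length(small, 5)
  labs <- sort(vapply(small, function(t) paste(sort(t), collapse = "+"),
                      character(1)))
  expect_identical(labs, sort(c("", "A", "B", "A+B", "A+A:B+B")))

  expect_true(respects_marginality(c("physical", "colour",
                                     "physical:colour")))
  expect_false(respects_marginality(c("colour3", "colour")))
  expect_false(respects_marginality("physical:colour"))
})

test_that("all-subsets selection ranks by AICc and recovers a strong
           interaction from its own model family", {
  cfg <- sim_config(seed = 77, n_observational = 500,
                    beta = c(intercept = 3.5, physical = -0.004,
                             colour = -3, interaction = 0.012),
                    sigma_obs = 0.8)
  obs <- sim_observational(cfg)
  cs <- all_subsets(obs)
  expect_equal(nrow(cs$table), 19)
  expect_equal(cs$table$delta[1], 0)
  expect_equal(which.max(cs$table$weight), 1L)
  expect_equal(sum(cs$table$weight), 1, tolerance = 1e-12)
  # the winner must carry the generating interactive structure (with colour
  # distances confined to [0, ~0.5] the polynomial interaction terms are
  # near-collinear mimics, so the exact winning subset varies)
  expect_true("physical" %in% best_model(cs)$terms)
  expect_true(any(grepl("^physical:", best_model(cs)$terms)))

  # over the interaction family itself, the generating model beats every
  # sub-model decisively
  cs3 <- all_subsets(obs, global = c("physical", "colour",
                                     "physical:colour"))
  expect_equal(nrow(cs3$table), 5)
  expect_setequal(best_model(cs3)$terms,
                  c("physical", "colour", "physical:colour"))
  expect_gt(cs3$table$delta[2], 2)
})

test_that("conditional slopes are linear in distance with the delta-method
           variance", {
  # noiseless construction: slope crosses zero at 400 cm
  set.seed(12)
  n <- 60
  phys <- runif(n, 0, 500)
  col <- runif(n, 0, 0.5)
  rate <- 2 + 0 * phys - 1 * col + 0.0025 * phys * col
  rec <- make_records(phys, col, rate)
  fit <- suppressWarnings(fit_rate_glm(rec, terms = c("physical", "colour",
                                                      "physical:colour")))
  expect_equal(suppressWarnings(conditional_slope(fit, 400)$slope), 0,
               tolerance = 1e-8)

  # noisy fit: boundary and structural checks
  rec$interception_rate <- rate + rnorm(n, 0, 0.5)
  fit <- fit_rate_glm(rec, terms = c("physical", "colour",
                                     "physical:colour"))
  cs0 <- conditional_slope(fit, 0)
  crow <- fit$coefficients[fit$coefficients$term == "colour", ]
  expect_equal(cs0$slope, crow$estimate)
  expect_equal(cs0$lower, crow$ci_lower)
  expect_equal(cs0$upper, crow$ci_upper)

  d <- seq(0, 500, 50)
  sl <- conditional_slope(fit, d)$slope
  expect_equal(diff(sl, differences = 2), rep(0, length(d) - 2),
               tolerance = 1e-12)

  # CI width is minimised where the covariance says it should be
  V <- vcov(fit$model)
  dstar <- -V["colour", "physical:colour"] /
    V["physical:colour", "physical:colour"]
  width <- function(dd) {
    x <- conditional_slope(fit, dd)
    x$upper - x$lower
  }
  expect_lt(width(dstar), width(dstar + 5))
  expect_lt(width(dstar), width(dstar - 5))

  expect_error(conditional_slope(fit_rate_glm(rec, "physical"), 100),
               "must contain")
})

test_that("conditional-slope CIs agree with a parametric bootstrap", {
  set.seed(404)
  n <- 80
  phys <- runif(n, 0, 500)
  col <- runif(n, 0, 0.5)
  rec <- make_records(phys, col, 3 - 0.002 * phys - 2 * col +
                        0.004 * phys * col + rnorm(n, 0, 0.7))
  fit <- fit_rate_glm(rec, terms = c("physical", "colour",
                                     "physical:colour"))
  b <- coef(fit$model)[c("colour", "physical:colour")]
  V <- vcov(fit$model)[c("colour", "physical:colour"),
                       c("colour", "physical:colour")]
  draws <- MASS::mvrnorm(10000, b, V)
  for (d in c(50, 250, 450)) {
    boot_se <- sd(draws[, 1] + d * draws[, 2])
    expect_equal(conditional_slope(fit, d)$se, boot_se, tolerance = 0.02)
  }
})

test_that("the factorial model inverts noiseless cell means exactly", {
  cells <- expand.grid(proximity = c("far", "near"),
                       colour_match = c("matched", "mismatched"))
  means <- c(1.79, 3.48, 1.81, 2.54)  # far/near x matched/mismatched
  rec <- data.frame(proximity = rep(cells$proximity, each = 3),
                    colour_match = rep(cells$colour_match, each = 3),
                    interception_rate = rep(means, each = 3))
  fit <- suppressWarnings(fit_factorial(rec))
  expect_equal(unname(coef(fit$model)), c(1.79, 1.69, 0.02, -0.96),
               tolerance = 1e-10)

  # all cells equal: every effect zero
  flat <- rec
  flat$interception_rate <- 2
  expect_equal(unname(coef(suppressWarnings(fit_factorial(flat))$model)),
               c(2, 0, 0, 0))

  # balanced random fixture equals the normal-equations solution
  set.seed(55)
  rnd <- rec
  rnd$interception_rate <- rnorm(12, 2, 1)
  ffit <- fit_factorial(rnd)
  X <- cbind(1, rnd$proximity == "near", rnd$colour_match == "mismatched",
             (rnd$proximity == "near") * (rnd$colour_match == "mismatched"))
  ne <- normal_equations(X, rnd$interception_rate)
  expect_equal(unname(coef(ffit$model)), unname(ne$beta), tolerance = 1e-10)

  expect_error(fit_factorial(rec[rec$proximity == "far" |
                                   rec$colour_match == "matched", ]),
               "empty treatment cell")
})

test_that("marginal means equal raw cell means in balance; contrasts are
           Tukey-adjusted upward; letters separate shifted cells", {
  cfg <- sim_config(seed = 6)
  fac <- sim_factorial(cfg)
  fit <- fit_factorial(fac)
  emm <- emmeans_and_contrasts(fit)
  raw <- tapply(fac$interception_rate,
                list(fac$proximity, fac$colour_match), mean)
  for (i in seq_len(nrow(emm$cells))) {
    expect_equal(emm$cells$emmean[i],
                 raw[as.character(emm$cells$proximity[i]),
                     as.character(emm$cells$colour_match[i])])
  }
  unadj <- as.data.frame(emmeans::contrast(
    emmeans::emmeans(fit$model, ~ proximity * colour_match),
    method = "pairwise", adjust = "none"))
  expect_true(all(emm$contrasts$p.value >= unadj$p.value - 1e-12))

  # four cells holding identical value sets: all differences exactly zero,
  # one shared letter, adjusted p of 1
  flat <- expand.grid(proximity = c("far", "near"),
                      colour_match = c("matched", "mismatched"),
                      rep = 1:3)
  flat$interception_rate <- rep(c(1.2, 1.7, 2.2), each = 4)
  eflat <- emmeans_and_contrasts(fit_factorial(flat))
  expect_true(all(eflat$cells$letters == "a"))
  expect_true(all(eflat$contrasts$p.value > 0.99))

  # one cell shifted by 10 residual SDs gets a unique letter
  shift <- fac
  sel <- shift$proximity == "near" & shift$colour_match == "matched"
  shift$interception_rate[sel] <- shift$interception_rate[sel] +
    10 * cfg$sigma_factorial
  eshift <- emmeans_and_contrasts(fit_factorial(shift))
  lab <- paste(eshift$cells$proximity, eshift$cells$colour_match, sep = ".")
  shifted_letter <- eshift$cells$letters[lab == "near.matched"]
  expect_equal(nchar(shifted_letter), 1)
  expect_false(grepl(shifted_letter,
                     paste(eshift$cells$letters[lab != "near.matched"],
                           collapse = "")))
})

test_that("the letter display separates exactly the declared pairs", {
  # four levels, only 1-4 and 2-4 differ
  sig <- rbind(c(1, 4), c(2, 4))
  lt <- letter_display(4, sig)
  expect_equal(grepl("a", lt), c(TRUE, TRUE, TRUE, FALSE))
  # no declared differences: everything shares one letter
  expect_equal(letter_display(3, matrix(numeric(0), 0, 2)), rep("a", 3))
  # all pairs differ: all letters unique
  all_sig <- t(combn(3, 2))
  expect_equal(anyDuplicated(letter_display(3, all_sig)), 0L)
})
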