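# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force quadrature, hand-rolled local
# regression, direct normal-equations algebra.

# fine-step Riemann-sum quantum catch for functional stimuli
riemann_catch <- function(refl_fun, sens_fun, ill_fun, step = 0.1,
                          lo = 300, hi = 700) {
  wl <- seq(lo, hi, by = step)
  sum(refl_fun(wl) * ill_fun(wl) * sens_fun(wl)) * step
}

# piecewise-linear interpolation by explicit bracket search
piecewise_linear <- function(x, y, xout) {
  vapply(xout, function(x0) {
    i <- max(which(x <= x0))
    if (x[i] == x0) return(y[i])
    y[i] + (y[i + 1] - y[i]) * (x0 - x[i]) / (x[i + 1] - x[i])
  }, numeric(1))
}

# local quadratic regression with tricube weights over the floor(n * span)
# nearest neighbours, evaluated at each input point
brute_local_regression <- function(x, y, span) {
  n <- length(x)
  q <- floor(n * span)
  vapply(x, function(x0) {
    d <- abs(x - x0)
    idx <- order(d)[seq_len(q)]
    dmax <- max(d[idx])
    w <- (1 - pmin(d[idx] / dmax, 1)^3)^3
    keep <- w > 0
    X <- cbind(1, x[idx] - x0, (x[idx] - x0)^2)
    cf <- lm.wfit(X[keep, , drop = FALSE], y[idx][keep], w[keep])$coefficients
    cf[1]
  }, numeric(1))
}

# type-7 percentile by explicit sort-and-interpolate
sort_interp_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# OLS coefficients and standard errors straight from the normal equations
normal_equations <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  list(beta = drop(beta), se = sqrt(diag(sigma2 * solve(XtX))),
       sigma2 = sigma2, df = df)
}

# random loci uniform in the unit square around the origin
random_loci <- function(n) {
  data.frame(x = runif(n, -1, 1), y = runif(n, -1, 1))
}

# a smooth Gaussian-band reflectance on an arbitrary grid
gaussian_refl <- function(centre, width, height = 0.8) {
  function(wl) height * exp(-(wl - centre)^2 / (2 * width^2))
}

# small wrapper: spectra object from a list of functions on a grid
spectra_from_functions <- function(funs, wl) {
  df <- data.frame(wl = wl)
  for (nm in names(funs)) df[[nm]] <- funs[[nm]](wl)
  as_spectra(df)
}
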