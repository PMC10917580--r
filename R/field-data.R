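#' Hourly prey-interception rate
#'
#' Interceptions are recorded as new-prey counts at fixed transect checks
#' (every 30 min over a 4-h session in the field protocol); the rate for an
#' individual is total new prey divided by the observed duration.
#'
#' @param counts nonnegative new-prey counts, one per check.
#' @param session_hours total observed duration in hours.
#' @return prey per hour.
#' @export
interception_rate <- function(counts, session_hours) {
  if (!is.numeric(session_hours) || length(session_hours) != 1L ||
      session_hours <= 0) {
    stop("session_hours must be a single positive duration", call. = FALSE)
  }
  if (any(counts < 0) || anyNA(counts)) {
    stop("prey counts must be nonnegative", call. = FALSE)
  }
  sum(counts) / session_hours
}

#' Per-spider rates from a raw checks table
#'
#' @param checks data frame with columns `spider_id` and `new_prey`, one row
#'   per transect check.
#' @param interval_min minutes between checks (default 30).
#' @return data frame with columns `spider_id` and `interception_rate`.
#' @export
interception_rates <- function(checks, interval_min = 30) {
  stopifnot(all(c("spider_id", "new_prey") %in% names(checks)))
  ids <- unique(checks$spider_id)
  rate <- vapply(ids, function(id) {
    cts <- checks$new_prey[checks$spider_id == id]
    interception_rate(cts, length(cts) * interval_min / 60)
  }, numeric(1))
  data.frame(spider_id = ids, interception_rate = rate)
}

#' Exclude spiders too far from any flower
#'
#' Drops records whose spider-to-inflorescence distance is strictly over the
#' cutoff ("over five metres" in the field protocol, so a record at exactly
#' the cutoff is retained). Idempotent.
#'
#' @param records data frame with a `physical_distance_cm` column.
#' @param max_cm cutoff in cm (default 500).
#' @return the filtered records, with attribute `n_removed`.
#' @export
exclude_distant <- function(records, max_cm = 500) {
  stopifnot("physical_distance_cm" %in% names(records))
  keep <- records$physical_distance_cm <= max_cm
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Empirical sample percentile
#'
#' Linear-interpolation (type-7) sample percentile, the default convention
#' of R's `quantile()`.
#'
#' @param values numeric sample, at least one value.
#' @param p percentile in \[0, 100\].
#' @return the percentile value.
#' @export
sample_percentile <- function(values, p) {
  if (length(values) == 0L || anyNA(values)) {
    stop("need at least one non-missing value", call. = FALSE)
  }
  stopifnot(p >= 0, p <= 100)
  unname(stats::quantile(values, probs = p / 100, type = 7))
}

#' Treatment distance levels from observational distances
#'
#' The factorial experiment places flowers at "near" and "far" distances
#' chosen as the 5th and 95th percentiles of the naturally observed
#' spider-flower distances, reported to the nearest cm.
#'
#' @param records data frame with a `physical_distance_cm` column, or a
#'   numeric vector of distances (cm).
#' @param probs two percentiles in \[0, 100\] (default 5 and 95).
#' @return named numeric `c(near = ..., far = ...)` in whole cm.
#' @export
design_distance_levels <- function(records, probs = c(5, 95)) {
  d <- if (is.data.frame(records)) records$physical_distance_cm else records
  stopifnot(length(probs) == 2L)
  c(near = round(sample_percentile(d, probs[1L])),
    far = round(sample_percentile(d, probs[2L])))
}

#' Assemble proximity records
#'
#' Joins per-spider interception rates with physical distances and fly-space
#' colour distances into the analysis table, applying the distance exclusion.
#'
#' @param rates data frame from [interception_rates()] (or with columns
#'   `spider_id`, `interception_rate`).
#' @param distances data frame with columns `spider_id`, `morph`,
#'   `flower_id`, `physical_distance_cm`, `colour_distance`.
#' @param max_cm exclusion cutoff passed to [exclude_distant()].
#' @return one row per retained spider with the six analysis columns.
#' @export
assemble_records <- function(rates, distances, max_cm = 500) {
  stopifnot(all(c("spider_id", "interception_rate") %in% names(rates)))
  need <- c("spider_id", "morph", "flower_id", "physical_distance_cm",
            "colour_distance")
  stopifnot(all(need %in% names(distances)))
  out <- merge(distances[need], rates, by = "spider_id")
  exclude_distant(out, max_cm = max_cm)
}
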