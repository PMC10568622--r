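# Shared low-level helpers: timestamps, truncated normals, rounding.

#' Parse ISO-8601 timestamps at minute resolution
#'
#' Timestamps throughout the package are UTC, ISO-8601, minute resolution
#' (`YYYY-MM-DDTHH:MM`). All interval logic uses half-open intervals
#' `[start, stop)`.
#'
#' @param x character vector of timestamps.
#' @return `POSIXct` vector (UTC).
#' @export
parse_ts <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(as.character(x), format = "%Y-%m-%dT%H:%M", tz = "UTC")
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) {
    abort(sprintf("unparseable timestamp(s): %s",
                  paste(head(unique(x[bad]), 5), collapse = ", ")))
  }
  out
}

#' Format timestamps as ISO-8601 minute strings
#' @param x POSIXct vector.
#' @return character vector.
#' @export
format_ts <- function(x) {
  out <- format(x, "%Y-%m-%dT%H:%M", tz = "UTC")
  out[is.na(x)] <- NA_character_
  out
}

hours_between <- function(later, earlier) {
  as.numeric(difftime(later, earlier, units = "hours"))
}

days_between <- function(later, earlier) {
  as.numeric(difftime(later, earlier, units = "days"))
}

# Inverse-CDF sampler for the truncated normal; deterministic given the RNG
# state, no rejection loop.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Analytic mean / sd of a truncated normal.
truncnorm_moments <- function(mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  da <- dnorm(a)
  db <- dnorm(b)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  list(mean = m, sd = sqrt(v))
}

# Find underlying (mu, sigma) so the [lower, upper]-truncated normal has the
# requested mean and sd. Naive truncation would bias hard-bounded marginals
# (e.g. age >= 65) upward by up to one SD.
calibrate_truncnorm <- function(target_mean, target_sd, lower, upper) {
  obj <- function(par) {
    mm <- truncnorm_moments(par[1], exp(par[2]), lower, upper)
    (mm$mean - target_mean)^2 + (mm$sd - target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               control = list(reltol = 1e-12, maxit = 2000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Round for rendering
#'
#' Quantities are computed in full precision and rounded only when rendered.
#' Uses base R rounding (IEC half-to-even), which reproduces the conventional
#' presentation of every rate this package reports.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded numeric vector.
#' @export
render_round <- function(x, digits = 2) round(x, digits)

# split/join for semicolon-packed list columns in the CSV formats
split_semi <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE), function(v) v[nzchar(v)])
}

join_semi <- function(x) {
  vapply(x, function(v) paste(v, collapse = ";"), character(1))
}
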