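#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rpois rlnorm runif qt sd median quantile setNames
NULL

#' Weekday labels used throughout the package
#'
#' Day 0 of every simulation horizon is a Monday; the weekday of day `t`
#' is `weekdays_short()[t %% 7 + 1]`.
#'
#' @return Character vector `c("Mon", ..., "Sun")`.
#' @export
weekdays_short <- function() {
  c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
}

#' Weekday of a simulation day index
#'
#' @param day Integer day index (day 0 = Monday).
#' @return Character weekday label.
#' @export
weekday_of <- function(day) {
  weekdays_short()[day %% 7L + 1L]
}

#' Convert natural-scale mean/sd to lognormal log-scale parameters
#'
#' Instance files state lognormal service-time parameters on the log scale
#' (`mu`, `sigma`). Hospital data usually comes as a natural-scale mean and
#' standard deviation; this converts them, so that
#' `rlnorm(n, mu, sigma)` has the requested mean and sd.
#'
#' @param mean Natural-scale mean (> 0).
#' @param sd Natural-scale standard deviation (>= 0).
#' @return Named list with `mu` and `sigma` (log scale).
#' @examples
#' lognormal_params(2, 0.3)
#' @export
lognormal_params <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  sigma2 <- log(1 + sd^2 / mean^2)
  list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Mean of a lognormal distribution from log-scale parameters
#'
#' @param mu,sigma Log-scale parameters.
#' @return `exp(mu + sigma^2 / 2)`.
#' @export
lognormal_mean <- function(mu, sigma) {
  exp(mu + sigma^2 / 2)
}

# Parse "H:MM" / "HH:MM" clock times to minutes from midnight; numeric
# input is passed through (already minutes).
parse_clock <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  vapply(x, function(s) {
    parts <- strsplit(as.character(s), ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L || anyNA(suppressWarnings(as.numeric(parts)))) {
      stop("cannot parse clock time '", s, "' (expected 'H:MM' or minutes)",
           call. = FALSE)
    }
    as.numeric(parts[1]) * 60 + as.numeric(parts[2])
  }, numeric(1), USE.NAMES = FALSE)
}

format_clock <- function(mins) {
  sprintf("%d:%02d", mins %/% 60, round(mins %% 60))
}

# Derive a child seed from a master seed and a stream label, keeping the
# result a valid 32-bit R integer. Streams let the generator reuse demand
# randomness while re-randomising service times (and vice versa).
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 69069 + h * 30269 + 101) %% 2147483647)
}
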