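#' Tidy the steady state of a tray inventory chain
#'
#' @param x A `di_fit` from [di_steady_state()].
#' @param ... Unused.
#' @return Tibble with one row per sterile-inventory state: `state`,
#'   `pi`.
#' @export
tidy.di_fit <- function(x, ...) {
  tibble(state = 0:x$Q, pi = x$pi)
}

#' One-row summary of a tray inventory chain fit
#'
#' @param x A `di_fit`.
#' @param ... Unused.
#' @return Tibble with `Q`, `service_level`, `p_stockout`.
#' @export
glance.di_fit <- function(x, ...) {
  tibble(Q = x$Q, service_level = x$service_level,
         p_stockout = 1 - x$service_level)
}

#' Tidy an MSER truncation analysis
#'
#' @param x An `mser_result`.
#' @param ... Unused.
#' @return The per-truncation statistic tibble (`d`, `value`), with the
#'   chosen truncation flagged.
#' @export
tidy.mser_result <- function(x, ...) {
  out <- x$statistics
  out$selected <- out$d == x$d_star
  out
}

#' @export
glance.mser_result <- function(x, ...) {
  tibble(m = x$m, d_star = x$d_star,
         points_truncated = x$d_star * x$m)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
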