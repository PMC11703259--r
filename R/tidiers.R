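#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an exponential calcium fit
#'
#' @param x A `ca_expfit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @method tidy ca_expfit
#' @export
tidy.ca_expfit <- function(x, ...) {
  tibble::tibble(term = c("A", "tau_ms", "C"),
                 estimate = c(x$A, x$tau_ms, x$C))
}

#' One-row summary of an exponential calcium fit
#'
#' @param x A `ca_expfit`.
#' @param ... Unused.
#' @return Tibble with `minimum`, `resid_norm`, `n`.
#' @method glance ca_expfit
#' @export
glance.ca_expfit <- function(x, ...) {
  tibble::tibble(minimum = x$minimum, resid_norm = x$resid_norm, n = x$n)
}

#' Tidy an ellipse fit
#'
#' @param x An `ellipse_fit`.
#' @param ... Unused.
#' @return One-row tibble of the geometric parameters.
#' @method tidy ellipse_fit
#' @export
tidy.ellipse_fit <- function(x, ...) {
  tibble::tibble(center_row = x$center_row, center_col = x$center_col,
                 major_len = x$major_len, minor_len = x$minor_len,
                 angle_deg = x$angle_deg)
}

#' Tidy an active-zone boundary
#'
#' @param x An `az_boundary`.
#' @param ... Unused.
#' @return Tibble of contour vertices with the level and crossing flag.
#' @method tidy az_boundary
#' @export
tidy.az_boundary <- function(x, ...) {
  tibble::tibble(row = x$vertices[, 1], col = x$vertices[, 2],
                 level = x$level, crossing = x$crossing)
}
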