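#' Standardize imaging days onto [-1, 1]
#'
#' Maps integer imaging days linearly onto the Legendre domain \eqn{[-1, 1]}.
#' The standardization window (`domain`) is a first-class argument so that a
#' model can be fitted on an early sub-window of days while its basis is later
#' evaluated at forecast days inside the same declared domain: the forecasting
#' scenarios rely on this.
#'
#' The map is \eqn{x_i = -1 + 2 (d_i - d_{min}) / (d_{max} - d_{min})} with
#' `domain = c(d_min, d_max)`. A degenerate single-point domain
#' (`d_min == d_max`) standardizes to 0.
#'
#' @param days Integer (or numeric) vector of imaging days, strictly
#'   increasing.
#' @param domain Length-2 numeric vector `c(domain_min, domain_max)` covering
#'   all `days`. Defaults to `range(days)`.
#' @return An object of class `time_grid`: a list with elements `days`,
#'   `domain` and `standardized` (values in \eqn{[-1, 1]}).
#' @examples
#' g <- standardize_time(1:20)
#' g$standardized[c(1, 20)]  # -1 and 1
#' @export
standardize_time <- function(days, domain = range(days)) {
  if (length(days) == 0L) stop("'days' must be non-empty")
  if (any(diff(days) <= 0)) stop("'days' must be strictly increasing")
  if (length(domain) != 2L) stop("'domain' must have length 2")
  if (domain[1] > min(days) || domain[2] < max(days)) {
    stop("'domain' [", domain[1], ", ", domain[2],
         "] does not cover all days [", min(days), ", ", max(days), "]")
  }
  width <- domain[2] - domain[1]
  if (width < 0) stop("'domain' must satisfy domain_min <= domain_max")
  std <- if (width == 0) rep(0, length(days)) else {
    -1 + 2 * (days - domain[1]) / width
  }
  structure(list(days = as.numeric(days), domain = as.numeric(domain),
                 standardized = std),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat("time_grid:", length(x$days), "days in [", x$days[1], ",",
      x$days[length(x$days)], "], domain [", x$domain[1], ",", x$domain[2],
      "]\n")
  invisible(x)
}

## Classical Legendre polynomials P_0..P_k at points x, by the three-term
## Bonnet recurrence (j+1) P_{j+1} = (2j+1) x P_j - j P_{j-1}.
legendre_raw <- function(x, order) {
  stopifnot(order >= 0)
  out <- matrix(0, length(x), order + 1L)
  out[, 1L] <- 1
  if (order >= 1L) out[, 2L] <- x
  if (order >= 2L) {
    for (j in 1L:(order - 1L)) {
      out[, j + 2L] <- ((2 * j + 1) * x * out[, j + 1L] - j * out[, j]) /
        (j + 1)
    }
  }
  out
}

#' Normalized Legendre covariable matrix
#'
#' Builds the \eqn{t \times (k+1)} matrix \eqn{\Phi} of Legendre polynomial
#' covariables evaluated at the standardized days of a [standardize_time()]
#' grid. By default the columns are the *normalized* polynomials
#' \eqn{\phi_j(x) = \sqrt{(2j+1)/2}\, P_j(x)}, the covariance-function
#' convention of the animal-breeding literature (orthonormal under the
#' continuous inner product on \eqn{[-1,1]}). Raw \eqn{P_j} are available with
#' `normalized = FALSE`.
#'
#' @param grid A `time_grid` from [standardize_time()], or a numeric vector of
#'   already-standardized points in \eqn{[-1, 1]}.
#' @param order Non-negative integer polynomial order \eqn{k}.
#' @param normalized Use the \eqn{\sqrt{(2j+1)/2}} normalization (default
#'   `TRUE`).
#' @return An object of class `legendre_basis`: list with `order`, `grid`,
#'   `normalized` and the matrix `phi` (rows = days, columns = degrees
#'   \eqn{0..k}).
#' @examples
#' b <- legendre_matrix(standardize_time(1:20), order = 2)
#' dim(b$phi)  # 20 x 3
#' @export
legendre_matrix <- function(grid, order, normalized = TRUE) {
  if (!is.numeric(order) || length(order) != 1L || order < 0 ||
      order != round(order)) {
    stop("'order' must be a single non-negative integer")
  }
  x <- if (inherits(grid, "time_grid")) grid$standardized else as.numeric(grid)
  if (any(x < -1 - 1e-12 | x > 1 + 1e-12)) {
    stop("standardized points must lie in [-1, 1]")
  }
  phi <- legendre_raw(x, order)
  if (normalized) {
    phi <- sweep(phi, 2L, sqrt((2 * (0:order) + 1) / 2), `*`)
  }
  colnames(phi) <- paste0("deg", 0:order)
  structure(list(order = as.integer(order),
                 grid = if (inherits(grid, "time_grid")) grid else NULL,
                 standardized = x, normalized = normalized, phi = phi),
            class = "legendre_basis")
}

## Convenience: phi matrix for a set of days under a declared domain.
legendre_phi <- function(days, domain, order, normalized = TRUE) {
  legendre_matrix(standardize_time(days, domain), order, normalized)$phi
}
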