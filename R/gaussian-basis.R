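#' Broad Gaussian baseline basis
#'
#' The baseline of a Raman measurement is a smooth curve with far less
#' curvature than any Raman peak (peak widths are below about 350 cm^-1).
#' It can therefore be spanned by a family of L broad Gaussian vectors laid
#' out along the wavenumber axis.  The design has exactly two rules:
#'
#' * the first and last centers are pinned to the grid endpoints
#'   (m_1 = nu_1, m_L = nu_p) and the centers are equally spaced, so the
#'   spacing is `dm = (nu_p - nu_1)/(L - 1)`;
#' * the common width is tied to the spacing so that each Gaussian decays to
#'   exactly 1/2 at its neighbours' centers: `sigma = dm * sqrt(1/(2*log(2)))`.
#'
#' With L = 11 on the 375-3500 cm^-1 grid this gives a center spacing of
#' 312.5 cm^-1 and a width of about 265 cm^-1.  Narrower widths (below
#' 350/(2 log 2), about 250 cm^-1) start to overlap the scale of real Raman
#' peaks; `gaussian_width()` warns when a choice of L enters that regime.
#'
#' @name gaussian_basis
NULL

# sigma = width_scale * dm; the default reproduces the half-value-at-
# neighbour rule.  The floor below which Gaussians are narrow enough to
# absorb genuine Raman peaks (widths < 350 cm^-1) is 350/(2 log 2).
.default_width_scale <- function() sqrt(1 / (2 * log(2)))

.sigma_floor_cm <- function() 350 / (2 * log(2))

#' Centers of the broad Gaussian vectors
#'
#' @param grid a [make_grid()] axis
#' @param L number of Gaussian vectors (at least 2: both endpoints are pinned)
#' @return L equally spaced centers in cm^-1, from `nu_1` to `nu_p`
#' @export
gaussian_centers <- function(grid, L) {
  stopifnot(inherits(grid, "wn_grid"))
  if (!is.numeric(L) || length(L) != 1L || L != round(L) || L < 2)
    stop("'L' must be a single integer >= 2", call. = FALSE)
  nu1 <- grid$nu[1L]; nup <- grid$nu[grid$p]
  nu1 + (nup - nu1) * (seq_len(L) - 1) / (L - 1)
}

#' Width parameter of the broad Gaussian vectors
#'
#' @inheritParams gaussian_centers
#' @param width_scale multiplier applied to the center spacing; the default
#'   `sqrt(1/(2 log 2))` makes each Gaussian equal 1/2 at the adjacent
#'   centers
#' @return the width sigma in cm^-1 used in the Gaussian exponent
#'   `exp(-(nu - m)^2 / (2 sigma^2))`
#' @export
gaussian_width <- function(grid, L, width_scale = .default_width_scale()) {
  stopifnot(inherits(grid, "wn_grid"))
  if (!is.numeric(L) || length(L) != 1L || L != round(L) || L < 2)
    stop("'L' must be a single integer >= 2", call. = FALSE)
  dm <- (grid$nu[grid$p] - grid$nu[1L]) / (L - 1)
  sigma <- width_scale * dm
  if (sigma < .sigma_floor_cm())
    warning(sprintf(paste0("sigma = %.1f cm^-1 is below the recommended floor of ",
                           "%.0f cm^-1 (Raman peaks are narrower than 350 cm^-1); ",
                           "the basis may absorb genuine peaks"),
                    sigma, .sigma_floor_cm()), call. = FALSE)
  sigma
}

#' Build the broad Gaussian matrix K_bl
#'
#' Element (i, l) is `exp(-(nu_i - m_l)^2 / (2 sigma^2))`: strictly positive
#' everywhere, equal to 1 at the center, and (with the default width) equal
#' to 1/2 at the neighbouring centers.
#'
#' @inheritParams gaussian_width
#' @return an object of class `gaussian_basis` with fields `K` (p x L
#'   matrix), `L`, `centers`, `sigma` and `delta_m`
#' @examples
#' g <- make_grid(375, 3500, 947)
#' gb <- build_gaussian_basis(g, L = 11)
#' gb$delta_m    # 312.5 cm^-1
#' gb$sigma      # about 265 cm^-1
#' @export
build_gaussian_basis <- function(grid, L, width_scale = .default_width_scale()) {
  stopifnot(inherits(grid, "wn_grid"))
  if (!is.numeric(L) || length(L) != 1L || L != round(L) || L < 2)
    stop("'L' must be a single integer >= 2", call. = FALSE)
  if (L >= grid$p)
    stop("'L' must be smaller than the number of channels", call. = FALSE)
  m <- gaussian_centers(grid, L)
  sigma <- gaussian_width(grid, L, width_scale)
  K <- exp(-outer(grid$nu, m, "-")^2 / (2 * sigma^2))
  colnames(K) <- paste0("g", seq_len(L))
  structure(list(grid = grid, K = K, L = as.integer(L), centers = m,
                 sigma = sigma, delta_m = if (L > 1) m[2L] - m[1L] else NA_real_),
            class = "gaussian_basis")
}

#' @export
print.gaussian_basis <- function(x, ...) {
  cat(sprintf("Broad Gaussian basis: L = %d vectors, center spacing %.4g cm^-1, sigma %.4g cm^-1\n",
              x$L, x$delta_m, x$sigma))
  invisible(x)
}
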