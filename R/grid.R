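#' Wavenumber grids and spectrum containers
#'
#' A `wn_grid` is the common Raman-shift axis shared by every spectrum and
#' model matrix in the package: `p` channels, uniformly spaced in cm^-1.
#' All model-fitting operations verify grid identity (same endpoints and
#' channel count) before touching the numbers, so a spectrum measured on a
#' different axis fails fast instead of being silently misaligned.
#'
#' @param nu_min,nu_max axis endpoints in cm^-1 (`nu_max > nu_min`)
#' @param n_channels number of channels (at least 3)
#' @return an object of class `wn_grid` with fields `nu` (the axis),
#'   `p` (channel count) and `spacing` (cm^-1 per channel)
#' @examples
#' g <- make_grid(375, 3500, 947)   # the default survey grid
#' g$spacing                        # about 3.3 cm^-1
#' @export
make_grid <- function(nu_min, nu_max, n_channels) {
  stopifnot(is.numeric(nu_min), is.numeric(nu_max), length(nu_min) == 1L,
            length(nu_max) == 1L)
  if (!is.numeric(n_channels) || length(n_channels) != 1L ||
      n_channels != round(n_channels) || n_channels < 3)
    stop("'n_channels' must be a single integer >= 3", call. = FALSE)
  if (nu_max <= nu_min)
    stop("'nu_max' must be strictly greater than 'nu_min'", call. = FALSE)
  p <- as.integer(n_channels)
  nu <- seq(nu_min, nu_max, length.out = p)
  structure(list(nu = nu, p = p, spacing = (nu_max - nu_min) / (p - 1)),
            class = "wn_grid")
}

#' @export
print.wn_grid <- function(x, ...) {
  cat(sprintf("Wavenumber grid: %g to %g cm^-1, %d channels (spacing %.4g cm^-1)\n",
              x$nu[1L], x$nu[x$p], x$p, x$spacing))
  invisible(x)
}

# grid identity contract: (min, max, p) triple equality
same_grid <- function(a, b) {
  isTRUE(a$p == b$p) && isTRUE(a$nu[1L] == b$nu[1L]) &&
    isTRUE(a$nu[a$p] == b$nu[b$p])
}

check_grid <- function(a, b, what = "object") {
  if (!same_grid(a, b))
    stop(sprintf("grid mismatch: %s is defined on a different wavenumber axis",
                 what), call. = FALSE)
  invisible(TRUE)
}

# width/radius parameters are given in cm^-1 but filters act on channels
cm_to_channels <- function(grid, width_cm) {
  max(1L, as.integer(round(width_cm / grid$spacing)))
}

#' Construct a spectrum on a wavenumber grid
#'
#' @param grid a [make_grid()] axis
#' @param values numeric intensities, one per channel, all finite
#' @param label free-text identifier carried through batch operations
#' @return an object of class `raman_spectrum`
#' @export
raman_spectrum <- function(grid, values, label = "") {
  stopifnot(inherits(grid, "wn_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$p)
    stop("'values' must have one intensity per grid channel", call. = FALSE)
  if (!all(is.finite(values)))
    stop("'values' must all be finite", call. = FALSE)
  structure(list(grid = grid, values = values, label = as.character(label)[1L]),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("Raman spectrum%s: %d channels, %g to %g cm^-1, intensity range [%.4g, %.4g]\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$grid$p, x$grid$nu[1L], x$grid$nu[x$grid$p],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.raman_spectrum <- function(x, ..., xlab = expression(paste("Raman shift (", cm^-1, ")")),
                                ylab = "Intensity", type = "l") {
  graphics::plot(x$grid$nu, x$values, type = type, xlab = xlab, ylab = ylab,
                 main = x$label, ...)
  invisible(x)
}

#' Reference spectrum library
#'
#' Holds the p x C matrix S whose columns are reference Raman signatures of
#' the target analytes.  Columns must be finite and none may be all-zero.
#'
#' @param grid shared wavenumber axis
#' @param S numeric p x C matrix of reference spectra
#' @param names optional column labels (analyte names)
#' @export
reference_library <- function(grid, S, names = colnames(S)) {
  stopifnot(inherits(grid, "wn_grid"))
  S <- as.matrix(S)
  if (nrow(S) != grid$p)
    stop("'S' must have one row per grid channel", call. = FALSE)
  if (!all(is.finite(S)))
    stop("'S' must be finite", call. = FALSE)
  if (any(colSums(abs(S)) == 0))
    stop("'S' contains an all-zero reference column", call. = FALSE)
  if (is.null(names)) names <- paste0("ref", seq_len(ncol(S)))
  colnames(S) <- names
  structure(list(grid = grid, S = S, names = names),
            class = "reference_library")
}

#' Background basis matrix
#'
#' Container for the p x M basis of background-material signatures
#' (columns of K_bg).  When produced by [build_background_basis()] the
#' columns are orthonormal left singular vectors of a corrected background
#' corpus; a hand-made basis is accepted as-is.
#'
#' @param grid shared wavenumber axis
#' @param K numeric p x M matrix
#' @export
background_basis <- function(grid, K) {
  stopifnot(inherits(grid, "wn_grid"))
  K <- as.matrix(K)
  if (nrow(K) != grid$p)
    stop("'K' must have one row per grid channel", call. = FALSE)
  if (!all(is.finite(K)))
    stop("'K' must be finite", call. = FALSE)
  structure(list(grid = grid, K = K, M = ncol(K)),
            class = "background_basis")
}

#' Heteroscedastic Gaussian noise model
#'
#' Instrument noise is modelled as n ~ N(0, gamma * Sigma) with Sigma a
#' diagonal matrix of per-channel variances.  `gamma` is an overall scale
#' (correction) factor.
#'
#' @param sigma_sq per-channel variances, all positive
#' @param gamma positive scale factor
#' @export
noise_model <- function(sigma_sq, gamma = 1) {
  sigma_sq <- as.numeric(sigma_sq)
  if (any(!is.finite(sigma_sq)) || any(sigma_sq <= 0))
    stop("'sigma_sq' must be positive and finite", call. = FALSE)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("'gamma' must be a positive scalar", call. = FALSE)
  structure(list(sigma_sq = sigma_sq, gamma = gamma), class = "noise_model")
}
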