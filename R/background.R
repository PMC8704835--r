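#' Build a background basis from a corpus of background spectra
#'
#' Each background spectrum is baseline-corrected, the corrected spectra
#' are stacked into a p x N matrix, and the left singular vectors of the M
#' largest singular values become the basis columns.  Columns are
#' orthonormal; the SVD sign ambiguity is fixed by flipping each vector so
#' its largest-magnitude element is positive.
#'
#' @param spectra list of [raman_spectrum()] objects on one grid (N >= M)
#' @param M number of basis vectors to keep
#' @param corrector function mapping a spectrum to a `baseline_fit`
#'   (default [arpls_baseline()]); use `identity_corrector` to skip
#'   correction
#' @return a [background_basis()] with orthonormal columns
#' @export
build_background_basis <- function(spectra, M, corrector = arpls_baseline) {
  if (inherits(spectra, "raman_spectrum")) spectra <- list(spectra)
  n <- length(spectra)
  if (n == 0L) stop("empty background corpus", call. = FALSE)
  grid <- spectra[[1L]]$grid
  for (s in spectra) check_grid(grid, s$grid, "background spectrum")
  if (!is.numeric(M) || length(M) != 1L || M < 1 || M != round(M))
    stop("'M' must be a positive integer", call. = FALSE)
  if (M > n)
    stop("'M' exceeds the number of background spectra", call. = FALSE)
  if (M >= grid$p)
    stop("'M' must be smaller than the number of channels", call. = FALSE)
  corrected <- vapply(spectra,
                      function(s) residuals(corrector(s)),
                      numeric(grid$p))
  sv <- svd(corrected, nu = M, nv = 0)
  U <- sv$u
  for (j in seq_len(M)) {            # deterministic sign convention
    i_max <- which.max(abs(U[, j]))
    if (U[i_max, j] < 0) U[, j] <- -U[, j]
  }
  colnames(U) <- paste0("bg", seq_len(M))
  background_basis(grid, U)
}

#' A pass-through "corrector" leaving spectra unchanged
#' @param x a [raman_spectrum()]
#' @return a `baseline_fit` whose baseline is identically zero
#' @export
identity_corrector <- function(x) {
  new_baseline_fit(x, rep(0, x$grid$p), "none")
}

#' Fraction of corpus energy captured by a background basis
#'
#' Squared Frobenius norm of the projection of the stacked spectra onto the
#' basis span, divided by the squared Frobenius norm of the stack.  Useful
#' for choosing the number of components M.
#'
#' @param spectra list of [raman_spectrum()] objects
#' @param basis a [background_basis()]
#' @return a number in \[0, 1\]
#' @export
explained_fraction <- function(spectra, basis) {
  if (inherits(spectra, "raman_spectrum")) spectra <- list(spectra)
  if (length(spectra) == 0L) stop("empty corpus", call. = FALSE)
  stopifnot(inherits(basis, "background_basis"))
  grid <- basis$grid
  for (s in spectra) check_grid(grid, s$grid, "spectrum")
  X <- vapply(spectra, function(s) s$values, numeric(grid$p))
  qrK <- qr(basis$K)
  proj <- qr.fitted(qrK, X)
  total <- sum(X^2)
  if (total == 0) return(0)
  sum(proj^2) / total
}
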