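#' Iterative median filter (IMF) baseline
#'
#' Repeated passes of a sliding-window median smooth away the narrow Raman
#' peaks and leave the slowly varying baseline.  The window is given in
#' cm^-1 and converted to an odd channel count; edges are handled by
#' mirror reflection.
#'
#' @param x a [raman_spectrum()]
#' @param window_cm window width in cm^-1 (default 300)
#' @param n_iter number of median passes (default 5)
#' @return a `baseline_fit`
#' @export
imf_baseline <- function(x, window_cm = 300, n_iter = 5L) {
  stopifnot(inherits(x, "raman_spectrum"))
  if (!is.numeric(n_iter) || length(n_iter) != 1L || n_iter < 1)
    stop("'n_iter' must be a positive integer", call. = FALSE)
  p <- x$grid$p
  k <- cm_to_channels(x$grid, window_cm)
  if (k < 3L) k <- 3L
  if (k %% 2L == 0L) k <- k + 1L
  if (k > p)
    stop("median window is wider than the spectrum", call. = FALSE)
  b <- x$values
  for (it in seq_len(n_iter)) b <- reflect_runmed(b, k)
  new_baseline_fit(x, b, "imf",
                   extra = list(window_channels = k, n_iter = as.integer(n_iter)))
}

# running median with mirror (no edge repeat) padding
reflect_runmed <- function(v, k) {
  p <- length(v)
  h <- (k - 1L) %/% 2L
  padded <- c(v[(h + 1L):2L], v, v[(p - 1L):(p - h)])
  out <- stats::runmed(padded, k, endrule = "keep")
  out[(h + 1L):(h + p)]
}

#' Rolling circle filter (RCF) baseline
#'
#' Rolls a circle beneath the spectrum: the circle is tangent to the slowly
#' varying baseline but too wide to enter the narrow Raman peaks, and the
#' baseline is the envelope traced by the top of the circle.  Realised as a
#' grayscale morphological opening (erosion then dilation) with a
#' semicircular structuring element of the given radius; the vertical
#' semi-axis of the element defaults to the intensity range of the
#' spectrum, so the element is a circle in (channel, normalised intensity)
#' coordinates.
#'
#' @param x a [raman_spectrum()]
#' @param radius_cm circle radius in cm^-1 (default 100)
#' @param height vertical semi-axis of the element in intensity units;
#'   default `diff(range(x))`
#' @return a `baseline_fit`
#' @export
rcf_baseline <- function(x, radius_cm = 100, height = NULL) {
  stopifnot(inherits(x, "raman_spectrum"))
  span <- x$grid$nu[x$grid$p] - x$grid$nu[1L]
  if (!is.numeric(radius_cm) || length(radius_cm) != 1L || radius_cm <= 0)
    stop("'radius_cm' must be a positive scalar", call. = FALSE)
  if (radius_cm > span / 2)
    stop("circle radius exceeds half the wavenumber span", call. = FALSE)
  r <- cm_to_channels(x$grid, radius_cm)
  v <- x$values
  if (is.null(height)) height <- diff(range(v))
  ker <- height * sqrt(pmax(0, 1 - (seq(-r, r) / r)^2))
  b <- ball_opening(v, ker, r)
  new_baseline_fit(x, b, "rcf",
                   extra = list(radius_channels = r, height = height))
}

# opening = erosion then dilation with structuring element ker (length 2r+1,
# centred); windows truncated at the edges
ball_opening <- function(v, ker, r) {
  p <- length(v)
  ero <- numeric(p)
  for (i in seq_len(p)) {
    lo <- max(1L, i - r); hi <- min(p, i + r)
    kk <- (lo - i + r + 1L):(hi - i + r + 1L)
    ero[i] <- min(v[lo:hi] - ker[kk])
  }
  dil <- numeric(p)
  for (i in seq_len(p)) {
    lo <- max(1L, i - r); hi <- min(p, i + r)
    kk <- (lo - i + r + 1L):(hi - i + r + 1L)
    dil[i] <- max(ero[lo:hi] + ker[kk])
  }
  dil
}
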