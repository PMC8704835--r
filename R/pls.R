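#' Penalized least-squares (Whittaker) baseline solver
#'
#' All three reweighted correctors (ALS, AirPLS, ArPLS) share one linear
#' solve: given per-channel weights w and a smoothness penalty lambda, the
#' baseline minimises
#' `(x - b)' W (x - b) + lambda * b' D'D b`
#' where D is the (p-2) x p second-difference matrix.  The minimiser solves
#' `(W + lambda D'D) b = W x`, a pentadiagonal system handled by a sparse
#' Cholesky factorisation.
#'
#' @param x numeric vector (measured intensities)
#' @param weights per-channel weights in \[0, 1\], not all zero
#' @param lambda positive smoothing coefficient
#' @return the baseline vector b
#' @examples
#' b <- pls_solve(c(0, 1, 0), rep(1, 3), 1)   # (2/7, 3/7, 2/7)
#' @export
pls_solve <- function(x, weights, lambda) {
  x <- as.numeric(x); w <- as.numeric(weights)
  p <- length(x)
  if (length(w) != p)
    stop("'weights' must have the same length as 'x'", call. = FALSE)
  if (p < 3)
    stop("need at least 3 channels", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("'lambda' must be a positive scalar", call. = FALSE)
  if (any(w < -1e-12) || any(w > 1 + 1e-12))
    stop("'weights' must lie in [0, 1]", call. = FALSE)
  if (all(w == 0))
    stop("all-zero weights give a singular system (D'D has rank p-2)",
         call. = FALSE)
  A <- Matrix::Diagonal(p, x = w) + lambda * penalty_matrix(p)
  as.numeric(Matrix::solve(A, w * x))
}

# (p-2) x p banded stencil [1, -2, 1]; annihilates constants and ramps
second_diff_matrix <- function(p) {
  ones <- rep(1, p - 2L)
  Matrix::bandSparse(p - 2L, p, k = 0:2,
                     diagonals = list(ones, -2 * ones, ones))
}

# D'D is rebuilt thousands of times in the reweighting loops; cache per p
.spb_cache <- new.env(parent = emptyenv())
penalty_matrix <- function(p) {
  key <- paste0("dtd", p)
  val <- get0(key, envir = .spb_cache)
  if (is.null(val)) {
    val <- Matrix::crossprod(second_diff_matrix(p))
    assign(key, val, envir = .spb_cache)
  }
  val
}

#' Asymmetric least squares (ALS) baseline
#'
#' Alternates the penalized solve with the asymmetric weight update:
#' channels at or above the current baseline (suspected Raman signal) get
#' weight `alpha`, channels below it get `1 - alpha`.  Iteration stops when
#' the boolean above/below pattern repeats (a history of depth 2 catches
#' 2-cycles) or at `max_iter`; non-convergence is flagged, not an error.
#'
#' @param x a [raman_spectrum()]
#' @param lambda smoothing coefficient (default 1000)
#' @param alpha asymmetry parameter; values between 1e-3 and 1e-1 are
#'   recommended (a warning is raised outside that band)
#' @param max_iter iteration cap
#' @return a `baseline_fit`
#' @export
als_baseline <- function(x, lambda = 1000, alpha = 0.01, max_iter = 50L) {
  stopifnot(inherits(x, "raman_spectrum"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 0.5)
    stop("'alpha' must lie in (0, 0.5)", call. = FALSE)
  if (alpha < 1e-3 || alpha > 1e-1)
    warning("'alpha' outside the recommended [1e-3, 1e-1] band", call. = FALSE)
  xv <- x$values; p <- length(xv)
  w <- rep(1, p)
  pattern_prev <- pattern_prev2 <- NULL
  b <- xv; converged <- FALSE; j <- 0L
  while (j < max_iter) {
    j <- j + 1L
    b <- pls_solve(xv, w, lambda)
    above <- xv >= b
    if (identical(above, pattern_prev) || identical(above, pattern_prev2)) {
      converged <- TRUE
      break
    }
    pattern_prev2 <- pattern_prev
    pattern_prev <- above
    w <- ifelse(above, alpha, 1 - alpha)
  }
  new_baseline_fit(x, b, "als", converged = converged, iterations = j,
                   extra = list(weights = w, lambda = lambda, alpha = alpha))
}

#' Adaptive iteratively reweighted penalized least squares (AirPLS) baseline
#'
#' Weight update at iteration j: channels at or above the baseline get
#' weight 0; channels below it get `exp(j * (x_i - b_i) / |d-|)` where
#' `|d-|` is the L1 norm of the negative residuals — always in (0, 1\].
#' Terminates when `||d-||_1 < 0.001 * ||x||_1`, when no channel lies below
#' the baseline, or at `max_iter`.
#'
#' @inheritParams als_baseline
#' @param lambda smoothing coefficient (default 50)
#' @export
airpls_baseline <- function(x, lambda = 50, max_iter = 50L) {
  stopifnot(inherits(x, "raman_spectrum"))
  xv <- x$values; p <- length(xv)
  w <- rep(1, p)
  b <- xv; converged <- FALSE; j <- 0L
  x_l1 <- sum(abs(xv))
  while (j < max_iter) {
    j <- j + 1L
    b <- pls_solve(xv, w, lambda)
    d <- xv - b
    neg <- d < 0
    dneg_l1 <- sum(-d[neg])
    if (!any(neg) || dneg_l1 < 0.001 * x_l1) {
      converged <- TRUE
      break
    }
    w <- numeric(p)
    w[neg] <- exp(j * d[neg] / dneg_l1)
    if (all(w == 0)) {      # underflow guard: nothing left to reweight
      converged <- TRUE
      break
    }
  }
  new_baseline_fit(x, b, "airpls", converged = converged, iterations = j,
                   extra = list(weights = w, lambda = lambda))
}

#' Asymmetrically reweighted penalized least squares (ArPLS) baseline
#'
#' Channels below the baseline keep weight 1; channels above it are
#' down-weighted by a logistic function of the residual, centred using the
#' mean and standard deviation of the negative residuals (an estimate of
#' the local noise level), so that noise-sized excursions above the
#' baseline are tolerated while genuine peaks are suppressed:
#' `w_i = 1 / (1 + exp(2 (d_i + m_d - 2 s_d) / s_d))` for `d_i >= 0`.
#' Iteration stops when the relative change of the weight vector falls
#' below `tol`.  The weighting scheme presumes noise: on (near) noise-free
#' input the negative-residual spread collapses, the logistic becomes a
#' hard step, and excluded edge channels make the baseline extrapolate
#' away from the data.  When the spread falls below `noise_floor` times
#' the intensity range the fit is therefore flagged degenerate, the
#' weights are replaced by the hard threshold `w_i = 1{x_i < b_i}`, and
#' the current (already essentially exact) baseline is returned.
#'
#' @inheritParams als_baseline
#' @param lambda smoothing coefficient (default 200)
#' @param tol relative weight-change tolerance
#' @param noise_floor fraction of the intensity range below which the
#'   negative-residual spread is treated as noiseless
#' @export
arpls_baseline <- function(x, lambda = 200, tol = 1e-6, max_iter = 100L,
                           noise_floor = 1e-3) {
  stopifnot(inherits(x, "raman_spectrum"))
  xv <- x$values; p <- length(xv)
  w <- rep(1, p)
  b <- xv; converged <- FALSE; degenerate <- FALSE; j <- 0L
  while (j < max_iter) {
    j <- j + 1L
    b <- pls_solve(xv, w, lambda)
    d <- xv - b
    dn <- d[d < 0]
    s <- if (length(dn) >= 2L) stats::sd(dn) else 0
    if (!is.finite(s) || s < 1e-12 * max(abs(xv)) ||
        s < noise_floor * diff(range(xv))) {
      # residuals below the baseline are (numerically) spread-free: the
      # logistic weights are undefined; substitute the hard threshold,
      # flag it, and stop — further reweighting cannot improve the fit
      degenerate <- TRUE
      converged <- TRUE
      w <- as.numeric(d < 0)
      break
    }
    m <- mean(dn)
    # plogis(-z) = 1/(1 + exp(z)), overflow-safe
    w_new <- ifelse(d < 0, 1, stats::plogis(-2 * (d + m - 2 * s) / s))
    if (sqrt(sum((w_new - w)^2)) < tol * sqrt(sum(w^2))) {
      w <- w_new
      converged <- TRUE
      break
    }
    w <- w_new
  }
  new_baseline_fit(x, b, "arpls", converged = converged, iterations = j,
                   extra = list(weights = w, lambda = lambda,
                                degenerate = degenerate))
}
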