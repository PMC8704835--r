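#' Root mean square modelling error (RMSME)
#'
#' After baseline correction, a spectrum should be explained by the known
#' subspace K = \[S, Kbg\] up to noise.  The modelling error is the residual
#' of the least-squares fit of the corrected spectrum on K, and the RMSME
#' is its root mean square: `sqrt(mean(n_i^2))` with `n = x' - K yhat`.
#' A corrector that removes the baseline without distorting the Raman
#' signature drives the RMSME down to the noise floor.
#'
#' @param x_corrected a [raman_spectrum()] (already baseline-corrected, or
#'   raw for the "no correction" reference point)
#' @param refs a [reference_library()]
#' @param bg a [background_basis()]
#' @param cond_threshold condition-number limit for K
#' @return a list with `rmsme`, the residual vector `modeling_error` and
#'   the fitted coefficients `y_hat`
#' @export
rmsme <- function(x_corrected, refs, bg, cond_threshold = 1e10) {
  stopifnot(inherits(x_corrected, "raman_spectrum"),
            inherits(refs, "reference_library"),
            inherits(bg, "background_basis"))
  check_grid(x_corrected$grid, refs$grid, "reference library")
  check_grid(x_corrected$grid, bg$grid, "background basis")
  K <- cbind(refs$S, bg$K)
  sv <- svd(K, nu = 0, nv = 0)$d
  if (sv[length(sv)] == 0 || sv[1L] / sv[length(sv)] > cond_threshold)
    stop("K = [S, Kbg] is rank deficient", call. = FALSE)
  qrK <- qr(K)
  y_hat <- qr.coef(qrK, x_corrected$values)
  n <- as.numeric(qr.resid(qrK, x_corrected$values))
  list(rmsme = sqrt(mean(n^2)), modeling_error = n, y_hat = y_hat)
}

#' Adaptive subspace detector (ASD) statistic
#'
#' GLRT statistic for the presence of a target signature in a corrected
#' spectrum: the energy of x' outside the background subspace Kbg, minus
#' its energy outside the full subspace K = \[S, Kbg\], normalised by the
#' latter:
#' `T = (x' P_bg_perp x' - x' P_K_perp x') / (x' P_K_perp x')`.
#' Because span(Kbg) is nested in span(K), T is always nonnegative, and it
#' is invariant to rescaling of x'.  The projections are applied through QR
#' factorisations; no p x p projector is materialised.
#'
#' @inheritParams rmsme
#' @param beta detection threshold; the target is declared present when
#'   `T > beta`
#' @param noise optional [noise_model()]; pre-scales the spectrum and both
#'   matrices by 1/sigma_i (whitening) before forming the statistic
#' @return a list with `statistic`, `threshold`, `decision`
#'   (`"agent_present"` or `"agent_absent"`) and `in_span` (TRUE when x'
#'   lies in span(K) so the denominator vanished and the statistic is Inf)
#' @export
asd_statistic <- function(x_corrected, refs, bg, beta = 1, noise = NULL,
                          cond_threshold = 1e10) {
  stopifnot(inherits(x_corrected, "raman_spectrum"),
            inherits(refs, "reference_library"),
            inherits(bg, "background_basis"))
  check_grid(x_corrected$grid, refs$grid, "reference library")
  check_grid(x_corrected$grid, bg$grid, "background basis")
  xv <- x_corrected$values
  if (all(xv == 0)) stop("x' is identically zero", call. = FALSE)
  S <- refs$S; Kbg <- bg$K
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_model"))
    w <- 1 / sqrt(noise$sigma_sq)
    xv <- xv * w; S <- S * w; Kbg <- Kbg * w
  }
  K <- cbind(S, Kbg)
  sv <- svd(K, nu = 0, nv = 0)$d
  if (sv[length(sv)] == 0 || sv[1L] / sv[length(sv)] > cond_threshold)
    stop("K = [S, Kbg] is rank deficient", call. = FALSE)
  rK <- qr.resid(qr(K), xv)
  rbg <- qr.resid(qr(Kbg), xv)
  den <- sum(rK^2)
  num <- sum(rbg^2) - den
  if (den <= .Machine$double.eps * sum(xv^2)) {
    t_stat <- Inf
    in_span <- TRUE
  } else {
    t_stat <- max(0, num) / den   # clamp roundoff on nested projections
    in_span <- FALSE
  }
  list(statistic = t_stat, threshold = beta,
       decision = if (t_stat > beta) "agent_present" else "agent_absent",
       in_span = in_span)
}

#' ROC curve from two sets of detection statistics
#'
#' Sweeps the threshold over the pooled unique statistic values; at each
#' threshold the false-alarm probability is the fraction of null (H0)
#' statistics strictly greater than it and the detection probability the
#' corresponding fraction of alternative (H1) statistics.  The curve is
#' anchored at (0,0) and (1,1) and the AUC computed by the trapezoid rule.
#'
#' @param stats_h1 statistics from scenes with the target present
#' @param stats_h0 statistics from target-free scenes
#' @return an object of class `roc_curve`: data frame `points` with
#'   columns `p_fa`, `p_d`, and scalar `auc`
#' @export
roc_curve <- function(stats_h1, stats_h0) {
  stats_h1 <- as.numeric(stats_h1); stats_h0 <- as.numeric(stats_h0)
  if (length(stats_h1) == 0L || length(stats_h0) == 0L)
    stop("both H1 and H0 statistic sets must be non-empty", call. = FALSE)
  thr <- sort(unique(c(stats_h1, stats_h0)), decreasing = TRUE)
  p_fa <- vapply(thr, function(b) mean(stats_h0 > b), numeric(1L))
  p_d <- vapply(thr, function(b) mean(stats_h1 > b), numeric(1L))
  pts <- data.frame(p_fa = c(0, p_fa, 1), p_d = c(0, p_d, 1))
  pts <- pts[order(pts$p_fa, pts$p_d), ]
  auc <- sum(diff(pts$p_fa) * (utils::head(pts$p_d, -1) + utils::tail(pts$p_d, -1)) / 2)
  structure(list(points = pts, auc = auc,
                 n_h1 = length(stats_h1), n_h0 = length(stats_h0)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d H1 + %d H0 statistics, AUC = %.4f\n",
              x$n_h1, x$n_h0, x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ..., add = FALSE, col = "black") {
  if (!add) {
    graphics::plot(x$points$p_fa, x$points$p_d, type = "l", col = col,
                   xlab = "False alarm probability",
                   ylab = "Detection probability",
                   xlim = c(0, 1), ylim = c(0, 1), ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
  } else {
    graphics::lines(x$points$p_fa, x$points$p_d, col = col, ...)
  }
  invisible(x)
}
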