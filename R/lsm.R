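#' Joint subspace baseline correction (the LSM corrector)
#'
#' Models the measured spectrum as
#' `x = S g + Kbg ybg + Kbl ybl + n`
#' where S holds reference analyte spectra, Kbg a background basis, and Kbl
#' broad Gaussian vectors spanning smooth baselines.  All coefficients are
#' estimated jointly by least squares, the baseline is `b = Kbl ybl`, and
#' the corrected spectrum is `x - b`.  Because signal and baseline are
#' estimated simultaneously, the Raman signature is not smoothed away the
#' way curvature-based correctors can do at low signal-to-noise ratio.
#'
#' The solve uses a QR factorisation of the augmented matrix
#' `K' = [S, Kbg, Kbl]` (never the explicit normal-equations inverse, which
#' squares the condition number).  The claimed linear independence of the
#' blocks is verified: if the condition number of K' exceeds
#' `cond_threshold` the fit aborts with a diagnostic naming the blocks.
#'
#' @param x a [raman_spectrum()]
#' @param refs a [reference_library()] (matrix S, p x C)
#' @param bg a [background_basis()] (matrix Kbg, p x M)
#' @param basis a [build_gaussian_basis()] object (matrix Kbl, p x L)
#' @param noise optional [noise_model()]; when supplied the fit becomes
#'   generalized least squares (rows pre-scaled by 1/sigma_i).  Default is
#'   ordinary least squares.
#' @param cond_threshold condition-number limit above which the augmented
#'   model is declared degenerate
#' @return an object of classes `lsm_fit` and `baseline_fit` with the
#'   coefficient partition (`g`, `ybg`, `ybl`), the estimated baseline,
#'   the corrected spectrum, the residual norm and the condition number
#' @examples
#' g <- make_grid(0, 100, 101)
#' refs <- reference_library(g, matrix(exp(-(g$nu - 40)^2 / 18), ncol = 1))
#' bg <- background_basis(g, matrix(exp(-(g$nu - 70)^2 / 8), ncol = 1))
#' kb <- build_gaussian_basis(g, 4)
#' x <- raman_spectrum(g, 2 * refs$S[, 1] + bg$K[, 1] + 5 + 0.02 * g$nu)
#' fit <- fit_lsm_baseline(x, refs, bg, kb)
#' coef(fit)$g   # close to 2
#' @export
fit_lsm_baseline <- function(x, refs, bg, basis, noise = NULL,
                             cond_threshold = 1e10) {
  stopifnot(inherits(x, "raman_spectrum"), inherits(refs, "reference_library"),
            inherits(bg, "background_basis"), inherits(basis, "gaussian_basis"))
  check_grid(x$grid, refs$grid, "reference library")
  check_grid(x$grid, bg$grid, "background basis")
  check_grid(x$grid, basis$grid, "Gaussian basis")
  model <- augmented_model(refs, bg, basis, noise = noise,
                           cond_threshold = cond_threshold)
  lsm_solve_one(x, model, keep_model = TRUE)
}

# Prefactorized augmented model, reusable across a batch.
# When a noise model is given, a whitened copy of K' is factorized and the
# spectrum is whitened before solving (generalized least squares); the
# baseline is still reported in the original units.
augmented_model <- function(refs, bg, basis, noise = NULL,
                            cond_threshold = 1e10) {
  check_grid(refs$grid, bg$grid, "background basis")
  check_grid(refs$grid, basis$grid, "Gaussian basis")
  C <- ncol(refs$S); M <- ncol(bg$K); L <- basis$L
  p <- refs$grid$p
  if (C + M + L >= p)
    stop("augmented model has as many columns as channels (C+M+L >= p)",
         call. = FALSE)
  Kprime <- cbind(refs$S, bg$K, basis$K)
  scale_w <- NULL
  Kfit <- Kprime
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_model"))
    if (length(noise$sigma_sq) != p)
      stop("noise model length does not match the grid", call. = FALSE)
    scale_w <- 1 / sqrt(noise$sigma_sq)
    Kfit <- Kprime * scale_w
  }
  sv <- svd(Kfit, nu = 0, nv = 0)$d
  cond <- sv[1L] / sv[length(sv)]
  if (!is.finite(cond) || cond > cond_threshold)
    stop(sprintf(paste0("augmented model [S (C=%d) | Kbg (M=%d) | Kbl (L=%d)] ",
                        "is degenerate: condition number %.3g exceeds %.3g; ",
                        "a background basis vector may resemble a broad Gaussian"),
                 C, M, L, cond, cond_threshold), call. = FALSE)
  list(grid = refs$grid, refs = refs, bg = bg, basis = basis,
       Kprime = Kprime, qr = qr(Kfit), scale_w = scale_w,
       C = C, M = M, L = L, cond = cond)
}

lsm_solve_one <- function(x, model, keep_model = FALSE) {
  xv <- if (is.null(model$scale_w)) x$values else x$values * model$scale_w
  yprime <- qr.coef(model$qr, xv)
  idx <- model$C + model$M
  ybl <- yprime[(idx + 1L):(idx + model$L)]
  b <- as.numeric(model$basis$K %*% ybl)
  fitted_vals <- as.numeric(model$Kprime %*% yprime)
  res <- x$values - fitted_vals
  fit <- new_baseline_fit(
    x, b, "lsm",
    subclass = "lsm_fit",
    extra = list(
      coefficients = list(
        g = stats::setNames(yprime[seq_len(model$C)], colnames(model$refs$S)),
        ybg = yprime[model$C + seq_len(model$M)],
        ybl = ybl),
      yprime = yprime,
      model_fit = fitted_vals,
      residual_norm = sqrt(sum(res^2)),
      condition_number = model$cond,
      L = model$L))
  if (keep_model) attr(fit, "model") <- model
  fit
}

#' @export
coef.lsm_fit <- function(object, ...) object$coefficients

#' @export
print.lsm_fit <- function(x, ...) {
  cat("Joint subspace (LSM) baseline fit\n")
  cat(sprintf("  model: C = %d references, M = %d background bases, L = %d Gaussians\n",
              length(x$coefficients$g), length(x$coefficients$ybg),
              length(x$coefficients$ybl)))
  cat(sprintf("  condition number of K': %.3g\n", x$condition_number))
  cat(sprintf("  residual norm: %.4g\n", x$residual_norm))
  g <- x$coefficients$g
  cat("  reference intensities g:\n")
  print(signif(g, 4))
  invisible(x)
}

#' Apply a fitted LSM model to new spectra
#'
#' The model matrices and their factorisation are reused; each new spectrum
#' gets its own coefficient estimate and baseline.
#'
#' @param object an `lsm_fit` returned by [fit_lsm_baseline()]
#' @param newdata a [raman_spectrum()] or a list of them
#' @param ... unused
#' @return an `lsm_fit` (or a list of them) for the new spectra
#' @export
predict.lsm_fit <- function(object, newdata, ...) {
  model <- attr(object, "model")
  if (is.null(model))
    stop("this fit does not carry its model matrices; refit with fit_lsm_baseline() or use correct_batch()",
         call. = FALSE)
  if (inherits(newdata, "raman_spectrum")) {
    check_grid(model$grid, newdata$grid, "new spectrum")
    return(lsm_solve_one(newdata, model))
  }
  lapply(newdata, function(s) {
    check_grid(model$grid, s$grid, sprintf("spectrum '%s'", s$label))
    lsm_solve_one(s, model)
  })
}

#' Simulate spectra from a fitted LSM model
#'
#' Draws `nsim` spectra as the fitted model spectrum `K' yhat'` plus white
#' Gaussian noise at the fit's residual scale.
#'
#' @param object an `lsm_fit`
#' @param nsim number of spectra
#' @param seed optional RNG seed
#' @param ... unused
#' @return a list of [raman_spectrum()] objects
#' @export
simulate.lsm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  p <- object$spectrum$grid$p
  sd_hat <- object$residual_norm / sqrt(p)
  lapply(seq_len(nsim), function(i)
    raman_spectrum(object$spectrum$grid,
                   object$model_fit + stats::rnorm(p, 0, sd_hat),
                   label = sprintf("sim%d", i)))
}

#' Correct a batch of spectra with one factorisation
#'
#' The augmented model `K' = [S, Kbg, Kbl]` is factorised once and reused
#' for every spectrum.  Per-spectrum failures are collected and re-raised
#' with the spectrum's label.
#'
#' @inheritParams fit_lsm_baseline
#' @param spectra a list of [raman_spectrum()] objects
#' @return a list of `lsm_fit` objects
#' @export
correct_batch <- function(spectra, refs, bg, basis, noise = NULL,
                          cond_threshold = 1e10) {
  if (inherits(spectra, "raman_spectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) > 0L)
  model <- augmented_model(refs, bg, basis, noise = noise,
                           cond_threshold = cond_threshold)
  lapply(spectra, function(s) {
    check_grid(model$grid, s$grid,
               sprintf("spectrum '%s'", s$label))
    tryCatch(lsm_solve_one(s, model),
             error = function(e)
               stop(sprintf("spectrum '%s': %s", s$label, conditionMessage(e)),
                    call. = FALSE))
  })
}
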