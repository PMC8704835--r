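#' Apply a named baseline corrector to one spectrum
#'
#' Dispatch helper shared by the evaluation loop and the command-line
#' interface.  `"none"` returns the spectrum uncorrected (the reference
#' point every corrector is compared against); `"lsm"` needs the reference
#' library, background basis and Gaussian basis.
#'
#' @param x a [raman_spectrum()]
#' @param method one of `"none"`, `"imf"`, `"rcf"`, `"als"`, `"airpls"`,
#'   `"arpls"`, `"lsm"`
#' @param refs,bg,basis model matrices (required for `"lsm"`)
#' @param params named list of method parameters overriding the defaults
#' @return a `baseline_fit`
#' @export
apply_corrector <- function(x, method, refs = NULL, bg = NULL, basis = NULL,
                            params = list()) {
  method <- match.arg(method, c("none", "imf", "rcf", "als", "airpls",
                                "arpls", "lsm"))
  call_with <- function(f, ...) do.call(f, c(list(x), params, list(...)))
  switch(method,
         none = identity_corrector(x),
         imf = call_with(imf_baseline),
         rcf = call_with(rcf_baseline),
         als = call_with(als_baseline),
         airpls = call_with(airpls_baseline),
         arpls = call_with(arpls_baseline),
         lsm = {
           if (is.null(refs) || is.null(bg) || is.null(basis))
             stop("'lsm' needs refs, bg and basis", call. = FALSE)
           do.call(fit_lsm_baseline,
                   c(list(x, refs, bg, basis), params))
         })
}

# batched RMSME and ASD statistics on a p x n matrix of corrected spectra;
# factorizations shared across columns (identical to the per-spectrum
# rmsme()/asd_statistic() definitions)
batch_metrics <- function(X, refs, bg) {
  K <- cbind(refs$S, bg$K)
  qrK <- qr(K)
  qrBg <- qr(bg$K)
  rK <- qr.resid(qrK, X)
  rBg <- qr.resid(qrBg, X)
  den <- colSums(rK^2)
  t_stat <- pmax(0, colSums(rBg^2) - den) / den
  list(rmsme = sqrt(colMeans(rK^2)), t = t_stat)
}

collect_corrected <- function(scenes, method, study, basis, params = list()) {
  xs <- lapply(scenes, function(sc) sc$x)
  if (method == "lsm") {
    fits <- correct_batch(xs, study$refs, study$bg, basis)
  } else {
    fits <- lapply(xs, apply_corrector, method = method, params = params)
  }
  vapply(fits, residuals, numeric(study$refs$grid$p))
}

#' Benchmark baseline correctors on a synthetic study
#'
#' For every requested corrector: correct all scenes, compute the mean
#' RMSME separately over target (H1) and target-free (H0) scenes, run the
#' adaptive subspace detector on the corrected spectra and report the ROC
#' area under the curve, plus the wall-clock time spent.
#'
#' @param study a [simulate_study()] result
#' @param methods correctors to evaluate (always include `"none"` to see
#'   the uncorrected reference point)
#' @param L number of broad Gaussian vectors for the `"lsm"` corrector
#' @param params optional named list: per-method parameter lists, e.g.
#'   `list(als = list(lambda = 500))`
#' @return a data frame with one row per method: `method`, `rmsme_h1`,
#'   `rmsme_h0`, `auc`, `seconds`
#' @export
evaluate_correctors <- function(study,
                                methods = c("none", "imf", "rcf", "als",
                                            "airpls", "arpls", "lsm"),
                                L = 11L, params = list()) {
  basis <- build_gaussian_basis(study$refs$grid, L)
  n1 <- length(study$h1)
  rows <- lapply(methods, function(m) {
    tm <- system.time({
      X <- collect_corrected(c(study$h1, study$h0), m, study, basis,
                             params = params[[m]] %||% list())
      met <- batch_metrics(X, study$refs, study$bg)
      roc <- roc_curve(met$t[seq_len(n1)], met$t[-seq_len(n1)])
    })
    data.frame(method = m,
               rmsme_h1 = mean(met$rmsme[seq_len(n1)]),
               rmsme_h0 = mean(met$rmsme[-seq_len(n1)]),
               auc = roc$auc,
               seconds = unname(tm["elapsed"]))
  })
  do.call(rbind, rows)
}

#' Sweep the number of broad Gaussian vectors
#'
#' Runs the subspace corrector at each requested L and reports mean RMSME
#' over H1 and H0 scenes; the row minimising the overall mean is flagged.
#'
#' @param study a [simulate_study()] result
#' @param L_values numbers of Gaussian vectors to try (each at least 2)
#' @return a data frame with columns `L`, `rmsme_h1`, `rmsme_h0`,
#'   `rmsme_mean`, `is_min`
#' @export
sweep_gaussian_count <- function(study, L_values = c(5L, 11L, 30L)) {
  if (any(L_values < 2)) stop("every L must be at least 2", call. = FALSE)
  n1 <- length(study$h1)
  rows <- lapply(L_values, function(L) {
    basis <- suppressWarnings(build_gaussian_basis(study$refs$grid, L))
    X <- collect_corrected(c(study$h1, study$h0), "lsm", study, basis)
    met <- batch_metrics(X, study$refs, study$bg)
    r1 <- mean(met$rmsme[seq_len(n1)]); r0 <- mean(met$rmsme[-seq_len(n1)])
    data.frame(L = L, rmsme_h1 = r1, rmsme_h0 = r0,
               rmsme_mean = mean(met$rmsme))
  })
  out <- do.call(rbind, rows)
  out$is_min <- seq_len(nrow(out)) == which.min(out$rmsme_mean)
  out
}
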