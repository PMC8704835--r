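# Common result class for every baseline corrector.  `corrected + baseline`
# reconstructs the input exactly by construction.

new_baseline_fit <- function(x, baseline_values, method, converged = TRUE,
                             iterations = NA_integer_, subclass = character(),
                             extra = list()) {
  stopifnot(inherits(x, "raman_spectrum"))
  baseline <- raman_spectrum(x$grid, baseline_values,
                             label = paste0(x$label, " baseline"))
  corrected <- raman_spectrum(x$grid, x$values - baseline_values,
                              label = paste0(x$label, " corrected"))
  structure(c(list(spectrum = x, baseline = baseline, corrected = corrected,
                   method = method, converged = converged,
                   iterations = iterations), extra),
            class = c(subclass, "baseline_fit"))
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("Baseline fit (method: %s)\n", x$method))
  cat(sprintf("  %d channels, %g to %g cm^-1\n", x$spectrum$grid$p,
              x$spectrum$grid$nu[1L], x$spectrum$grid$nu[x$spectrum$grid$p]))
  if (!is.na(x$iterations))
    cat(sprintf("  iterations: %d (converged: %s)\n", x$iterations, x$converged))
  cat(sprintf("  baseline range [%.4g, %.4g]\n",
              min(x$baseline$values), max(x$baseline$values)))
  invisible(x)
}

#' @export
summary.baseline_fit <- function(object, ...) {
  b <- object$baseline$values; xv <- object$spectrum$values
  out <- list(method = object$method,
              p = object$spectrum$grid$p,
              converged = object$converged,
              iterations = object$iterations,
              baseline_range = range(b),
              baseline_fraction = sum(b^2) / max(sum(xv^2), .Machine$double.eps),
              corrected_range = range(object$corrected$values))
  class(out) <- "summary.baseline_fit"
  out
}

#' @export
print.summary.baseline_fit <- function(x, ...) {
  cat(sprintf("Baseline correction summary (method: %s)\n", x$method))
  cat(sprintf("  channels: %d; converged: %s", x$p, x$converged))
  if (!is.na(x$iterations)) cat(sprintf(" after %d iterations", x$iterations))
  cat("\n")
  cat(sprintf("  baseline range:  [%.4g, %.4g]\n",
              x$baseline_range[1L], x$baseline_range[2L]))
  cat(sprintf("  corrected range: [%.4g, %.4g]\n",
              x$corrected_range[1L], x$corrected_range[2L]))
  cat(sprintf("  baseline energy fraction: %.3f\n", x$baseline_fraction))
  invisible(x)
}

#' Extract the estimated baseline from a fit
#' @param object a `baseline_fit`
#' @param ... unused
#' @return numeric vector of baseline values
#' @export
fitted.baseline_fit <- function(object, ...) object$baseline$values

#' Extract the corrected spectrum (input minus baseline)
#' @inheritParams fitted.baseline_fit
#' @export
residuals.baseline_fit <- function(object, ...) object$corrected$values

#' @export
plot.baseline_fit <- function(x, ..., legend_pos = "topright") {
  nu <- x$spectrum$grid$nu
  ylim <- range(x$spectrum$values, x$baseline$values, x$corrected$values)
  graphics::plot(nu, x$spectrum$values, type = "l", col = "grey40",
                 xlab = expression(paste("Raman shift (", cm^-1, ")")),
                 ylab = "Intensity", ylim = ylim,
                 main = sprintf("Baseline correction (%s)", x$method), ...)
  graphics::lines(nu, x$baseline$values, col = "red", lwd = 2)
  graphics::lines(nu, x$corrected$values, col = "blue")
  graphics::legend(legend_pos, legend = c("measured", "baseline", "corrected"),
                   col = c("grey40", "red", "blue"), lty = 1, bty = "n")
  invisible(x)
}
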