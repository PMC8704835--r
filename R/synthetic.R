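#' Synthetic Raman scenes
#'
#' Seeded generator of ground-truth scenes with the additive structure
#' `x = t + b + n`, `t = S g + Kbg ybg`: narrow Raman peaks from a
#' reference library, background-material structure, a smooth baseline and
#' heteroscedastic Gaussian noise.  It stands in for instrument data when
#' benchmarking correctors: every component of each scene is stored, so
#' recovery can be checked against the truth.
#'
#' @name synthetic
NULL

# set.seed locally, restoring the caller's RNG state when the calling
# function exits (the restore expression is registered in the caller frame)
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  old <- get0(".Random.seed", envir = globalenv())
  restore <- if (is.null(old)) {
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = envir)
  set.seed(seed)
  invisible(NULL)
}

#' Describe one Raman peak
#'
#' @param center peak position in cm^-1
#' @param width_fwhm full width at half maximum in cm^-1 (Raman peaks are
#'   narrower than 350 cm^-1; wider values trigger a warning)
#' @param height peak height
#' @param shape `"gaussian"` or `"lorentzian"`
#' @export
peak_spec <- function(center, width_fwhm, height = 1,
                      shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  if (width_fwhm <= 0 || height <= 0)
    stop("'width_fwhm' and 'height' must be positive", call. = FALSE)
  if (width_fwhm >= 350)
    warning("peak FWHM of 350 cm^-1 or more is wider than real Raman peaks",
            call. = FALSE)
  structure(list(center = center, width_fwhm = width_fwhm, height = height,
                 shape = shape), class = "peak_spec")
}

eval_peak <- function(peak, nu) {
  u <- nu - peak$center
  switch(peak$shape,
         gaussian = peak$height * exp(-4 * log(2) * u^2 / peak$width_fwhm^2),
         lorentzian = peak$height / (1 + (2 * u / peak$width_fwhm)^2))
}

#' Synthesize a reference spectrum from a list of peaks
#'
#' Peak profiles are summed on the grid and the result normalised to a
#' maximum of 1 (reference libraries store shapes; intensities live in the
#' coefficient vector g).
#'
#' @param grid a [make_grid()] axis
#' @param peaks list of [peak_spec()] objects (at least one), all centred
#'   inside the grid
#' @return a [raman_spectrum()]
#' @export
simulate_reference <- function(grid, peaks) {
  stopifnot(inherits(grid, "wn_grid"))
  if (inherits(peaks, "peak_spec")) peaks <- list(peaks)
  if (length(peaks) == 0L) stop("need at least one peak", call. = FALSE)
  lo <- grid$nu[1L]; hi <- grid$nu[grid$p]
  v <- numeric(grid$p)
  for (pk in peaks) {
    stopifnot(inherits(pk, "peak_spec"))
    if (pk$center < lo || pk$center > hi)
      stop(sprintf("peak center %g cm^-1 is outside the grid", pk$center),
           call. = FALSE)
    v <- v + eval_peak(pk, grid$nu)
  }
  raman_spectrum(grid, v / max(v))
}

#' Synthesize a smooth baseline
#'
#' Four families are available.  `"broad_gauss_mix"` lies exactly in the
#' span of the broad Gaussian basis (useful for exact-recovery checks);
#' `"poly"`, `"sigmoid"` and `"exp_decay"` lie outside it, exercising the
#' robustness of the subspace corrector.  When `params` are omitted they
#' are drawn from the seeded RNG at the given `amplitude` scale.
#'
#' @param grid a [make_grid()] axis
#' @param family one of `"poly"`, `"sigmoid"`, `"broad_gauss_mix"`,
#'   `"exp_decay"`
#' @param params family parameters:
#'   * poly: `coef`, polynomial coefficients (ascending powers) in the
#'     scaled coordinate u = (nu - nu_1)/(nu_p - nu_1)
#'   * sigmoid: `a` (amplitude), `center`, `scale` (cm^-1), `offset`
#'   * broad_gauss_mix: `L` (default 11) and nonnegative `coef` (length L)
#'   * exp_decay: `a`, `tau` (cm^-1), `offset`
#' @param amplitude intensity scale used when drawing random parameters
#' @param seed optional RNG seed
#' @return a [raman_spectrum()]; always nonnegative
#' @export
simulate_baseline <- function(grid,
                              family = c("poly", "sigmoid", "broad_gauss_mix",
                                         "exp_decay"),
                              params = list(), amplitude = 1, seed = NULL) {
  stopifnot(inherits(grid, "wn_grid"))
  family <- match.arg(family)
  local_seed(seed)
  nu <- grid$nu
  u <- (nu - nu[1L]) / (nu[grid$p] - nu[1L])
  v <- switch(family,
    poly = {
      cf <- params$coef
      if (is.null(cf)) {
        cf <- amplitude * c(stats::runif(1, 0.4, 1), stats::runif(1, -0.8, 0.8),
                            stats::runif(1, -0.6, 0.6))
        base <- drop(outer(u, seq_along(cf) - 1, "^") %*% cf)
        base <- base - min(base) + 0.1 * amplitude   # keep positive
        base
      } else {
        drop(outer(u, seq_along(cf) - 1, "^") %*% cf)
      }
    },
    sigmoid = {
      a <- params$a %||% amplitude * stats::runif(1, 0.5, 1)
      ctr <- params$center %||% stats::runif(1, nu[1L], nu[grid$p])
      sc <- params$scale %||% stats::runif(1, 200, 800)
      off <- params$offset %||% 0.1 * amplitude
      if (a < 0 || off < 0) stop("negative amplitude", call. = FALSE)
      a / (1 + exp(-(nu - ctr) / sc)) + off
    },
    broad_gauss_mix = {
      L <- params$L %||% 11L
      cf <- params$coef %||% (amplitude * stats::runif(L, 0.1, 1))
      if (length(cf) != L) stop("'coef' must have length L", call. = FALSE)
      if (any(cf < 0)) stop("negative amplitude", call. = FALSE)
      kb <- build_gaussian_basis(grid, L)
      drop(kb$K %*% cf)
    },
    exp_decay = {
      a <- params$a %||% amplitude * stats::runif(1, 0.5, 1)
      tau <- params$tau %||% stats::runif(1, 500, 2000)
      off <- params$offset %||% 0.1 * amplitude
      if (a < 0 || off < 0) stop("negative amplitude", call. = FALSE)
      a * exp(-(nu - nu[1L]) / tau) + off
    })
  if (any(v < 0))
    stop("baseline parameters produce negative values", call. = FALSE)
  raman_spectrum(grid, v, label = family)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default heteroscedastic noise profile
#'
#' Per-channel variances follow a smooth positive profile, larger at the
#' low-wavenumber end where fluorescence (and hence shot noise) is
#' strongest, normalised to median 1 so that `gamma` sets the median
#' per-channel variance directly.
#'
#' @param grid a [make_grid()] axis
#' @param gamma overall variance scale
#' @return a [noise_model()]
#' @export
default_noise_model <- function(grid, gamma = 1) {
  prof <- 1 + 0.75 * exp(-(grid$nu - grid$nu[1L]) / 1000)
  noise_model(prof / stats::median(prof), gamma = gamma)
}

#' Compose one synthetic scene
#'
#' `x = S g + Kbg ybg + b + n` with `n ~ N(0, gamma * Sigma)` drawn
#' channel-wise.  Every component is stored so the construction identity
#' holds exactly.
#'
#' @param refs a [reference_library()]
#' @param g reference intensity vector (length C; zero for target-free
#'   scenes)
#' @param bg a [background_basis()]
#' @param y_bg background coefficient vector (length M)
#' @param baseline a [raman_spectrum()] (the true baseline b)
#' @param noise a [noise_model()]
#' @param seed optional RNG seed (omit to draw from the current stream)
#' @return an object of class `synthetic_scene` with fields `x`, `t`, `b`,
#'   `n`, `g`, `y_bg`, `seed`
#' @export
simulate_scene <- function(refs, g, bg, y_bg, baseline, noise, seed = NULL) {
  stopifnot(inherits(refs, "reference_library"),
            inherits(bg, "background_basis"),
            inherits(baseline, "raman_spectrum"),
            inherits(noise, "noise_model"))
  grid <- refs$grid
  check_grid(grid, bg$grid, "background basis")
  check_grid(grid, baseline$grid, "baseline")
  if (length(g) != ncol(refs$S))
    stop("'g' must have one coefficient per reference spectrum", call. = FALSE)
  if (length(y_bg) != ncol(bg$K))
    stop("'y_bg' must have one coefficient per background basis vector",
         call. = FALSE)
  if (length(noise$sigma_sq) != grid$p)
    stop("noise model length does not match the grid", call. = FALSE)
  local_seed(seed)
  t_vals <- drop(refs$S %*% g + bg$K %*% y_bg)
  n_vals <- stats::rnorm(grid$p, 0, sqrt(noise$gamma * noise$sigma_sq))
  x_vals <- t_vals + baseline$values + n_vals
  structure(list(x = raman_spectrum(grid, x_vals),
                 t = raman_spectrum(grid, t_vals),
                 b = baseline,
                 n = raman_spectrum(grid, n_vals),
                 g = g, y_bg = y_bg, seed = seed),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("Synthetic scene: %d channels; target %s; baseline family '%s'\n",
              x$x$grid$p, if (any(x$g > 0)) "present" else "absent",
              x$b$label))
  invisible(x)
}

#' Built-in reference library of synthetic analytes
#'
#' Seven synthetic analyte signatures built from fixed peak tables.  The
#' first ("target") follows the canonical layout of an organophosphorus
#' agent spectrum: a dominant C-H stretch near 2700-3100 cm^-1 and several
#' subpeaks between 500 and 1700 cm^-1.  The rest provide distinct
#' distractor signatures so that the reference matrix S has C = 7 columns.
#'
#' @param grid a [make_grid()] axis
#' @return a [reference_library()]
#' @export
default_reference_library <- function(grid) {
  mk <- function(tab) {
    simulate_reference(grid, lapply(seq_len(nrow(tab)), function(i)
      peak_spec(tab[i, 1], tab[i, 2], tab[i, 3],
                shape = if (tab[i, 4] == 1) "gaussian" else "lorentzian")))
  }
  # columns: center, fwhm, height, shape (1 gaussian / 2 lorentzian)
  tabs <- list(
    target = rbind(c(2930, 60, 1.0, 1), c(2880, 45, 0.55, 1),
                   c(720, 25, 0.25, 2), c(840, 30, 0.20, 1),
                   c(1015, 22, 0.30, 2), c(1270, 35, 0.15, 1),
                   c(1450, 40, 0.18, 1), c(1660, 30, 0.10, 2)),
    agentB = rbind(c(2850, 55, 1.0, 1), c(705, 28, 0.45, 2),
                   c(1130, 30, 0.35, 1), c(1390, 35, 0.25, 1)),
    agentC = rbind(c(520, 30, 1.0, 2), c(650, 25, 0.6, 2),
                   c(980, 28, 0.4, 1), c(1610, 40, 0.3, 1)),
    agentD = rbind(c(1340, 45, 1.0, 1), c(1590, 45, 0.8, 1),
                   c(2980, 60, 0.5, 1)),
    agentE = rbind(c(800, 26, 1.0, 2), c(1080, 30, 0.7, 2),
                   c(2210, 35, 0.45, 1)),
    agentF = rbind(c(620, 22, 1.0, 2), c(740, 24, 0.8, 2),
                   c(880, 26, 0.5, 2), c(3050, 70, 0.35, 1)),
    agentG = rbind(c(1001, 18, 1.0, 2), c(1030, 20, 0.5, 2),
                   c(1600, 35, 0.6, 1), c(3060, 55, 0.55, 1)))
  S <- vapply(tabs, function(tb) mk(tb)$values, numeric(grid$p))
  reference_library(grid, S, names = names(tabs))
}

# Background truth process: heterogeneous substrate bands plus atmospheric
# O2/N2 lines.  Substrate materials (concrete, asphalt, soil) vary
# spot-to-spot, so every draw jitters band centers (sd 15 cm^-1), widths
# (+/- 20%) and heights (+/- 40%); the atmospheric lines are stable in
# position (sd 1 cm^-1) with +/- 30% intensity.  Draws use the current RNG
# stream.  Returns a nonnegative vector with unit-height scale.
.substrate_bands <- list(
  rbind(c(480, 180, 1.0, 1), c(1000, 250, 0.8, 1), c(1450, 200, 0.5, 1)),
  rbind(c(700, 220, 1.0, 1), c(1300, 280, 0.7, 1), c(2900, 150, 0.4, 1)),
  rbind(c(560, 120, 1.0, 2), c(1100, 160, 0.6, 2), c(1980, 200, 0.3, 1)))
.gas_lines <- rbind(c(1556, 20, 0.9, 1), c(2331, 18, 1.0, 1))   # O2, N2

background_truth <- function(grid) {
  v <- numeric(grid$p)
  mix <- stats::runif(length(.substrate_bands), 0.2, 1)
  for (k in seq_along(.substrate_bands)) {
    tb <- .substrate_bands[[k]]
    for (i in seq_len(nrow(tb))) {
      pk <- peak_spec(tb[i, 1] + stats::rnorm(1, 0, 15),
                      tb[i, 2] * stats::runif(1, 0.8, 1.2),
                      tb[i, 3] * stats::runif(1, 0.6, 1.4),
                      shape = if (tb[i, 4] == 1) "gaussian" else "lorentzian")
      v <- v + mix[k] * eval_peak(pk, grid$nu)
    }
  }
  for (i in seq_len(nrow(.gas_lines))) {
    pk <- peak_spec(.gas_lines[i, 1] + stats::rnorm(1, 0, 1),
                    .gas_lines[i, 2],
                    .gas_lines[i, 3] * stats::runif(1, 0.7, 1.3))
    v <- v + eval_peak(pk, grid$nu)
  }
  v
}

# Held-out corpus of background measurements used to estimate the basis:
# background truth + smooth baseline + instrument noise, as measured.
simulate_background_corpus <- function(grid, n = 40, amplitude = 1,
                                       noise = default_noise_model(grid),
                                       seed = NULL) {
  local_seed(seed)
  lapply(seq_len(n), function(i) {
    bl <- simulate_baseline(grid, sample(c("poly", "exp_decay", "sigmoid"), 1),
                            amplitude = 3 * amplitude)
    raman_spectrum(grid, amplitude * background_truth(grid) + bl$values +
                     stats::rnorm(grid$p, 0, sqrt(noise$gamma * noise$sigma_sq)),
                   label = sprintf("background%d", i))
  })
}

#' Study configuration for [simulate_study()]
#'
#' Defaults follow the survey protocol the package benchmarks against:
#' 500 target scenes and 1000 target-free scenes on the 375-3500 cm^-1 /
#' 947-channel grid, a low signal-to-noise ratio (target peak height equal
#' to 5 median noise standard deviations), baselines 2-6 times taller than
#' the target peak drawn from a mix of in-span and out-of-span families,
#' and M = 6 background basis vectors estimated from a 40-spectrum corpus.
#'
#' @param n_h1,n_h0 number of target / target-free scenes
#' @param snr target peak height divided by the median noise standard
#'   deviation
#' @param baseline_rel range (relative to the target peak height) from
#'   which each scene's baseline amplitude is drawn
#' @param families baseline families sampled per scene (uniformly)
#' @param M number of background basis vectors
#' @param n_bg_corpus corpus size used to estimate the background basis
#' @export
study_config <- function(n_h1 = 500L, n_h0 = 1000L, snr = 5,
                         baseline_rel = c(2, 6),
                         families = c("poly", "sigmoid", "broad_gauss_mix",
                                      "exp_decay"),
                         M = 6L, n_bg_corpus = 40L) {
  if (n_h1 < 1 || n_h0 < 1)
    stop("scene counts must be positive", call. = FALSE)
  list(n_h1 = as.integer(n_h1), n_h0 = as.integer(n_h0), snr = snr,
       baseline_rel = baseline_rel, families = families,
       M = as.integer(M), n_bg_corpus = as.integer(n_bg_corpus))
}

#' Generate a full synthetic detection study
#'
#' Emulates the survey protocol end to end.  First the background basis is
#' estimated the way a practitioner would: a held-out corpus of background
#' measurements is baseline-corrected (stiff ArPLS, so that substrate
#' features narrower than the 350 cm^-1 peak bound survive) and the M
#' leading singular vectors are kept.  Then one measurement site is drawn:
#' a fresh realisation of the heterogeneous substrate/gas process (band
#' positions, widths and heights jitter spot-to-spot), shared by every
#' scene of the study the way a field campaign measures one background
#' spot repeatedly — so every spectrum carries the same systematic
#' site-versus-basis mismatch, as with instrument data.  Per scene the
#' site signature fluctuates by +/- 10% in amplitude (source and
#' collection drift).  H1 scenes add the target signature with 20%
#' amplitude jitter
#' around the configured SNR; every scene gets its own baseline (family
#' and amplitude drawn per scene) and noise realisation.  Fully
#' reproducible from the seed.
#'
#' @param grid a [make_grid()] axis (default the 375-3500/947 survey grid)
#' @param config a [study_config()]
#' @param seed RNG seed
#' @return a list with `h1`, `h0` (lists of `synthetic_scene`), `refs`,
#'   `bg` (the corpus-estimated basis used for correction and detection),
#'   `noise`, `config`, `seed`, `target` (index of the target column)
#' @export
simulate_study <- function(grid = make_grid(375, 3500, 947),
                           config = study_config(), seed = 1) {
  stopifnot(inherits(grid, "wn_grid"))
  local_seed(seed)
  refs <- default_reference_library(grid)
  noise <- default_noise_model(grid, gamma = 1)   # median sd = 1
  sd_med <- sqrt(noise$gamma) * stats::median(sqrt(noise$sigma_sq))
  amp <- config$snr * sd_med                      # target peak height
  bg_scale <- 0.8 * amp                           # background feature scale
  corpus <- simulate_background_corpus(grid, n = config$n_bg_corpus,
                                       amplitude = bg_scale, noise = noise)
  bg <- build_background_basis(corpus, M = config$M,
                               corrector = function(s)
                                 arpls_baseline(s, lambda = 1e8))
  site <- background_basis(grid,
                           cbind(site = bg_scale * background_truth(grid)))
  draw_scene <- function(with_target) {
    g <- numeric(ncol(refs$S))
    if (with_target) g[1L] <- amp * stats::runif(1, 0.8, 1.2)
    fam <- sample(config$families, 1L)
    b_amp <- amp * stats::runif(1, config$baseline_rel[1L],
                                config$baseline_rel[2L])
    bl <- simulate_baseline(grid, fam, amplitude = b_amp)
    simulate_scene(refs, g, site, stats::runif(1, 0.9, 1.1), bl, noise)
  }
  h1 <- lapply(seq_len(config$n_h1), function(i) draw_scene(TRUE))
  h0 <- lapply(seq_len(config$n_h0), function(i) draw_scene(FALSE))
  list(h1 = h1, h0 = h0, refs = refs, bg = bg, noise = noise,
       config = config, seed = seed, target = 1L)
}
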