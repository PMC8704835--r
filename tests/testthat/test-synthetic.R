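test_that("reference synthesis: normalisation, superposition, closed forms", {
  g <- make_grid(0, 1000, 1001)
  one <- simulate_reference(g, list(peak_spec(500, 40)))
  expect_equal(max(one$values), 1)
  expect_equal(which.max(one$values), 501L)

  # disjoint peaks superpose (up to the common normalisation)
  two <- simulate_reference(g, list(peak_spec(200, 10), peak_spec(800, 10, 0.5)))
  expect_equal(two$values[201], 1, tolerance = 1e-6)
  expect_equal(two$values[801], 0.5, tolerance = 1e-6)

  # lorentzian at one FWHM from center is height/5
  lor <- peak_spec(500, 40, height = 2, shape = "lorentzian")
  prof <- 2 / (1 + (2 * (g$nu - 500) / 40)^2)
  expect_equal(prof[541], 2 / 5, tolerance = 1e-12)     # nu - c = 40
  lone <- simulate_reference(g, list(lor))
  expect_equal(lone$values, prof / max(prof), tolerance = 1e-12)

  expect_error(simulate_reference(g, list(peak_spec(2000, 10))), "outside")
  expect_error(peak_spec(500, -1), "positive")
  expect_warning(peak_spec(500, 400), "350")
})

test_that("baseline families: exact forms, positivity, smoothness", {
  g <- make_grid(375, 3500, 947)
  const <- simulate_baseline(g, "poly", params = list(coef = 4.5))
  expect_equal(const$values, rep(4.5, 947))

  gb <- build_gaussian_basis(g, 11)
  cf <- seq(0.5, 1.5, length.out = 11)
  mix <- simulate_baseline(g, "broad_gauss_mix",
                           params = list(L = 11, coef = cf))
  expect_same_values(mix$values, drop(gb$K %*% cf))

  expect_error(simulate_baseline(g, "broad_gauss_mix",
                                 params = list(L = 11, coef = rep(-1, 11))),
               "negative")

  # every family is smooth: bounded second differences relative to range
  for (fam in c("poly", "sigmoid", "broad_gauss_mix", "exp_decay")) {
    b <- simulate_baseline(g, fam, amplitude = 10, seed = 71)
    expect_true(all(b$values >= 0))
    d2 <- diff(b$values, differences = 2)
    expect_lt(max(abs(d2)), 1e-3 * diff(range(b$values)) + 1e-9)
  }
})

test_that("scenes satisfy the construction identity and the noiseless limit", {
  g <- make_grid(375, 3500, 200)
  m <- tiny_model(p = 200, C = 3, M = 2)
  refs <- reference_library(g, m$refs$S)
  bg <- background_basis(g, m$bg$K)
  bl <- simulate_baseline(g, "exp_decay", amplitude = 5, seed = 72)
  nm <- default_noise_model(g, gamma = 1)
  sc <- simulate_scene(refs, c(2, 0, 0), bg, c(1, 3), bl, nm, seed = 73)
  expect_same_values(sc$x$values,
                     sc$t$values + sc$b$values + sc$n$values)
  expect_same_values(sc$t$values,
                     drop(refs$S %*% sc$g + bg$K %*% sc$y_bg))

  tiny <- simulate_scene(refs, c(2, 0, 0), bg, c(1, 3), bl,
                         default_noise_model(g, gamma = 1e-30), seed = 74)
  expect_same_values(tiny$x$values, tiny$t$values + tiny$b$values, tol = 1e-6)

  # target-free scenes have zero Raman signature from S
  h0 <- simulate_scene(refs, c(0, 0, 0), bg, c(1, 3), bl, nm, seed = 75)
  expect_equal(max(abs(h0$t$values - drop(bg$K %*% c(1, 3)))), 0)
})

test_that("scene noise matches the configured heteroscedastic variances", {
  g <- make_grid(0, 49, 50)
  refs <- reference_library(g, matrix(exp(-(g$nu - 25)^2 / 8), ncol = 1))
  bg <- background_basis(g, matrix(1 / sqrt(50), 50, 1))
  bl <- simulate_baseline(g, "poly", params = list(coef = 1))
  nm <- noise_model(seq(0.5, 3, length.out = 50), gamma = 2)
  set.seed(76)
  draws <- replicate(2e4, simulate_scene(refs, 1, bg, 1, bl, nm)$n$values)
  v_emp <- apply(draws, 1, var)
  expect_lt(max(abs(v_emp / (2 * nm$sigma_sq) - 1)), 0.05)
})

test_that("scene generation is deterministic given a seed", {
  g <- make_grid(375, 3500, 120)
  m <- tiny_model(p = 120)
  refs <- reference_library(g, m$refs$S)
  bg <- background_basis(g, m$bg$K)
  bl <- simulate_baseline(g, "sigmoid", amplitude = 3, seed = 77)
  nm <- default_noise_model(g)
  s1 <- simulate_scene(refs, c(1, 0), bg, c(1, 1), bl, nm, seed = 78)
  s2 <- simulate_scene(refs, c(1, 0), bg, c(1, 1), bl, nm, seed = 78)
  expect_identical(s1$x$values, s2$x$values)

  # and the caller's RNG stream is left untouched
  set.seed(79); before <- rnorm(3)
  set.seed(79); invisible(simulate_scene(refs, c(1, 0), bg, c(1, 1), bl, nm,
                                         seed = 80))
  expect_identical(rnorm(3), before)
})

test_that("in-span baselines are recovered ever more exactly as noise vanishes", {
  g <- make_grid(375, 3500, 300)
  refs <- default_reference_library(g)
  set.seed(81)
  bgm <- qr.Q(qr(matrix(rnorm(300 * 3), 300, 3)))
  bg <- background_basis(g, bgm)
  gb <- build_gaussian_basis(g, 11)
  cf <- runif(11, 1, 5)
  bl <- simulate_baseline(g, "broad_gauss_mix", params = list(L = 11, coef = cf))
  rmse <- vapply(c(1e-2, 1e-4, 1e-6), function(gam) {
    sc <- simulate_scene(refs, c(2, rep(0, 6)), bg, rnorm(3), bl,
                         default_noise_model(g, gamma = gam), seed = 82)
    fit <- fit_lsm_baseline(sc$x, refs, bg, gb)
    sqrt(mean((fit$coefficients$ybl - cf)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
  expect_lt(rmse[3], 1e-2)
})

test_that("study generation matches its configuration and seed contract", {
  g <- make_grid(375, 3500, 947)
  cfg <- study_config(n_h1 = 6, n_h0 = 9, n_bg_corpus = 8, M = 3)
  st1 <- simulate_study(g, cfg, seed = 83)
  expect_length(st1$h1, 6)
  expect_length(st1$h0, 9)
  expect_equal(ncol(st1$bg$K), 3)
  st2 <- simulate_study(g, cfg, seed = 83)
  expect_identical(st1$h1[[3]]$x$values, st2$h1[[3]]$x$values)
  expect_identical(st1$bg$K, st2$bg$K)

  # H0 scenes carry no target signature
  expect_true(all(vapply(st1$h0, function(s) all(s$g == 0), logical(1))))

  # estimated basis columns are orthonormal
  G <- crossprod(st1$bg$K)
  expect_lt(max(abs(G - diag(3))), 1e-8)
  expect_error(study_config(n_h1 = 0), "positive")
})

test_that("generated H1 scenes hit the configured SNR on average", {
  g <- make_grid(375, 3500, 947)
  cfg <- study_config(n_h1 = 40, n_h0 = 1, n_bg_corpus = 6, M = 2, snr = 5)
  st <- simulate_study(g, cfg, seed = 84)
  sd_med <- median(sqrt(st$noise$gamma * st$noise$sigma_sq))
  snr_scene <- vapply(st$h1, function(s) s$g[1] / sd_med, numeric(1))
  expect_lt(abs(mean(snr_scene) / cfg$snr - 1), 0.1)
})
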