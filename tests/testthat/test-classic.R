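# ---- shared penalized solve -------------------------------------------------

test_that("pls_solve: constants are fixed points and the 3-channel case is exact", {
  x <- rep(4.2, 25)
  expect_same_values(pls_solve(x, rep(1, 25), 10), x)
  w <- runif(25); w[3] <- 1
  expect_same_values(pls_solve(x, w, 1e4), x, tol = 1e-9)

  # hand-solved 3x3 system (I + D'D) b = x with x = (0,1,0)
  expect_equal(pls_solve(c(0, 1, 0), rep(1, 3), 1), c(2, 3, 2) / 7,
               tolerance = 1e-12)
})

test_that("pls_solve matches the dense oracle on random instances", {
  for (rep in 1:25) {
    set.seed(300 + rep)
    p <- sample(10:60, 1)
    x <- rnorm(p, sd = 5)
    w <- runif(p)
    lam <- 10^runif(1, -1, 4)
    D <- diff(diag(p), differences = 2)
    dense <- solve(diag(w) + lam * t(D) %*% D, w * x)
    expect_lt(max(abs(pls_solve(x, w, lam) - dense)), 1e-8)
  }
})

test_that("pls_solve tends to the straight-line fit as lambda grows", {
  set.seed(14)
  p <- 50
  x <- 3 + 0.2 * seq_len(p) + rnorm(p)
  b <- pls_solve(x, rep(1, p), 1e14)
  line <- fitted(lm(x ~ seq_len(p)))
  expect_lt(max(abs(b - line)), 1e-6)
})

test_that("pls_solve validates its arguments", {
  expect_error(pls_solve(1:5, rep(0, 5), 1), "singular")
  expect_error(pls_solve(1:5, rep(2, 5), 1), "\\[0, 1\\]")
  expect_error(pls_solve(1:5, rep(1, 4), 1), "length")
  expect_error(pls_solve(1:5, rep(1, 5), -1), "positive")
})

# ---- ALS --------------------------------------------------------------------

test_that("ALS assigns alpha above the baseline and 1-alpha below", {
  g <- tiny_grid(40)
  set.seed(8)
  x <- raman_spectrum(g, rnorm(40, 10))
  fit <- als_baseline(x, lambda = 10, alpha = 0.05, max_iter = 1)
  above <- x$values >= fitted(fit)
  expect_true(all(fit$weights[above] == 0.05))
  expect_true(all(fit$weights[!above] == 0.95))
})

test_that("ALS converges immediately on a constant spectrum", {
  g <- tiny_grid(30)
  x <- raman_spectrum(g, rep(7, 30))
  fit <- als_baseline(x)
  expect_true(fit$converged)
  expect_same_values(fitted(fit), x$values, tol = 1e-9)
})

test_that("ALS baseline stays under a peak riding on a line", {
  g <- make_grid(0, 500, 251)
  peak <- 100 * exp(-(g$nu - 250)^2 / (2 * 10^2))
  x <- raman_spectrum(g, 5 + 0.02 * g$nu + peak)
  fit <- als_baseline(x, lambda = 1000, alpha = 0.01)
  apex <- which.max(peak)
  expect_gt(x$values[apex] - fitted(fit)[apex], 0.9 * 100)
})

test_that("ALS warns for asymmetry outside the recommended band", {
  g <- tiny_grid(30)
  x <- raman_spectrum(g, rnorm(30))
  expect_warning(als_baseline(x, alpha = 0.4), "recommended")
  expect_error(als_baseline(x, alpha = 0.7), "0.5")
})

# ---- AirPLS -----------------------------------------------------------------

test_that("AirPLS weights are zero above the baseline, in (0,1] below", {
  g <- tiny_grid(50)
  set.seed(17)
  x <- raman_spectrum(g, rnorm(50, 20, 3))
  fit <- airpls_baseline(x, lambda = 10, max_iter = 3)
  d <- x$values - fitted(fit)
  # weights stored are the last update, computed from the returned baseline
  if (!fit$converged) {
    expect_true(all(fit$weights[d >= 0] == 0))
    w_below <- fit$weights[d < 0]
    expect_true(all(w_below > 0 & w_below <= 1))
  }
  expect_same_values(fitted(fit) + residuals(fit), x$values)
})

test_that("AirPLS terminates at once on a constant spectrum", {
  g <- tiny_grid(30)
  x <- raman_spectrum(g, rep(3, 30))
  fit <- airpls_baseline(x)
  expect_true(fit$converged)
  expect_equal(fit$iterations, 1L)
  expect_same_values(fitted(fit), x$values, tol = 1e-9)
})

# ---- ArPLS ------------------------------------------------------------------

test_that("ArPLS weights: unity below baseline, logistic and monotone above", {
  g <- tiny_grid(80)
  set.seed(23)
  x <- raman_spectrum(g, rnorm(80, 50, 4))
  fit <- arpls_baseline(x, lambda = 100, max_iter = 100)
  d <- x$values - fitted(fit)
  # recompute the Eq-style weights from the converged baseline
  dn <- d[d < 0]
  m <- mean(dn); s <- sd(dn)
  w_expect <- ifelse(d < 0, 1, 1 / (1 + exp(2 * (d + m - 2 * s) / s)))
  expect_true(all(fit$weights[d < 0] == 1))
  ord <- order(d[d >= 0])
  expect_true(all(diff(fit$weights[d >= 0][ord]) <= 1e-12))
  # half weight where the logistic argument vanishes
  d_half <- 2 * s - m
  expect_equal(1 / (1 + exp(2 * (d_half + m - 2 * s) / s)), 0.5)
})

test_that("ArPLS is equivariant under a constant intensity shift", {
  g <- tiny_grid(60)
  set.seed(29)
  x <- raman_spectrum(g, rnorm(60, 10, 2))
  shifted <- raman_spectrum(g, x$values + 123.4)
  f1 <- arpls_baseline(x, lambda = 50)
  f2 <- arpls_baseline(shifted, lambda = 50)
  expect_same_values(fitted(f2), fitted(f1) + 123.4, tol = 1e-6)
  expect_same_values(f1$weights, f2$weights, tol = 1e-8)
})

test_that("ArPLS flags degenerate noiseless residuals and still returns", {
  g <- tiny_grid(30)
  x <- raman_spectrum(g, rep(5, 30))          # constant: d- is empty
  fit <- arpls_baseline(x)
  expect_true(fit$degenerate)
  expect_true(fit$converged)
  expect_same_values(fitted(fit), x$values, tol = 1e-9)
})

# ---- smooth-curve recovery for the PLS family -------------------------------

test_that("PLS correctors recover a pure smooth curve within 2%", {
  g <- make_grid(375, 3500, 947)
  b_true <- 100 * exp(-(g$nu - 375) / 1200) + 20
  x <- raman_spectrum(g, b_true)
  for (f in list(als_baseline, airpls_baseline, arpls_baseline)) {
    fit <- f(x)
    expect_lt(max(abs(fitted(fit) - b_true)) / max(b_true), 0.02)
  }
})

# ---- IMF --------------------------------------------------------------------

test_that("IMF: constants are invariant and the 5-channel spike is erased", {
  g <- tiny_grid(30)
  x <- raman_spectrum(g, rep(2, 30))
  expect_same_values(fitted(imf_baseline(x, 20, 3)), x$values)

  g5 <- make_grid(0, 4, 5)
  spike <- raman_spectrum(g5, c(0, 0, 5, 0, 0))
  fit <- imf_baseline(spike, window_cm = 3, n_iter = 1)   # 3-channel window
  expect_equal(fitted(fit), rep(0, 5))
})

test_that("IMF matches brute-force medians with reflected edges", {
  g <- make_grid(0, 10, 11)
  set.seed(37)
  v <- rnorm(11)
  fit <- imf_baseline(raman_spectrum(g, v), window_cm = 5, n_iter = 1)
  k <- fit$window_channels
  h <- (k - 1) %/% 2
  padded <- c(v[(h + 1):2], v, v[(11 - 1):(11 - h)])
  brute <- vapply(seq_len(11), function(i) median(padded[i:(i + k - 1)]),
                  numeric(1))
  expect_same_values(fitted(fit), brute)
})

test_that("IMF iteration shrinks the per-pass change", {
  g <- make_grid(0, 1000, 501)
  set.seed(41)
  x <- raman_spectrum(g, cumsum(rnorm(501)) + 50)
  prev <- x$values
  deltas <- numeric(4)
  for (k in 1:4) {
    cur <- fitted(imf_baseline(x, window_cm = 50, n_iter = k))
    deltas[k] <- max(abs(cur - prev))
    prev <- cur
  }
  expect_true(all(diff(deltas) <= 1e-9))
})

test_that("IMF rejects windows wider than the spectrum", {
  g <- tiny_grid(30)
  x <- raman_spectrum(g, rnorm(30))
  expect_error(imf_baseline(x, window_cm = 1e5), "wider")
})

# ---- RCF --------------------------------------------------------------------

test_that("RCF reproduces an affine ramp and never exceeds the spectrum", {
  g <- make_grid(0, 1000, 501)
  ramp <- raman_spectrum(g, 2 + 0.05 * g$nu)
  fit <- rcf_baseline(ramp, radius_cm = 100)
  expect_lt(max(abs(fitted(fit) - ramp$values)), 1)

  set.seed(43)
  bumpy <- raman_spectrum(g, 50 + 10 * sin(g$nu / 150) +
                            100 * exp(-(g$nu - 480)^2 / 50))
  fit2 <- rcf_baseline(bumpy, radius_cm = 100)
  expect_true(all(fitted(fit2) <= bumpy$values + 1e-9))
})

test_that("RCF bridges a narrow spike", {
  g <- make_grid(0, 200, 201)   # spacing 1 cm^-1: channels = cm^-1
  v <- numeric(201); v[100:102] <- 100
  fit <- rcf_baseline(raman_spectrum(g, v), radius_cm = 50)
  expect_lt(max(fitted(fit)), 5)
})

test_that("RCF rejects radii beyond half the axis span", {
  g <- make_grid(0, 100, 101)
  x <- raman_spectrum(g, rnorm(101))
  expect_error(rcf_baseline(x, radius_cm = 60), "half")
})

# ---- common contract --------------------------------------------------------

test_that("every corrector returns baseline + corrected = input exactly", {
  g <- make_grid(375, 3500, 400)
  set.seed(47)
  x <- raman_spectrum(g, abs(rnorm(400, 50, 10)))
  fits <- list(imf_baseline(x), rcf_baseline(x), als_baseline(x),
               airpls_baseline(x), arpls_baseline(x))
  for (fit in fits) {
    expect_length(fitted(fit), 400)
    expect_same_values(fitted(fit) + residuals(fit), x$values)
  }
})
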