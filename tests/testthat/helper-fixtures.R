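# Small in-code fixtures shared across test files.

# compact grid for fast model tests
tiny_grid <- function(p = 60, lo = 0, hi = 100) make_grid(lo, hi, p)

# a small full-rank model: C references, M background vectors, L Gaussians
tiny_model <- function(p = 60, C = 2, M = 2, L = 4, seed = 101) {
  grid <- tiny_grid(p)
  set.seed(seed)
  S <- vapply(seq_len(C), function(c) {
    ctr <- runif(1, 15, 85)
    exp(-(grid$nu - ctr)^2 / (2 * runif(1, 2, 5)^2))
  }, numeric(p))
  Kbg <- qr.Q(qr(matrix(rnorm(p * M), p, M)))
  list(grid = grid,
       refs = reference_library(grid, S),
       bg = background_basis(grid, Kbg),
       basis = suppressWarnings(build_gaussian_basis(grid, L)))
}

# random spectrum orthogonal to the columns of a matrix
orth_to <- function(grid, mat, seed = 1) {
  set.seed(seed)
  v <- qr.resid(qr(mat), rnorm(grid$p))
  raman_spectrum(grid, v)
}

expect_same_values <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(a - b)), tol)
}
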