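# Independent oracles used across the suite. These deliberately avoid the
# package's own evaluation path: closed-form polynomials instead of the
# recurrence, and raw Gauss-Hermite quadrature instead of inner_product().

# Hand-expanded probabilists' Hermite polynomials He_0..He_5.
he_closed <- list(
  function(x) rep(1, length(x)),
  function(x) x,
  function(x) x^2 - 1,
  function(x) x^3 - 3 * x,
  function(x) x^4 - 6 * x^2 + 3,
  function(x) x^5 - 10 * x^3 + 15 * x
)

# \int f(x) p(x) dx against the standard normal density, by raw
# Gauss-Hermite quadrature (physicists' rule, x = sqrt(2) u).
quad_gauss <- function(f, n_nodes = 60L) {
  gh <- pracma::gaussHermite(n_nodes)
  x <- sqrt(2) * gh$x
  sum(gh$w * f(x)) / sqrt(pi)
}

# Population coordinate of f on closed-form basis order i (the limit of
# the per-basis estimator): \int f h_i p dx / \int h_i^2 p dx.
oracle_coord <- function(f, i, convention = "simulation") {
  k <- if (convention == "simulation") sqrt(sqrt(2 * pi) * factorial(i))
  else sqrt(factorial(i))
  h <- function(x) he_closed[[i + 1L]](x) / k
  quad_gauss(function(x) f(x) * h(x)) / quad_gauss(function(x) h(x)^2)
}

# Default normalization constants, from their closed forms.
K0_SIM <- (2 * pi)^0.25
K2_SIM <- sqrt(2 * sqrt(2 * pi))

# Small deterministic grid fixture for voxel-level tests.
make_grid <- function(dims = c(6, 6, 6)) array(TRUE, dims)

# Spatially smoothed i.i.d. Gaussian subject maps (null fixture for the
# permutation test; smoothing gives suprathreshold clusters a
# non-degenerate size distribution, as in real BOLD loading maps).
smooth_null_maps <- function(S, dims, sigma_vox = 0.85) {
  V <- prod(dims)
  t(vapply(seq_len(S), function(s) {
    as.vector(funcoord:::smooth3d(array(stats::rnorm(V), dims),
                                  rep(sigma_vox, 3)))
  }, numeric(V)))
}

# Planted-cluster coordinate centers: five distinct interaction types,
# two pairs sharing the same linear (order-1) component so that the
# linear coordinate alone cannot separate them.
planted_centers <- function() {
  rbind(c(0,  1,  0.8,  0,   0),
        c(0,  1, -0.8,  0,   0),
        c(0, -1,  0,    0.8, 0),
        c(0, -1,  0,   -0.8, 0),
        c(0,  0,  0,    0,   1))
}
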