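test_that("zscore uses the population SD and rejects degenerate input", {
  expect_equal(zscore(c(1, 2, 3)),
               c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_error(zscore(c(5, 5, 5)), "degenerate")
  v <- zscore(rnorm(50))
  expect_equal(zscore(v), v, tolerance = 1e-12)   # idempotent
})

test_that("per-basis estimator is the exact ratio of sums", {
  set.seed(2)
  x <- rnorm(200)
  # self-projection and linearity are exact, not just asymptotic
  for (ord in 0:4) {
    y <- hermite_poly(x, ord) / hermite_norm_const(ord, "simulation")
    expect_equal(unname(coef(funcoord(x, y))[ord + 1L]), 1,
                 tolerance = 1e-12)
  }
  y <- 3 * hermite_poly(x, 1) / hermite_norm_const(1, "unit")
  expect_equal(unname(coef(funcoord(x, y, convention = "unit"))[2L]), 3,
               tolerance = 1e-12)
})

test_that("estimated coordinates converge to the quadrature oracle", {
  set.seed(3)
  x <- rnorm(2e5)
  fit <- funcoord(x, x^2)
  expect_equal(unname(coef(fit)[3L]), K2_SIM, tolerance = 0.01)
  expect_equal(unname(coef(fit)[3L]),
               oracle_coord(function(x) x^2, 2), tolerance = 0.01)
  # error decays like T^(-1/2) for a target in the basis span; the
  # spectrum decays with order, as for smooth dependence functions
  truth <- c(1, 1, 0.3, 0.15, 0.1)
  Ts <- c(1e2, 1e3, 1e4, 1e5)
  err <- vapply(seq_along(Ts), function(i) {
    E <- matrix(0, 10, 5)
    for (s in 1:10) {
      set.seed(100 * s + i)
      xs <- rnorm(Ts[i])
      ys <- drop(hermite_basis(xs, basis_spec(5, "unit")) %*% truth)
      E[s, ] <- abs(coef(funcoord(xs, ys, convention = "unit")) - truth)
    }
    max(colMeans(E))     # worst per-order error, seed-averaged
  }, numeric(1))
  slope <- coef(lm(log(err) ~ log(Ts)))[2L]
  expect_lt(abs(slope - (-0.5)), 0.25)
  expect_lt(err[4L], 0.02)
})

test_that("truncation does not move lower-order per-basis estimates", {
  set.seed(4)
  x <- rnorm(500); y <- x^2 + rnorm(500)
  c3 <- coef(funcoord(x, y, order = 3))
  c5 <- coef(funcoord(x, y, order = 5))
  expect_identical(unname(c3), unname(c5[1:3]))   # bit-identical
})

test_that("per-basis and joint OLS agree asymptotically, not exactly", {
  set.seed(5)
  x <- rnorm(5000); y <- x^2 + 0.5 * x + rnorm(5000)
  cb <- coef(funcoord(x, y, estimator = "per-basis"))
  cj <- coef(funcoord(x, y, estimator = "joint"))
  expect_false(identical(cb, cj))
  expect_lt(max(abs(cb - cj)), 2 / sqrt(5000) * 3)
})

test_that("estimation is directional", {
  set.seed(6)
  x <- rnorm(5000); y <- x^2 + 0.1 * rnorm(5000)
  both <- bidirectional_coordinates(x, y)
  expect_gt(coef(both$forward)["c2"], 1.5)     # forward sees the square
  expect_lt(abs(coef(both$reverse)["c2"]), 0.5)
  expect_false(isTRUE(all.equal(coef(both$forward), coef(both$reverse))))
})

test_that("reconstruction matches the coordinate expansion", {
  f <- funcoord(rnorm(100), rnorm(100), order = 5, convention = "unit")
  f$coefficients[] <- c(0, 1, 0, 0, 0)        # one-hot order 1
  g <- seq(-2, 2, by = 0.5)
  expect_equal(predict(f, newx = g), g, tolerance = 1e-12)
  f$coefficients[] <- 0
  expect_equal(predict(f, newx = g), rep(0, length(g)))
  set.seed(7)
  x <- rnorm(5e4)
  fit <- funcoord(x, x^2)
  expect_lt(abs(predict(fit, newx = 0)), 0.1)  # true curve passes 0
})

test_that("variance partition respects basis orthogonality", {
  set.seed(8)
  x <- rnorm(5000)
  h1 <- hermite_poly(x, 1) / hermite_norm_const(1)
  # joint OLS on a target inside the linear span: higher orders add
  # exactly nothing (for per-basis fits the same holds asymptotically)
  fit_j <- funcoord(x, h1, estimator = "joint")
  vp_j <- variance_partition(fit_j, group_a = 0:1, group_b = 0:4)
  expect_equal(vp_j$delta, 0, tolerance = 1e-10)
  fit <- funcoord(x, h1)
  vp <- variance_partition(fit, group_a = 0:1, group_b = 0:4)
  expect_lt(abs(vp$delta), 0.05)
  # a pure quadratic is invisible to the linear group
  fit2 <- funcoord(x, hermite_poly(x, 2) / hermite_norm_const(2))
  vp2 <- variance_partition(fit2, group_a = 0:1, group_b = 0:4)
  expect_lt(vp2$r2_a, 0.02)
  expect_gt(vp2$r2_b, 0.95)
  # x^3 = He_3 + 3 He_1 is purely odd
  fit3 <- funcoord(x, x^3)
  vp3 <- variance_partition(fit3, group_a = c(1, 3), group_b = 0:4)
  expect_gt(vp3$r2_a, 0.95)
  expect_error(variance_partition(fit, integer(0), 0:4), "non-empty")
})

test_that("pearson_fc is the linear baseline", {
  x <- rnorm(100)
  expect_equal(pearson_fc(x, 2 * x + 1), 1, tolerance = 1e-12)
  expect_equal(pearson_fc(x, -x), -1, tolerance = 1e-12)
  expect_error(pearson_fc(x, rep(1, 100)), "degenerate")
})

test_that("empirical basis recovers known orthogonal families", {
  set.seed(9)
  # Gaussian sample -> unit-convention Hermite basis
  x <- rnorm(2e5)
  eb <- empirical_basis(x, 4)
  g <- seq(-2, 2, by = 0.25)
  M <- predict(eb, g)
  H <- hermite_basis(g, basis_spec(4, "unit"))
  for (j in 1:4)
    expect_lt(max(abs(abs(M[, j]) - abs(H[, j]))), 0.1)
  # empirical orthonormality to high precision by construction
  Mx <- predict(eb, x)
  expect_equal(crossprod(Mx) / length(x), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  # uniform sample -> normalized Legendre system
  u <- runif(5e4, -1, 1)
  ebu <- empirical_basis(u, 3)
  Mu <- predict(ebu, g <- seq(-1, 1, by = 0.2))
  leg2 <- sqrt(5) * (3 * g^2 - 1) / 2        # normalized P_2 on U(-1,1)
  expect_lt(max(abs(abs(Mu[, 3]) - abs(leg2))), 0.05)
  # degenerate cases
  expect_equal(unname(predict(empirical_basis(rnorm(50), 1), 0)[1, 1]), 1,
               tolerance = 1e-10)
  expect_error(empirical_basis(rep(1, 100), 3), "degenerate|distinct")
})

test_that("fits serialize to TSV and JSON round-trippably", {
  set.seed(10)
  fit <- funcoord(rnorm(100), rnorm(100))
  tsv <- tempfile(fileext = ".tsv")
  write_funcoord(fit, tsv)
  d <- read.table(tsv, header = TRUE)
  expect_equal(d$order, 0:4)
  expect_equal(d$value, unname(coef(fit)))
  js <- tempfile(fileext = ".json")
  write_funcoord(fit, js)
  j <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(j$values, unname(coef(fit)))
  expect_equal(j$convention, "simulation")
  expect_equal(j$n, 100L)
})
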