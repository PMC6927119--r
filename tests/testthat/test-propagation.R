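test_that("normalized Laplacian has the standard spectral structure", {
  expect_equal(normalized_laplacian(diag(3)), matrix(0, 3, 3))
  l <- normalized_laplacian(matrix(1, 3, 3))
  ev <- eigen(l, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(ev), c(0, 1, 1), tolerance = 1e-12)

  s <- random_similarity(6, 1)
  l2 <- normalized_laplacian(s)
  ev2 <- eigen(l2, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev2 > -1e-8) && all(ev2 < 2 + 1e-8))
  # sqrt-degree vector spans the null space
  expect_lt(max(abs(l2 %*% sqrt(rowSums(s)))), 1e-9)
  expect_error(normalized_laplacian(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("pairwise weighted-difference sums equal the trace expressions", {
  for (seed in 1:3) {
    set.seed(seed)
    f <- matrix(rnorm(5 * 4), 5, 4)
    sm <- random_similarity(5, seed)
    sd_ <- random_similarity(4, seed + 5)
    dm <- rowSums(sm); dd <- rowSums(sd_)
    # miRNA-side double sum over row pairs
    lhs_m <- 0
    for (i in 1:5) for (j in 1:5)
      lhs_m <- lhs_m + sm[i, j] * sum((f[i, ] / sqrt(dm[i]) -
                                       f[j, ] / sqrt(dm[j]))^2)
    lm <- normalized_laplacian(sm)
    expect_equal(lhs_m / 2, sum(diag(t(f) %*% lm %*% f)), tolerance = 1e-8)
    # disease-side double sum over column pairs
    lhs_d <- 0
    for (u in 1:4) for (v in 1:4)
      lhs_d <- lhs_d + sd_[u, v] * sum((f[, u] / sqrt(dd[u]) -
                                        f[, v] / sqrt(dd[v]))^2)
    ld <- normalized_laplacian(sd_)
    expect_equal(lhs_d / 2, sum(diag(f %*% ld %*% t(f))), tolerance = 1e-8)
  }
})

test_that("objective and gradient agree with hand expansion and each other", {
  set.seed(2)
  y <- matrix(rbinom(6, 1, .5), 2, 3)
  f <- matrix(rnorm(6), 2, 3)
  lm <- normalized_laplacian(random_similarity(2, 3))
  ld <- normalized_laplacian(random_similarity(3, 4))
  expect_equal(propagation_objective(y, y, lm, ld, 0, 0), 0)
  expect_gte(propagation_objective(y, y, lm, ld, 2, 2), 0)
  byhand <- sum((f - y)^2) + 1.5 / 2 * sum(diag(t(f) %*% lm %*% f)) +
    0.5 / 2 * sum(diag(f %*% ld %*% t(f)))
  expect_equal(propagation_objective(f, y, lm, ld, 1.5, 0.5), byhand)

  # gradient vanishes at y when unregularized; affine in F
  expect_equal(propagation_gradient(y, y, lm, ld, 0, 0), matrix(0, 2, 3),
               ignore_attr = TRUE)
  f2 <- matrix(rnorm(6), 2, 3)
  g <- function(x) propagation_gradient(x, y, lm, ld, 1.2, 0.7)
  expect_equal(g(f) + g(f2) - g(matrix(0, 2, 3)), g(f + f2), tolerance = 1e-12)
})

test_that("gradient matches central finite differences", {
  set.seed(3)
  y <- matrix(rbinom(20, 1, .4), 5, 4)
  lm <- normalized_laplacian(random_similarity(5, 6))
  ld <- normalized_laplacian(random_similarity(4, 7))
  f <- matrix(rnorm(20), 5, 4)
  g <- propagation_gradient(f, y, lm, ld, 1.3, 0.6)
  h <- 1e-6
  for (idx in sample(20, 5)) {
    fp <- f; fm <- f
    fp[idx] <- fp[idx] + h
    fm[idx] <- fm[idx] - h
    num <- (propagation_objective(fp, y, lm, ld, 1.3, 0.6) -
            propagation_objective(fm, y, lm, ld, 1.3, 0.6)) / (2 * h)
    expect_equal(g[idx], num, tolerance = 1e-5)
  }
})

test_that("the exact solver satisfies stationarity", {
  set.seed(4)
  y <- matrix(rbinom(12, 1, .5), 4, 3)
  lm <- normalized_laplacian(random_similarity(4, 8))
  ld <- normalized_laplacian(random_similarity(3, 9))
  f <- propagation_exact(y, lm, ld, 2, 0.5)
  expect_lt(max(abs(propagation_gradient(f, y, lm, ld, 2, 0.5))), 1e-10)
})

test_that("AdaGrad reaches the closed-form minimizer", {
  # unregularized case: minimizer is y itself
  set.seed(5)
  y <- matrix(rbinom(12, 1, .5), 4, 3)
  lm <- normalized_laplacian(random_similarity(4, 1))
  ld <- normalized_laplacian(random_similarity(3, 2))
  sol0 <- adagrad_solve(y, lm, ld, 0, 0)
  expect_equal(sol0$f, y, tolerance = 1e-6, ignore_attr = TRUE)

  # against the Kronecker linear-system solution
  for (seed in 1:3) {
    set.seed(seed + 10)
    y2 <- matrix(rbinom(4 * 3, 1, .4), 4, 3)
    lm2 <- normalized_laplacian(random_similarity(4, seed + 20))
    ld2 <- normalized_laplacian(random_similarity(3, seed + 30))
    exact <- propagation_exact(y2, lm2, ld2, 1, 1)
    sol <- adagrad_solve(y2, lm2, ld2, 1, 1, tol = 1e-14, max_iter = 50000)
    expect_lt(max(abs(sol$f - exact)), 1e-4)
    # approximate stationarity relative to the start
    g0 <- propagation_gradient(y2, y2, lm2, ld2, 1, 1)
    g1 <- propagation_gradient(sol$f, y2, lm2, ld2, 1, 1)
    expect_lt(norm(g1, "F") / norm(g0, "F"), 1e-3)
  }
})

test_that("stronger miRNA regularization shrinks the smoothness penalty", {
  set.seed(6)
  y <- matrix(rbinom(15, 1, .4), 5, 3)
  lm <- normalized_laplacian(random_similarity(5, 40))
  ld <- normalized_laplacian(random_similarity(3, 41))
  pen <- vapply(c(0.25, 1, 4, 16), function(lam) {
    f <- propagation_exact(y, lm, ld, lam, 0)
    sum(diag(t(f) %*% lm %*% f))
  }, numeric(1))
  expect_true(all(diff(pen) <= 1e-10))
})
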