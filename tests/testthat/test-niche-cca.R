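rand_comm <- function(n, m, seed) {
  set.seed(seed)
  matrix(rpois(n * m, 10) + 1L, n, m,
         dimnames = list(paste0("s", 1:n), paste0("k", 1:m)))
}

test_that("a constant constraint explains no inertia", {
  Y <- rand_comm(8, 5, 71)
  expect_warning(fit <- cca_fit(Y, rep(1, 8)), "aliased")
  expect_equal(fit$constrained_inertia, 0)
  expect_equal(length(fit$eig), 0)
  expect_true(is.na(fit$pseudo_F))
})

test_that("eigenvalues and inertia match the vegan reference implementation", {
  skip_if_not_installed("vegan")
  for (seed in c(72, 73, 74)) {
    Y <- rand_comm(10, 6, seed)
    set.seed(seed + 100)
    X <- data.frame(ph = rnorm(10), cn = rnorm(10),
                    veg = sample(c("a", "b"), 10, replace = TRUE))
    fit <- cca_fit(Y, X)
    ref <- vegan::cca(Y ~ ph + cn + veg, data = X)
    expect_equal(fit$total_inertia, ref$tot.chi, tolerance = 1e-10)
    expect_equal(fit$constrained_inertia, ref$CCA$tot.chi, tolerance = 1e-10)
    expect_equal(unname(fit$eig), unname(ref$CCA$eig), tolerance = 1e-8)
  }
})

test_that("eigenvalue sum equals constrained inertia and CA is recovered", {
  Y <- rand_comm(9, 5, 75)
  set.seed(175)
  X <- matrix(rnorm(27), 9, 3)
  fit <- cca_fit(Y, X)
  expect_equal(sum(fit$eig), fit$constrained_inertia, tolerance = 1e-10)
  expect_lte(fit$constrained_inertia, fit$total_inertia + 1e-12)
  expect_true(all(diff(fit$eig) <= 1e-12))

  # a full indicator basis of samples reproduces unconstrained CA inertia
  ind <- diag(9)[, -1]
  fit2 <- cca_fit(Y, ind)
  expect_equal(fit2$constrained_inertia, fit2$total_inertia,
               tolerance = 1e-10)
})

test_that("aliased constraint columns are dropped with a warning", {
  Y <- rand_comm(8, 4, 76)
  set.seed(176)
  x <- rnorm(8)
  expect_warning(fit <- cca_fit(Y, cbind(a = x, b = 2 * x)), "aliased")
  expect_equal(fit$rank, 1)
})

test_that("a noise-free gradient community is explained as the basis grows", {
  ph <- seq(4, 8, length.out = 10)
  opt <- c(4.5, 6, 7.5)
  Y <- exp(-1.5 * outer(ph, opt, `-`)^2)
  Y <- Y / rowSums(Y)
  # abundances are an exact (unimodal, nonlinear) function of one
  # gradient: explained inertia rises towards 1 as the polynomial basis
  # of that gradient becomes flexible enough
  ratios <- vapply(c(1, 2, 4, 6), function(d) {
    f <- cca_fit(Y, stats::poly(ph, d))
    f$constrained_inertia / f$total_inertia
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
  expect_gt(ratios[1], 0.5)
  expect_gt(ratios[4], 0.99)
})

test_that("permutation tests are reproducible, ordered and floored", {
  Y <- rand_comm(12, 5, 77)
  set.seed(177)
  x <- rnorm(12)
  p1 <- permutation_test(Y, x, n_perm = 199, seed = 5)
  p2 <- permutation_test(Y, x, n_perm = 199, seed = 5)
  expect_identical(p1$p_value, p2$p_value)
  expect_gte(p1$p_value, 1 / 200)

  # constant factor: nothing to test
  expect_equal(permutation_test(Y, rep(2, 12), n_perm = 99)$p_value, 1.0)

  # a strong gradient hits the attainable floor
  ph <- seq(4, 8, length.out = 12)
  opt <- c(4.5, 5.5, 6.5, 7.5, 8)
  Ys <- exp(-2 * outer(ph, opt, `-`)^2) + 0.001
  Ys <- 1000 * Ys / rowSums(Ys)
  pt <- permutation_test(Ys, ph, n_perm = 999, seed = 9)
  expect_equal(pt$p_value, 0.001)
})

test_that("categorical factors are dummy-coded and permuted as a block", {
  Y <- rand_comm(12, 4, 78)
  set.seed(178)
  veg <- sample(c("forest", "grassland", "moor"), 12, replace = TRUE)
  pt <- permutation_test(Y, veg, n_perm = 99, seed = 3)
  expect_true(pt$p_value > 0 && pt$p_value <= 1)
  fit <- cca_fit(Y, data.frame(veg = veg))
  expect_equal(fit$rank, 2)                # 3 levels -> 2 dummy columns
})

test_that("niche_screen tabulates factors by threshold with cluster counts", {
  set.seed(79)
  m1 <- matrix(rpois(15, 20) + 1L, 5, 3,
               dimnames = list(paste0("s", 1:5), c("K1", "K2", "K3")))
  class(m1) <- c("abundance_matrix", class(m1))
  env <- data.frame(pH = runif(5, 4, 8), C = runif(5),
                    row.names = paste0("s", 1:5))
  out <- niche_screen(list(id0.9 = m1), env, n_perm = 99, seed = 2)
  expect_equal(rownames(out), c("pH", "C", "n_clusters"))
  expect_equal(out["n_clusters", 1], 3)
  expect_true(all(out[1:2, 1] >= 0.01 & out[1:2, 1] <= 1))
})
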