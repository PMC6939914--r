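block_table <- function(n_per = 8, n_sp = 9, strength = 60, seed = 71) {
  # treatment fully determines composition; year is balanced noise-free
  set.seed(seed)
  trt <- rep(c("a", "b", "c"), each = n_per)
  year <- rep(rep(2001:2002, length.out = n_per), 3)
  Y <- matrix(2, length(trt), n_sp)
  for (i in seq_along(trt)) {
    blk <- match(trt[i], c("a", "b", "c"))
    Y[i, ((blk - 1) * 3 + 1):(blk * 3)] <- strength
  }
  Y <- Y + matrix(rpois(length(Y), 1), nrow(Y))
  list(Y = Y, trt = trt, year = year)
}

test_that("square-root transform is exact and applied once", {
  expect_equal(sqrt_transform(c(0, 4, 16)), c(0, 2, 4), ignore_attr = TRUE)
  expect_error(sqrt_transform(-1), class = "recolonize_param_error")
  expect_false(isTRUE(all.equal(sqrt_transform(sqrt_transform(16)),
                                sqrt_transform(16))))
})

test_that("inertia decomposition closes and matches vegan exactly", {
  skip_if_not_installed("vegan")
  layout <- experiment_layout()
  pl <- simulate_plants(layout, plant_sim_params(), seed = 72)
  d <- pl[pl$season == "summer", ]
  Y <- sqrt_transform(d[, grep("^sp", names(pl))])
  res <- pcca(Y, d$treatment, d$year)
  expect_equal(res$conditional_inertia + res$constrained_inertia +
                 res$residual_inertia, res$total_inertia, tolerance = 1e-9)
  m <- vegan::cca(Y, stats::model.matrix(~ factor(d$treatment))[, -1],
                  stats::model.matrix(~ factor(d$year))[, -1])
  expect_equal(res$total_inertia, m$tot.chi, tolerance = 1e-10)
  expect_equal(res$conditional_inertia, m$pCCA$tot.chi, tolerance = 1e-10)
  expect_equal(res$constrained_inertia, m$CCA$tot.chi, tolerance = 1e-10)
  expect_equal(res$residual_inertia, m$CA$tot.chi, tolerance = 1e-10)
  expect_equal(sort(res$eig, decreasing = TRUE),
               unname(m$CCA$eig), tolerance = 1e-10)
})

test_that("R2 is invariant to rescaling all abundances", {
  b <- block_table()
  r1 <- pcca(b$Y, b$trt, b$year)
  r2 <- pcca(b$Y * 37, b$trt, b$year)
  expect_equal(r1$R2, r2$R2, tolerance = 1e-12)
  expect_equal(r1$total_inertia, r2$total_inertia, tolerance = 1e-12)
})

test_that("plain CCA (empty condition) matches a direct eigen oracle", {
  b <- block_table(seed = 73)
  res <- pcca(b$Y, b$trt, condition = NULL)
  # direct oracle: weighted projection of the standardized matrix
  Y <- b$Y
  P <- Y / sum(Y)
  r <- rowSums(P)
  cm <- colSums(P)
  Q <- (P - outer(r, cm)) / sqrt(outer(r, cm))
  X <- model.matrix(~ factor(b$trt)) * sqrt(r)
  H <- X %*% solve(crossprod(X), t(X))
  fit <- H %*% Q
  expect_equal(res$constrained_inertia, sum(fit^2), tolerance = 1e-10)
  ev <- eigen(crossprod(fit), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(res$eig, decreasing = TRUE), ev[seq_along(res$eig)],
               tolerance = 1e-10)
})

test_that("treatment-determined composition yields R2 near 1 and minimal p", {
  b <- block_table()
  res <- pcca(b$Y, b$trt, b$year)
  expect_gt(res$R2, 0.95)
  pt <- permutation_test(b$Y, b$trt, b$year, n_perm = 199, seed = 2)
  expect_equal(pt$perm_p, 1 / 200)
  pt2 <- permutation_test(b$Y, b$trt, b$year, n_perm = 199, seed = 2)
  expect_identical(pt$perm_p, pt2$perm_p)
  expect_identical(pt$F_perm, pt2$F_perm)
})

test_that("degenerate and collinear inputs are rejected with clear errors", {
  Y <- matrix(5, 10, 4)
  expect_error(pcca(Y, rep(c("a", "b"), 5), NULL),
               class = "recolonize_degenerate_error")
  b <- block_table()
  expect_error(pcca(b$Y, b$trt, condition = b$trt),
               class = "recolonize_param_error", regexp = "aliased")
  expect_error(permutation_test(b$Y, b$trt, b$year, n_perm = 9),
               class = "recolonize_param_error")
  yr1 <- c(2001, rep(2002, length(b$trt) - 1))
  expect_error(permutation_test(b$Y, b$trt, yr1, n_perm = 99,
                                scheme = "within_year"),
               class = "recolonize_param_error")
})

test_that("within-year permutation respects condition blocks", {
  b <- block_table()
  pt <- permutation_test(b$Y, b$trt, b$year, n_perm = 99, seed = 3,
                         scheme = "within_year")
  expect_true(pt$perm_p <= 0.05)
  expect_equal(pt$scheme, "within_year")
})

test_that("seasonal wrapper reports one result per season", {
  layout <- experiment_layout()
  pl <- simulate_plants(layout, plant_sim_params(), seed = 74)
  res <- plant_pcca(pl, n_perm = 99, seed = 4)
  expect_setequal(res$summary$season, c("winter", "summer"))
  expect_true(all(res$summary$perm_p >= 1 / 100 & res$summary$perm_p <= 1))
  expect_true(all(res$summary$R2 > 0 & res$summary$R2 < 1))
})
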