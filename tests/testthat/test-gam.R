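test_that("unpenalized Gaussian-identity fit equals ordinary least squares", {
  set.seed(21)
  # plot smooths omitted: at lambda = 0 they are exactly collinear with the
  # treatment smooths (both spaces contain the centered linear trend)
  d <- expand.grid(month = 0:29, treatment = c("A", "B"))
  d$count <- rnorm(nrow(d), 3 + 0.1 * d$month)
  f <- fit_gam(d, family = "gaussian", k_treatment = 6, plot = NULL,
               select = "none", lambda = 0)
  X <- f$design$X
  ls <- lm.fit(X, d$count)
  expect_lt(max(abs(f$fitted - ls$fitted.values)), 1e-8)
  # V_beta reduces to the unpenalized covariance at lambda = 0
  sigma2 <- sum(ls$residuals^2) / (nrow(X) - ncol(X))
  V_ls <- chol2inv(chol(crossprod(X))) * sigma2
  expect_lt(max(abs(f$V_beta - V_ls)), 1e-6 * max(abs(V_ls)))
})

test_that("constant Poisson response shrinks all smooths away", {
  d <- expand.grid(plot = c("p1", "p2"), month = 0:49)
  d$treatment <- "A"
  d$count <- 5L
  f <- fit_gam(d, k_treatment = 10, k_plot = 6)
  expect_true(all(f$edf < 0.01))
  expect_lt(abs(f$beta[["intercept.A"]] - log(5)), 1e-3)
})

test_that("all-zero response is flagged as degenerate", {
  d <- data.frame(month = 0:30, treatment = "A", count = 0L)
  expect_error(fit_gam(d, plot = NULL, k_treatment = 5),
               class = "recolonize_degenerate_error")
})

test_that("a known smooth is recovered near the information bound", {
  # Poisson counts from log mu(t) = 1 + sin(2 pi t / 12): with mean counts
  # near 3 the pointwise posterior sd is ~0.12-0.15, so the max error over
  # a dense grid concentrates around 0.25-0.35 (mgcv attains the same)
  set.seed(1)
  t <- seq(0, 24, length.out = 200)
  truth <- 1 + sin(2 * pi * t / 12)
  d <- data.frame(month = t, treatment = "A", count = rpois(200, exp(truth)))
  f <- fit_gam(d, plot = NULL, k_treatment = 10)
  err <- max(abs(predict_treatment_curve(f, "A", t)$estimate - truth))
  expect_lt(err, 0.35)
  expect_gt(f$edf[["s(time):A"]], 3)  # the oscillation is actually tracked
})

test_that("fitter agrees with an independent GAM implementation", {
  skip_if_not_installed("mgcv")
  set.seed(22)
  t <- seq(0, 24, length.out = 150)
  truth <- 1.5 + 0.8 * sin(2 * pi * t / 12)
  y <- rpois(150, exp(truth))
  d <- data.frame(month = t, treatment = "A", count = y)
  f <- fit_gam(d, plot = NULL, k_treatment = 10)
  m <- mgcv::gam(y ~ s(t, k = 10), family = stats::poisson())
  mine <- predict_treatment_curve(f, "A", t)$estimate
  theirs <- as.numeric(mgcv::predict.gam(m, type = "link"))
  # smoothing-parameter selection differs (in-package GCV vs mgcv's exact
  # machinery); curves should agree to well within one posterior sd
  expect_lt(max(abs(mine - theirs)), 0.25)
})

test_that("Tweedie scale is recovered from compound Poisson-gamma data", {
  set.seed(23)
  n <- 500
  t <- seq(0, 24, length.out = n)
  mu <- exp(1.5 + 0.5 * sin(2 * pi * t / 12))
  phi <- 2
  pw <- 1.5
  lam <- mu^(2 - pw) / (phi * (2 - pw))
  N <- rpois(n, lam)
  y <- vapply(seq_len(n), function(i) {
    if (N[i] == 0) 0 else {
      sum(rgamma(N[i], shape = (2 - pw) / (pw - 1),
                 scale = phi * (pw - 1) * mu[i]^(pw - 1)))
    }
  }, 0)
  d <- data.frame(month = t, treatment = "A", E = y)
  f <- fit_gam(d, response = "E", family = "tweedie", plot = NULL,
               k_treatment = 10, tweedie_power = pw)
  expect_lt(abs(f$phi - phi) / phi, 0.25)
  expect_true(any(y == 0))  # exact zeros handled by the log-link fit
})

test_that("adding a smooth never increases the unpenalized deviance", {
  set.seed(24)
  d <- data.frame(month = 0:59, treatment = "A",
                  count = rpois(60, exp(1 + 0.3 * sin((0:59) / 4))))
  f <- fit_gam(d, plot = NULL, k_treatment = 8, select = "none", lambda = 0)
  expect_lte(f$deviance, f$null_deviance + 1e-8)
})

test_that("standard errors are positive and widest at the range edges", {
  set.seed(25)
  t <- seq(0, 36, length.out = 120)
  d <- data.frame(month = t, treatment = "A",
                  count = rpois(120, exp(1 + 0.5 * cos(t / 5))))
  f <- fit_gam(d, plot = NULL, k_treatment = 10)
  pc <- predict_treatment_curve(f, "A", t)
  expect_true(all(pc$se > 0))
  interior <- pc$se[t > 6 & t < 30]
  expect_gt(pc$se[1], stats::median(interior))
  expect_gt(pc$se[length(t)], stats::median(interior))
  # prediction at a fitted point reproduces the linear predictor
  expect_lt(max(abs(pc$estimate - f$linear_predictor)), 1e-10)
  expect_error(predict_treatment_curve(f, "C", 0:10),
               class = "recolonize_param_error")
  expect_error(predict_treatment_curve(f, "A", 40),
               class = "recolonize_param_error")
})

test_that("treatment curves cover the generating trajectory", {
  layout <- experiment_layout()
  params <- trajectory_params()
  counts <- simulate_counts(layout, params, seed = 31)
  f <- fit_gam(counts)
  grid <- layout$census_months
  covered <- 0L
  total <- 0L
  lm_df <- latent_mean(layout, params, months = grid)
  for (trt in c("control", "kr_plus", "rodent_plus")) {
    truth <- log(lm_df$mu[lm_df$treatment == trt])
    pc <- predict_treatment_curve(f, trt, grid)
    hit <- truth >= pc$estimate - 1.96 * pc$se &
      truth <= pc$estimate + 1.96 * pc$se
    covered <- covered + sum(hit)
    total <- total + length(hit)
  }
  expect_gte(covered / total, 0.85)
})
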