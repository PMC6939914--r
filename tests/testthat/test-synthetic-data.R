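test_that("layout validates its invariants", {
  layout <- experiment_layout()
  expect_s3_class(layout, "experiment_layout")
  expect_equal(unname(table(layout$treatment_of_plot)[c("control", "kr_plus",
                                                        "rodent_plus")]),
               c(4L, 3L, 3L), ignore_attr = TRUE)
  expect_error(experiment_layout(n_control = 1), class = "recolonize_param_error")
  expect_error(experiment_layout(change_month = 0),
               class = "recolonize_param_error")
  expect_error(experiment_layout(change_month = 71),
               class = "recolonize_param_error")
  expect_error(trajectory_params(control_level = 0),
               class = "recolonize_param_error")
})

test_that("count simulation is deterministic under a fixed seed", {
  layout <- experiment_layout()
  a <- simulate_counts(layout, trajectory_params(), seed = 11)
  b <- simulate_counts(layout, trajectory_params(), seed = 11)
  expect_identical(a, b)
  c <- simulate_counts(layout, trajectory_params(), seed = 12)
  expect_false(identical(a, c))
})

test_that("degenerate trajectory parameters collapse all treatments", {
  layout <- experiment_layout()
  lvl <- 6
  params <- trajectory_params(
    control_level = lvl,
    prechange_level = c(kr_plus = lvl, rodent_plus = lvl),
    recovery_delay = c(kr_plus = 0, rodent_plus = 0),
    recovery_rate = c(kr_plus = 1e6, rodent_plus = 1e6),
    overshoot_amplitude = c(kr_plus = 0, rodent_plus = 0),
    plot_sd = 0)
  counts <- simulate_counts(layout, params, seed = 3)
  mu <- latent_mean(layout, params)
  expect_true(all(abs(mu$mu - lvl) < 1e-9))
  se <- sqrt(lvl / nrow(counts))
  expect_lt(abs(mean(counts$count) - lvl), 3 * se)
})

test_that("latent mean equals the pre-change level until the delay elapses", {
  layout <- experiment_layout()
  params <- trajectory_params(recovery_delay = c(kr_plus = 12,
                                                 rodent_plus = 0))
  mu <- latent_mean(layout, params, months = layout$change_month + 1)
  kr <- mu$mu[mu$treatment == "kr_plus"]
  expect_equal(kr, unname(params$prechange_level[["kr_plus"]]))
  ctrl <- mu$mu[mu$treatment == "control"]
  expect_equal(ctrl, params$control_level)
  # after the delay the mean rises strictly toward the control level
  mu2 <- latent_mean(layout, params,
                     months = layout$change_month + 12 + c(1, 6, 18))
  kr2 <- mu2$mu[mu2$treatment == "kr_plus"]
  expect_true(all(diff(kr2) > 0))
  expect_lt(max(kr2), params$control_level + 1e-9)
})

test_that("count marginals recover the latent mean when plot_sd = 0", {
  layout <- experiment_layout(n_control = 30, n_kr_plus = 2,
                              n_rodent_plus = 2, n_months = 40,
                              change_month = 20)
  params <- trajectory_params(control_level = 5, plot_sd = 0)
  counts <- simulate_counts(layout, params, seed = 8)
  ctrl <- counts[counts$treatment == "control", ]
  for (m in c(0, 15, 35)) {
    x <- ctrl$count[ctrl$month == m]
    expect_lt(abs(mean(x) - 5), 3 * sqrt(5 / length(x)))
  }
})

test_that("capture histories obey the simulation contract", {
  layout <- experiment_layout()
  # near-certain survival and detection, identity movement
  eps <- 1e-12
  ip <- individual_sim_params(S = c(control = 1 - eps, kr_plus = 1 - eps,
                                    rodent_plus = 1 - eps),
                              p = c(control = 1 - eps, kr_plus = 1 - eps,
                                    rodent_plus = 1 - eps),
                              Psi = diag(3))
  h <- simulate_histories(layout, ip, 100, seed = 4, n_occasions = 6)
  mat <- h$histories
  for (i in seq_len(nrow(mat))) {
    f <- h$first[i]
    expect_true(all(mat[i, seq_len(f - 1)] == 0L) || f == 1L)
    expect_true(all(mat[i, f:6] == mat[i, f]))  # constant stratum, always seen
  }
  # near-zero survival: no individual detected twice
  ip0 <- individual_sim_params(S = c(control = eps, kr_plus = eps,
                                     rodent_plus = eps),
                               p = c(control = 0.5, kr_plus = 0.5,
                                     rodent_plus = 0.5),
                               Psi = diag(3))
  h0 <- simulate_histories(layout, ip0, 200, seed = 5, n_occasions = 6)
  expect_true(all(rowSums(h0$histories > 0L) == 1L))
  expect_error(
    individual_sim_params(Psi = matrix(c(0.6, 0.3, 0.2, 0.8), 2)),
    class = "recolonize_param_error")
})

test_that("observed return rate matches enumerated expectation (T = 3)", {
  layout <- experiment_layout()
  S <- 0.8
  p <- 0.5
  ip <- individual_sim_params(S = c(control = S, kr_plus = S,
                                    rodent_plus = S),
                              p = c(control = p, kr_plus = p,
                                    rodent_plus = p),
                              Psi = random_psi(3))
  n <- 5000
  h <- simulate_histories(layout, ip, n, seed = 6, n_occasions = 3)
  redetected <- rowSums(h$histories > 0L) > 1L
  # enumerated: entry at occ 1 -> S p + S(1-p)S p ; entry at occ 2 -> S p
  p1 <- S * p + S * (1 - p) * S * p
  p2 <- S * p
  expected <- mean(c(p1, p2))  # entry occasion uniform on {1, 2}
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(mean(redetected) - expected), 3 * se)
})

test_that("plant simulation carries a weak treatment and strong year signal", {
  layout <- experiment_layout()
  expect_error(plant_sim_params(n_species = 1),
               class = "recolonize_param_error")
  expect_error(simulate_plants(layout, plant_sim_params(), years = 2011,
                               seed = 1),
               class = "recolonize_param_error")
  pl <- simulate_plants(layout, plant_sim_params(), seed = 10)
  expect_identical(pl, simulate_plants(layout, plant_sim_params(), seed = 10))
  sp <- grep("^sp", names(pl))
  expect_true(all(pl[, sp] >= 0))
  expect_true(all(pl[, sp] == round(pl[, sp])))

  # no treatment effect: pCCA R2 vanishes with many quadrats
  p0 <- plant_sim_params(treatment_effect_sd = 0, quadrats_per_plot = 150)
  pl0 <- simulate_plants(layout, p0, seed = 11)
  d <- pl0[pl0$season == "winter", ]
  r0 <- pcca(sqrt_transform(d[, sp]), d$treatment, d$year)
  expect_lt(r0$R2, 0.01)

  # no year effect: conditioning on year removes almost nothing
  p1 <- plant_sim_params(year_effect_sd = 0, treatment_effect_sd = 0.8)
  pl1 <- simulate_plants(layout, p1, seed = 12)
  d1 <- pl1[pl1$season == "winter", ]
  r1 <- pcca(sqrt_transform(d1[, sp]), d1$treatment, d1$year)
  expect_lt(r1$conditional_inertia / r1$total_inertia, 0.05)
})

test_that("simulated captures form a consistent record table", {
  layout <- experiment_layout(n_months = 24, change_month = 12)
  caps <- simulate_captures(layout, trajectory_params(),
                            granivore_trajectory(), seed = 13)
  expect_true(all(c("period", "plot", "treatment", "species", "tag",
                    "mass_g") %in% names(caps)))
  expect_true(all(caps$mass_g > 0))
  expect_identical(caps, simulate_captures(layout, trajectory_params(),
                                           granivore_trajectory(), seed = 13))
  # a tag keeps one species
  tab <- tapply(caps$species, caps$tag, function(x) length(unique(x)))
  expect_true(all(tab == 1L))
})
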