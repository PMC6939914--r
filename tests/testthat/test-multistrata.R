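test_that("single-path histories have closed-form probabilities", {
  pars <- multistrata_params(S = 0.8, p = 0.5, Psi = matrix(1))
  expect_equal(history_likelihood(c(1, 1), pars), 0.8 * 1 * 0.5)
  pars2 <- multistrata_params(
    S = c(A = 0.8, B = 0.8), p = c(A = 0.5, B = 0.5),
    Psi = matrix(c(0.7, 0.3, 0.3, 0.7), 2, byrow = TRUE))
  # latent paths A->A->B and A->B->B
  expect_equal(history_likelihood(c(1, 0, 2), pars2), 0.0672)
  expect_error(history_likelihood(c(0, 0, 0), pars2),
               class = "recolonize_param_error")
})

test_that("forward recursion equals brute-force path enumeration", {
  set.seed(61)
  for (rep in 1:150) {
    K <- sample(1:3, 1)
    T_ <- sample(2:5, 1)
    S <- runif(K, 0.05, 0.95)
    p <- runif(K, 0.05, 0.95)
    Psi <- random_psi(K)
    pars <- multistrata_params(S, p, Psi)
    first <- sample.int(T_ - 1L, 1)
    h <- integer(T_)
    h[first] <- sample.int(K, 1)
    for (t in (first + 1):T_) h[t] <- sample(0:K, 1)
    expect_equal(history_likelihood(h, pars),
                 brute_force_history_prob(h, S, p, Psi), tolerance = 1e-12)
  }
})

test_that("conditional history probabilities are a proper distribution", {
  set.seed(62)
  for (rep in 1:20) {
    K <- sample(1:3, 1)
    T_ <- sample(2:4, 1)
    pars <- multistrata_params(runif(K, 0.1, 0.9), runif(K, 0.1, 0.9),
                               random_psi(K))
    first <- sample.int(T_ - 1L, 1)
    s0 <- sample.int(K, 1)
    hs <- enumerate_histories(T_, K, first, s0)
    total <- sum(vapply(hs, history_likelihood, 0, params = pars))
    expect_equal(total, 1, tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to permuting stratum labels", {
  set.seed(63)
  K <- 3
  S <- runif(K, 0.2, 0.9)
  p <- runif(K, 0.2, 0.9)
  Psi <- random_psi(K)
  h <- c(0L, 2L, 0L, 3L, 1L)
  perm <- c(3L, 1L, 2L)
  hp <- c(0L, perm)[h + 1L]
  pars <- multistrata_params(S, p, Psi)
  inv <- order(perm)
  pars_p <- multistrata_params(S[inv], p[inv], Psi[inv, inv])
  expect_equal(history_likelihood(h, pars),
               history_likelihood(hp, pars_p), tolerance = 1e-12)
})

test_that("single-stratum fit matches an independent CJS oracle", {
  layout <- experiment_layout()
  eps <- 1e-12
  ip <- individual_sim_params(S = c(control = 0.8, kr_plus = 0.8,
                                    rodent_plus = 0.8),
                              p = c(control = 0.5, kr_plus = 0.5,
                                    rodent_plus = 0.5),
                              Psi = diag(3))
  h3 <- simulate_histories(layout, ip, 600, seed = 64, n_occasions = 7)
  # collapse to a single stratum
  mat <- h3$histories
  mat[mat > 0L] <- 1L
  h1 <- capture_histories(mat, strata = "all")
  fit <- fit_multistrata(h1, S_varies = FALSE, p_varies = FALSE,
                         Psi_varies = FALSE, n_restarts = 1)
  # independent CJS maximum likelihood on the logit scale
  cjs_nll <- function(th) {
    -cjs_loglik(mat, plogis(th[1]), plogis(th[2]))
  }
  opt <- optim(c(0, 0), cjs_nll, method = "BFGS")
  expect_equal(unname(fit$params$S[1]), plogis(opt$par[1]), tolerance = 1e-6)
  expect_equal(unname(fit$params$p[1]), plogis(opt$par[2]), tolerance = 1e-6)
  expect_equal(fit$loglik, -opt$value, tolerance = 1e-6)
})

test_that("parameters are recovered from simulated two-stratum histories", {
  layout <- experiment_layout()
  truth_S <- c(control = 0.9, kr_plus = 0.5, rodent_plus = 0.7)
  truth_p <- c(control = 0.5, kr_plus = 0.5, rodent_plus = 0.5)
  Psi <- matrix(c(0.8, 0.1, 0.1,
                  0.15, 0.8, 0.05,
                  0.1, 0.1, 0.8), 3, byrow = TRUE)
  ip <- individual_sim_params(truth_S, truth_p, Psi)
  h <- simulate_histories(layout, ip, 1500, seed = 65, n_occasions = 8)
  fit <- fit_multistrata(h, S_varies = TRUE, p_varies = FALSE,
                         Psi_varies = TRUE, n_restarts = 1)
  expect_true(all(abs(fit$params$S - truth_S) < 0.08))
  expect_true(all(abs(fit$params$p - truth_p) < 0.08))
  expect_true(all(abs(fit$params$Psi - Psi) < 0.08))
  expect_true(all(abs(rowSums(fit$params$Psi) - 1) < 1e-10))
})

test_that("AIC selection prefers the smaller model on ties", {
  mk <- function(aic, k) structure(list(AIC = aic, n_params = k),
                                   class = "multistrata_fit")
  expect_equal(select_model(list(mk(100, 3), mk(98, 5), mk(105, 2)))$AIC, 98)
  tie <- select_model(list(mk(100, 5), mk(100, 3)))
  expect_equal(tie$n_params, 3)
  expect_error(select_model(list()), class = "recolonize_param_error")
})

test_that("new-individual tabulation counts each tag once", {
  caps <- data.frame(
    period = c(27, 30, 40, 27, 50, 20),
    plot = c("P2", "P2", "P2", "P5", "P5", "P1"),
    treatment = c("control", "control", "control", "kr_plus", "kr_plus",
                  "control"),
    species = "DM",
    tag = c("x", "x", "x", "y", "y", "z"),
    stringsAsFactors = FALSE)
  out <- tabulate_new_individuals(caps, change_month = 26)
  expect_equal(sum(out$influx$n_new), 3)
  x_row <- out$influx[out$influx$plot == "P2" & out$influx$n_new > 0, ]
  expect_equal(x_row$year_since_change, 0L)  # first capture wins
  z_row <- out$influx[out$influx$plot == "P1" & out$influx$n_new > 0, ]
  expect_equal(z_row$year_since_change, -1L)
  empty <- tabulate_new_individuals(caps[0, ], change_month = 26)
  expect_equal(nrow(empty$influx), 0L)
})

test_that("tabulation agrees with a first-occurrence scan on simulated data", {
  layout <- experiment_layout(n_months = 30, change_month = 15)
  caps <- simulate_captures(layout, trajectory_params(),
                            granivore_trajectory(), seed = 66)
  out <- tabulate_new_individuals(caps, change_month = 15)
  # oracle: scan records in time order, count unseen tags
  caps_o <- caps[order(caps$period), ]
  seen <- character(0)
  counts <- list()
  for (i in seq_len(nrow(caps_o))) {
    if (!(caps_o$tag[i] %in% seen)) {
      seen <- c(seen, caps_o$tag[i])
      key <- paste(caps_o$plot[i], floor((caps_o$period[i] - 15) / 12))
      counts[[key]] <- (counts[[key]] %||% 0) + 1
    }
  }
  for (i in seq_len(nrow(out$influx))) {
    key <- paste(out$influx$plot[i], out$influx$year_since_change[i])
    expect_equal(out$influx$n_new[i], counts[[key]] %||% 0)
  }
  expect_equal(sum(out$influx$n_new), length(seen))
})

test_that("MARK-style .inp files round-trip", {
  layout <- experiment_layout()
  h <- simulate_histories(layout, individual_sim_params(), 40, seed = 67,
                          n_occasions = 6)
  path <- withr::local_tempfile(fileext = ".inp")
  write_inp(h, path)
  lines <- readLines(path)
  expect_match(lines[1], "^[A-C0]{6} 1;$")
  h2 <- read_inp(path, strata = h$strata)
  expect_identical(h2$histories, unname(h$histories))
})
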