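`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracles used across tests.  These deliberately share no code
# with the package internals they check.

# Brute-force multistate history probability: enumerate every latent
# trajectory (including death times) from the first capture onward.
brute_force_history_prob <- function(h, S, p, Psi) {
  T_ <- length(h)
  first <- which(h > 0)[1L]
  K <- length(S)
  rec <- function(t, state) {
    if (t == T_) return(1)
    rest_blank <- all(h[(t + 1L):T_] == 0L)
    total <- 0
    # dies in this interval: all later occasions must be non-detections
    if (rest_blank) total <- total + (1 - S[state])
    for (j in seq_len(K)) {
      obs <- h[t + 1L]
      det_prob <- if (obs == 0L) 1 - p[j] else if (obs == j) p[j] else 0
      if (det_prob > 0) {
        total <- total + S[state] * Psi[state, j] * det_prob * rec(t + 1L, j)
      }
    }
    total
  }
  rec(first, h[first])
}

# All possible observation sequences following a first capture at occasion
# `first` in stratum `s0`, for T occasions and K strata.
enumerate_histories <- function(T_, K, first, s0) {
  tails <- list(integer(0))
  for (t in seq_len(T_ - first)) {
    tails <- unlist(lapply(tails, function(x) {
      lapply(0:K, function(v) c(x, v))
    }), recursive = FALSE)
  }
  lapply(tails, function(tl) c(rep(0L, first - 1L), s0, tl))
}

# Independent single-stratum Cormack-Jolly-Seber history log-likelihood via
# the chi (never-seen-again) recursion.
cjs_loglik <- function(histmat, S, p) {
  T_ <- ncol(histmat)
  chi <- numeric(T_)
  chi[T_] <- 1
  for (t in (T_ - 1L):1L) chi[t] <- (1 - S) + S * (1 - p) * chi[t + 1L]
  sum(apply(histmat, 1L, function(h) {
    det <- which(h > 0)
    f <- det[1L]
    l <- det[length(det)]
    ll <- 0
    if (l > f) {
      for (t in (f + 1L):l) {
        ll <- ll + log(S) + if (h[t] > 0) log(p) else log(1 - p)
      }
    }
    ll + log(chi[l])
  }))
}

# Random row-stochastic transition matrix.
random_psi <- function(K) {
  m <- matrix(stats::runif(K * K, 0.05, 1), K, K)
  m / rowSums(m)
}

# Small capture-record table used by energetics and influx tests.
toy_captures <- function() {
  data.frame(
    period = c(0, 0, 0, 1, 1, 13, 13, 25),
    plot = c("P1", "P1", "P1", "P2", "P1", "P1", "P2", "P2"),
    treatment = c("control", "control", "control", "kr_plus", "control",
                  "control", "kr_plus", "kr_plus"),
    species = c("DM", "DM", "DO", "DM", "DS", "DM", "DO", "DO"),
    tag = c("a", "b", "c", "d", "e", "a", "f", "f"),
    mass_g = c(16, 16, 81, 45, 120, 17, 50, 52),
    stringsAsFactors = FALSE)
}

# Two artificial treatments (3 plots each) sharing one seasonal latent
# trajectory, optionally offset on the log scale.
make_two_treatment_fit <- function(seed = 41, offset = 0, n_months = 48,
                                   family = "poisson") {
  set.seed(seed)
  d <- expand.grid(plot = paste0("p", 1:6), month = 0:(n_months - 1))
  d$treatment <- rep(c("A", "B"), each = 3)[match(d$plot, paste0("p", 1:6))]
  eta <- 1.5 + 0.4 * sin(2 * pi * d$month / 12) +
    ifelse(d$treatment == "B", offset, 0)
  d$count <- rpois(nrow(d), exp(eta))
  fit_gam(d, k_treatment = 10, k_plot = 5, family = family)
}

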