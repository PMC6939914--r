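#' Multistate capture-recapture parameters
#'
#' @param S named per-stratum apparent-survival probabilities in (0,1).
#' @param p named per-stratum recapture probabilities in (0,1).
#' @param Psi row-stochastic stratum-transition matrix (rows sum to 1
#'   within 1e-10).
#' @return An object of class \code{"multistrata_params"}.
#' @export
multistrata_params <- function(S, p, Psi) {
  Psi <- as.matrix(Psi)
  K <- length(S)
  if (length(p) != K || !identical(dim(Psi), c(K, K))) {
    stop_param("S, p and Psi must agree on the number of strata")
  }
  if (any(S <= 0 | S >= 1) || any(p <= 0 | p >= 1)) {
    stop_param("S and p must lie in (0,1)")
  }
  if (any(Psi < 0) || any(abs(rowSums(Psi) - 1) > 1e-10)) {
    stop_param("Psi rows must sum to 1 (within 1e-10)")
  }
  strata <- names(S) %||% LETTERS[seq_len(K)]
  names(S) <- names(p) <- strata
  dimnames(Psi) <- list(strata, strata)
  structure(list(S = S, p = p, Psi = Psi, strata = strata),
            class = "multistrata_params")
}

# Vectorized forward recursion over latent strata for all histories at once.
# hist: n x T integer matrix (0 = non-detection); first: first-detection
# occasion per row.  Events per interval: survive (S of current stratum),
# move (Psi row), detect (p of destination stratum).  Returns per-history
# log-probability conditioned on first capture.
ms_forward_loglik <- function(hist, first, S, p, Psi) {
  n <- nrow(hist)
  T_ <- ncol(hist)
  K <- length(S)
  alpha <- matrix(0, n, K)
  dead <- numeric(n)
  alpha[cbind(seq_len(n), hist[cbind(seq_len(n), first)])] <- 1
  if (T_ >= 2) {
    for (t in 2:T_) {
      act <- which(first < t)
      if (!length(act)) next
      a <- alpha[act, , drop = FALSE]
      dead[act] <- dead[act] + drop(a %*% (1 - S))
      a <- (a %*% (Psi * S))          # (diag(S) %*% Psi) applied to rows
      obs <- hist[act, t]
      det <- obs > 0L
      if (any(det)) {
        rows <- act[det]
        s <- obs[det]
        newa <- matrix(0, length(rows), K)
        newa[cbind(seq_along(rows), s)] <- a[det, , drop = FALSE][
          cbind(seq_along(rows), s)] * p[s]
        alpha[rows, ] <- newa
        dead[rows] <- 0
      }
      if (any(!det)) {
        rows <- act[!det]
        alpha[rows, ] <- a[!det, , drop = FALSE] *
          rep(1 - p, each = length(rows))
      }
    }
  }
  log(rowSums(alpha) + dead)
}

#' Probability of one capture history
#'
#' Likelihood of the post-first-capture observation sequence of a multistate
#' capture history, conditioned on the first capture, under the
#' Arnason-Schwarz model: per interval the animal survives with the current
#' stratum's \code{S}, moves along its \code{Psi} row, and is detected with
#' the destination stratum's \code{p}.  Latent strata during non-detection
#' occasions are marginalized by a forward recursion.
#'
#' @param h integer vector over occasions (0 = non-detection, positive =
#'   stratum index), or a single-row \code{\link{capture_histories}}.
#' @param params a \code{\link{multistrata_params}}.
#' @return Probability in (0, 1].
#' @examples
#' p <- multistrata_params(S = 0.8, p = 0.5, Psi = matrix(1))
#' history_likelihood(c(1, 1), p)   # 0.8 * 1 * 0.5
#' @export
history_likelihood <- function(h, params) {
  if (inherits(h, "capture_histories")) h <- h$histories[1L, ]
  h <- as.integer(h)
  if (all(h == 0L)) stop_param("history contains no detection")
  first <- which(h != 0L)[1L]
  exp(ms_forward_loglik(matrix(h, 1L), first, params$S, params$p, params$Psi))
}

# --- parameter packing on logit / multinomial-logit scales ----------------

ms_n_params <- function(K, S_varies, p_varies, Psi_varies) {
  (if (S_varies) K else 1L) + (if (p_varies) K else 1L) +
    (if (K > 1L) (if (Psi_varies) K * (K - 1L) else 1L) else 0L)
}

ms_unpack <- function(theta, K, S_varies, p_varies, Psi_varies) {
  i <- 0L
  nS <- if (S_varies) K else 1L
  S <- rep(stats::plogis(theta[i + seq_len(nS)]), length.out = K)
  i <- i + nS
  np <- if (p_varies) K else 1L
  p <- rep(stats::plogis(theta[i + seq_len(np)]), length.out = K)
  i <- i + np
  if (K == 1L) {
    Psi <- matrix(1, 1, 1)
  } else if (Psi_varies) {
    Psi <- matrix(0, K, K)
    for (k in seq_len(K)) {
      e <- exp(theta[i + seq_len(K - 1L)])
      i <- i + K - 1L
      Psi[k, -k] <- e / (1 + sum(e))
      Psi[k, k] <- 1 / (1 + sum(e))
    }
  } else {
    m <- stats::plogis(theta[i + 1L])
    i <- i + 1L
    Psi <- matrix(m / (K - 1L), K, K)
    diag(Psi) <- 1 - m
  }
  list(S = S, p = p, Psi = Psi)
}

#' Fit a multistate capture-recapture model
#'
#' Maximizes the Arnason-Schwarz likelihood over capture histories by
#' quasi-Newton (BFGS) search on logit (survival, recapture, shared
#' movement) and multinomial-logit (transition rows) scales, with seeded
#' random restarts to guard against local maxima.  Equality constraints
#' across strata are applied when a vary-flag is \code{FALSE}.
#'
#' @param histories a \code{\link{capture_histories}} object.
#' @param S_varies,p_varies,Psi_varies whether survival, recapture and
#'   transition structure differ by stratum.
#' @param start optional \code{\link{multistrata_params}} starting values.
#' @param n_restarts number of additional random starts.
#' @param seed seed for the random restarts.
#' @return An object of class \code{"multistrata_fit"} with the estimated
#'   \code{params}, standard errors (\code{se}, delta method from the
#'   inverse Hessian), \code{loglik}, \code{n_params}, \code{AIC}, the
#'   candidate flags and convergence information.  Estimates within 1e-4 of
#'   a boundary are flagged via \code{boundary}.
#' @export
fit_multistrata <- function(histories, S_varies = TRUE, p_varies = FALSE,
                            Psi_varies = TRUE, start = NULL, n_restarts = 3,
                            seed = 1) {
  if (!inherits(histories, "capture_histories")) {
    stop_param("'histories' must be a capture_histories object")
  }
  hist <- histories$histories
  if (ncol(hist) < 2L) stop_param("need at least 2 occasions")
  first <- histories$first
  K <- length(histories$strata)
  npar <- ms_n_params(K, S_varies, p_varies, Psi_varies)
  nll <- function(theta) {
    pr <- ms_unpack(theta, K, S_varies, p_varies, Psi_varies)
    -sum(ms_forward_loglik(hist, first, pr$S, pr$p, pr$Psi))
  }
  starts <- list(rep(0, npar))
  if (!is.null(start)) {
    starts[[1L]] <- ms_pack(start, S_varies, p_varies, Psi_varies)
  }
  set.seed(substream_seed(seed, 6L))
  for (r in seq_len(n_restarts)) {
    starts[[r + 1L]] <- stats::rnorm(npar, 0, 1)
  }
  best <- NULL
  for (th0 in starts) {
    opt <- tryCatch(
      stats::optim(th0, nll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-9) best <- opt
  }
  if (is.null(best)) {
    gr <- tryCatch(sqrt(sum(numeric_grad(nll, starts[[1L]])^2)),
                   error = function(e) NA_real_)
    stop(errorCondition(
      paste0("multistate likelihood maximization failed; gradient norm at ",
             "start: ", signif(gr, 4)),
      class = c("recolonize_convergence_error", "error")))
  }
  theta <- best$par
  pr <- ms_unpack(theta, K, S_varies, p_varies, Psi_varies)
  params <- multistrata_params(
    stats::setNames(pmin(pmax(pr$S, 1e-12), 1 - 1e-12), histories$strata),
    stats::setNames(pmin(pmax(pr$p, 1e-12), 1 - 1e-12), histories$strata),
    pr$Psi)
  H <- tryCatch(stats::optimHess(theta, nll), error = function(e) NULL)
  se_theta <- if (!is.null(H)) {
    Vt <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vt)) sqrt(pmax(diag(Vt), 0)) else rep(NA_real_, npar)
  } else rep(NA_real_, npar)
  boundary <- any(c(pr$S, pr$p) < 1e-4 | c(pr$S, pr$p) > 1 - 1e-4)
  if (boundary) warning("estimates at the parameter boundary (p or S near 0/1)")
  structure(
    list(params = params, theta = theta, se_theta = se_theta,
         loglik = -best$value, n_params = npar,
         AIC = 2 * npar + 2 * best$value,
         S_varies = S_varies, p_varies = p_varies, Psi_varies = Psi_varies,
         boundary = boundary, convergence = best$convergence,
         n_histories = nrow(hist), n_occasions = ncol(hist)),
    class = "multistrata_fit")
}

ms_pack <- function(params, S_varies, p_varies, Psi_varies) {
  K <- length(params$S)
  qS <- stats::qlogis(if (S_varies) params$S else mean(params$S))
  qp <- stats::qlogis(if (p_varies) params$p else mean(params$p))
  th <- c(qS, qp)
  if (K > 1L) {
    if (Psi_varies) {
      for (k in seq_len(K)) {
        th <- c(th, log(params$Psi[k, -k] / params$Psi[k, k]))
      }
    } else {
      th <- c(th, stats::qlogis(mean(1 - diag(params$Psi))))
    }
  }
  unname(th)
}

numeric_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x))
    e[i] <- eps
    (f(x + e) - f(x - e)) / (2 * eps)
  }, 0)
}

#' @export
print.multistrata_fit <- function(x, ...) {
  cat("Multistate capture-recapture fit (", x$n_histories, " histories, ",
      x$n_occasions, " occasions)\n", sep = "")
  cat("S(", if (x$S_varies) "strata" else ".", ") p(",
      if (x$p_varies) "strata" else ".", ") Psi(",
      if (x$Psi_varies) "strata" else ".", ")  logLik = ",
      signif(x$loglik, 7), "  AIC = ", signif(x$AIC, 7), "\n", sep = "")
  cat("S:\n"); print(round(x$params$S, 4))
  cat("p:\n"); print(round(x$params$p, 4))
  cat("Psi:\n"); print(round(x$params$Psi, 4))
  invisible(x)
}

#' Fit a candidate set of multistate models
#'
#' Fits every combination of the supplied vary-flags and returns the fits
#' with an AIC table.
#'
#' @param histories a \code{\link{capture_histories}}.
#' @param S_vary,Psi_vary,p_vary logical vectors of flags to cross.
#' @param ... passed to \code{\link{fit_multistrata}}.
#' @return List with \code{fits} (list of \code{multistrata_fit}) and
#'   \code{aic} (data frame sorted by AIC).
#' @export
multistrata_candidates <- function(histories, S_vary = c(TRUE, FALSE),
                                   Psi_vary = c(TRUE, FALSE),
                                   p_vary = FALSE, ...) {
  grid <- expand.grid(S = S_vary, Psi = Psi_vary, p = p_vary,
                      KEEP.OUT.ATTRS = FALSE)
  fits <- lapply(seq_len(nrow(grid)), function(i) {
    fit_multistrata(histories, S_varies = grid$S[i], p_varies = grid$p[i],
                    Psi_varies = grid$Psi[i], ...)
  })
  aic <- data.frame(
    model = vapply(fits, function(f) {
      paste0("S(", if (f$S_varies) "s" else ".", ")p(",
             if (f$p_varies) "s" else ".", ")Psi(",
             if (f$Psi_varies) "s" else ".", ")")
    }, ""),
    n_params = vapply(fits, `[[`, 0L, "n_params"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    AIC = vapply(fits, `[[`, 0, "AIC"))
  ord <- order(aic$AIC, aic$n_params)
  list(fits = fits[ord], aic = aic[ord, ])
}

#' Select the best model by AIC
#'
#' Returns the minimum-AIC candidate; ties (within \code{tol}) are broken
#' toward fewer parameters.
#'
#' @param candidates list of \code{\link{fit_multistrata}} results (or the
#'   \code{fits} element of \code{\link{multistrata_candidates}}).
#' @param tol AIC difference treated as a tie.
#' @return The selected \code{multistrata_fit}.
#' @export
select_model <- function(candidates, tol = 1e-9) {
  if (!length(candidates)) stop_param("no fitted candidates")
  aic <- vapply(candidates, function(x) as.numeric(x[["AIC"]]), 0)
  np <- vapply(candidates, function(x) as.numeric(x[["n_params"]]), 0)
  tied <- which(aic <= min(aic) + tol)
  candidates[[tied[which.min(np[tied])]]]
}

#' Tabulate new individuals per plot and year since the treatment change
#'
#' An individual is "new" at its first-ever capture and contributes to that
#' capture's plot and year-since-change.  Per-treatment yearly means are the
#' mean of plot totals within treatment and year (plots with no new
#' individuals in a year count as zero).
#'
#' @param captures data frame with columns \code{period}, \code{plot},
#'   \code{tag} and (optionally) \code{treatment}.
#' @param change_month month index of the treatment change.
#' @return List with \code{influx} (plot, year_since_change, n_new,
#'   treatment) and \code{means} (treatment, year_since_change, mean_new).
#' @export
tabulate_new_individuals <- function(captures, change_month) {
  if (!nrow(captures)) {
    return(list(influx = data.frame(plot = character(0),
                                    year_since_change = integer(0),
                                    n_new = integer(0),
                                    treatment = character(0)),
                means = data.frame(treatment = character(0),
                                   year_since_change = integer(0),
                                   mean_new = numeric(0))))
  }
  captures <- captures[order(captures$period), , drop = FALSE]
  tp <- captures[!duplicated(captures[, c("tag", "period", "plot")]), ,
                 drop = FALSE]
  n_anom <- sum(duplicated(tp[, c("tag", "period")]))
  if (n_anom > 0L) {
    message(n_anom, " tag(s) recorded in two plots in one census; ",
            "first record wins")
  }
  firsts <- captures[!duplicated(captures$tag), , drop = FALSE]
  firsts$year_since_change <-
    as.integer(floor((firsts$period - change_month) / 12))
  plot_trt <- unique(captures[, intersect(c("plot", "treatment"),
                                          names(captures)), drop = FALSE])
  years <- sort(unique(firsts$year_since_change))
  grid <- expand.grid(plot = unique(captures$plot),
                      year_since_change = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- as.data.frame(table(plot = firsts$plot,
                             year_since_change = firsts$year_since_change),
                       stringsAsFactors = FALSE)
  tab$year_since_change <- as.integer(tab$year_since_change)
  influx <- merge(grid, tab, by = c("plot", "year_since_change"), all.x = TRUE)
  influx$Freq[is.na(influx$Freq)] <- 0L
  names(influx)[names(influx) == "Freq"] <- "n_new"
  if ("treatment" %in% names(plot_trt)) {
    influx <- merge(influx, plot_trt, by = "plot")
    means <- stats::aggregate(n_new ~ treatment + year_since_change,
                              data = influx, FUN = mean)
    names(means)[names(means) == "n_new"] <- "mean_new"
  } else {
    means <- stats::aggregate(n_new ~ year_since_change, data = influx,
                              FUN = mean)
    names(means)[names(means) == "n_new"] <- "mean_new"
  }
  influx <- influx[order(influx$plot, influx$year_since_change), ]
  rownames(influx) <- NULL
  list(influx = influx, means = means)
}
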