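#' Fitting control parameters
#'
#' @param tol relative deviance-change convergence tolerance for the
#'   penalized IRLS loop.
#' @param maxit maximum IRLS iterations.
#' @param lambda_range range of log smoothing parameters searched.
#' @param select_tol relative tolerance on the selection criterion for the
#'   coordinate-wise smoothing-parameter search.
#' @param max_sweeps maximum coordinate-descent sweeps over the smoothing
#'   parameters.
#' @return List of control parameters.
#' @export
gam_control <- function(tol = 1e-8, maxit = 200, lambda_range = c(-10, 20),
                        select_tol = 1e-3, max_sweeps = 4) {
  list(tol = tol, maxit = maxit, lambda_range = lambda_range,
       select_tol = select_tol, max_sweeps = max_sweeps)
}

gam_family <- function(name, tweedie_power = 1.5) {
  switch(name,
    poisson = list(
      name = "poisson", link = "log",
      variance = function(mu) mu,
      dev = function(y, mu) {
        2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
      }),
    tweedie = {
      p <- tweedie_power
      if (p <= 1 || p >= 2) stop_param("tweedie_power must lie in (1, 2)")
      list(
        name = "tweedie", link = "log", power = p,
        variance = function(mu) mu^p,
        dev = function(y, mu) {
          2 * sum(y^(2 - p) / ((1 - p) * (2 - p)) -
                  y * mu^(1 - p) / (1 - p) + mu^(2 - p) / (2 - p))
        })
    },
    gaussian = list(
      name = "gaussian", link = "identity",
      variance = function(mu) rep(1, length(mu)),
      dev = function(y, mu) sum((y - mu)^2)),
    stop_param("unknown family: ", name))
}

# Penalized iteratively reweighted least squares for a log or identity link.
pirls <- function(X, y, Spen, fam, control, beta0 = NULL) {
  n <- nrow(X)
  p <- ncol(X)
  loglink <- fam$link == "log"
  if (loglink && all(y == 0)) {
    stop_degenerate("all-zero response: log-link fit is degenerate")
  }
  solve_penalized <- function(XtWX, XtWz) {
    ridge <- 0
    repeat {
      H <- XtWX + Spen + diag(ridge, p)
      R <- tryCatch(chol(H), error = function(e) NULL)
      if (!is.null(R)) {
        return(list(beta = backsolve(R, forwardsolve(t(R), XtWz)), H = H))
      }
      ridge <- if (ridge == 0) 1e-10 * mean(diag(XtWX) + 1) else ridge * 100
      if (ridge > 1e-2 * mean(diag(XtWX) + 1)) {
        stop("penalized normal equations are numerically singular")
      }
    }
  }
  if (is.null(beta0)) {
    eta <- if (loglink) log(pmax(y, 0.1 * mean(y[y > 0]))) else y
    beta <- NULL
  } else {
    beta <- beta0
    eta <- drop(X %*% beta)
  }
  dev <- Inf
  trace <- numeric(0)
  for (it in seq_len(control$maxit)) {
    mu <- if (loglink) exp(eta) else eta
    if (loglink) mu <- pmax(mu, 1e-10)
    w <- if (loglink) mu^2 / fam$variance(mu) else 1 / fam$variance(mu)
    z <- if (loglink) eta + (y - mu) / mu else y
    sw <- sqrt(w)
    XtWX <- crossprod(X * sw)
    XtWz <- crossprod(X, w * z)
    sol <- solve_penalized(XtWX, XtWz)
    beta_new <- drop(sol$beta)
    # step halving if the penalized deviance worsens
    step <- 1
    repeat {
      b <- if (is.null(beta)) beta_new else beta + step * (beta_new - beta)
      eta_new <- drop(X %*% b)
      mu_new <- if (loglink) pmax(exp(eta_new), 1e-10) else eta_new
      dev_new <- fam$dev(y, mu_new) + drop(crossprod(b, Spen %*% b))
      if (is.finite(dev_new) && (dev_new <= dev + 1e-10 || is.null(beta) ||
                                 step < 1 / 64)) break
      step <- step / 2
    }
    beta <- b
    eta <- eta_new
    trace <- c(trace, dev_new)
    if (is.finite(dev) && abs(dev - dev_new) < control$tol * (abs(dev_new) + 0.1)) {
      dev <- dev_new
      mu <- if (loglink) pmax(exp(eta), 1e-10) else eta
      w <- if (loglink) mu^2 / fam$variance(mu) else 1 / fam$variance(mu)
      XtWX <- crossprod(X * sqrt(w))
      return(list(beta = beta, eta = eta, mu = mu,
                  deviance = fam$dev(y, mu), penalized_deviance = dev,
                  XtWX = XtWX, H = XtWX + Spen, iterations = it,
                  converged = TRUE, trace = trace))
    }
    dev <- dev_new
  }
  stop(errorCondition(
    paste0("penalized IRLS did not converge in ", control$maxit,
           " iterations; deviance trace: ",
           paste(signif(utils::tail(trace, 5), 6), collapse = ", ")),
    class = c("recolonize_convergence_error", "error")))
}

# Assemble the model design: one intercept per treatment level, one centered
# treatment-specific smooth of time per level (own smoothing parameter), and
# optionally one shrinkage-penalized smooth per plot sharing a single
# smoothing parameter.
assemble_design <- function(time, treatment, plot, k_treatment, k_plot,
                            include_plot_smooths, penalty_order = 2) {
  treatment <- factor(treatment)
  n <- length(time)
  levs <- levels(treatment)
  blocks <- list()
  cols <- list()
  penalties <- list()   # one entry per smoothing parameter
  p0 <- 0L
  Xint <- outer(as.integer(treatment), seq_along(levs), `==`) * 1
  colnames(Xint) <- paste0("intercept.", levs)
  blocks[[length(blocks) + 1L]] <- list(type = "intercept", levels = levs,
                                        cols = p0 + seq_len(ncol(Xint)))
  cols[[length(cols) + 1L]] <- Xint
  p0 <- p0 + ncol(Xint)
  for (lev in levs) {
    idx <- which(treatment == lev)
    bb <- build_basis(time[idx], smooth_spec("time", by = lev,
                                             k = k_treatment,
                                             penalty_order = penalty_order))
    Xs <- matrix(0, n, ncol(bb$X))
    Xs[idx, ] <- bb$X
    colnames(Xs) <- paste0("s(time).", lev, ".", seq_len(ncol(Xs)))
    bcols <- p0 + seq_len(ncol(Xs))
    blocks[[length(blocks) + 1L]] <- list(type = "treatment_smooth",
                                          level = lev, basis = bb,
                                          cols = bcols,
                                          lambda_index = length(penalties) + 1L)
    penalties[[length(penalties) + 1L]] <- list(cols = bcols, S = bb$S,
                                                label = paste0("s(time):", lev))
    # double-penalty shrinkage: the penalty null space (linear trend) gets
    # its own selectable smoothing parameter, so a no-signal smooth can be
    # shrunk to exactly its intercept without biasing real trends
    if (!is.null(bb$M)) {
      penalties[[length(penalties) + 1L]] <-
        list(cols = bcols, S = bb$M,
             label = paste0("s(time):", lev, ":null"))
    }
    cols[[length(cols) + 1L]] <- Xs
    p0 <- p0 + ncol(Xs)
  }
  plot_lambda_index <- NULL
  if (include_plot_smooths && !is.null(plot)) {
    plot <- factor(plot)
    if (nlevels(plot) > 1L) {
      plot_lambda_index <- length(penalties) + 1L
      plot_pen_cols <- integer(0)
      plot_pen_S <- list()
      for (pl in levels(plot)) {
        idx <- which(plot == pl)
        bb <- build_basis(time[idx], smooth_spec("time", by = pl, k = k_plot,
                                                 penalty_order = penalty_order,
                                                 shrink = TRUE))
        Xs <- matrix(0, n, ncol(bb$X))
        Xs[idx, ] <- bb$X
        colnames(Xs) <- paste0("s(time).plot", pl, ".", seq_len(ncol(Xs)))
        bcols <- p0 + seq_len(ncol(Xs))
        blocks[[length(blocks) + 1L]] <- list(type = "plot_smooth", plot = pl,
                                              basis = bb, cols = bcols,
                                              lambda_index = plot_lambda_index)
        plot_pen_cols <- c(plot_pen_cols, bcols)
        plot_pen_S <- c(plot_pen_S, list(bb$S))
        cols[[length(cols) + 1L]] <- Xs
        p0 <- p0 + ncol(Xs)
      }
      Sp <- matrix(0, length(plot_pen_cols), length(plot_pen_cols))
      at <- 0L
      for (Sb in plot_pen_S) {
        ix <- at + seq_len(ncol(Sb))
        Sp[ix, ix] <- Sb
        at <- at + ncol(Sb)
      }
      penalties[[plot_lambda_index]] <- list(cols = plot_pen_cols, S = Sp,
                                             label = "s(time):plot (shared)")
    }
  }
  X <- do.call(cbind, cols)
  list(X = X, blocks = blocks, penalties = penalties, p = p0,
       treatment_levels = levs, time_range = range(time))
}

embed_penalties <- function(design, lambda) {
  p <- design$p
  Spen <- matrix(0, p, p)
  for (j in seq_along(design$penalties)) {
    pen <- design$penalties[[j]]
    Spen[pen$cols, pen$cols] <- Spen[pen$cols, pen$cols] + lambda[j] * pen$S
  }
  Spen
}

#' Fit a treatment-by-time generalized additive model
#'
#' Fits a GAM with log link (Poisson or Tweedie; Gaussian-identity is
#' provided for engine validation): one intercept per treatment, one
#' penalized cubic-spline smooth of time per treatment, and optionally one
#' shrinkage-penalized deviation smooth per plot sharing a single smoothing
#' parameter.  Smoothing parameters are selected by GCV (default) or an
#' approximate REML criterion, each minimized coordinate-wise by golden
#' search on the log scale with outer performance iterations.
#'
#' The returned Bayesian posterior covariance of the coefficients,
#' \eqn{V_\beta = (X'WX + \sum_j \lambda_j S_j)^{-1} \phi}, drives the
#' credible intervals of \code{\link{difference_smooth}}.
#'
#' @param data data frame of one row per plot and census month.
#' @param response name of the response column.
#' @param family \code{"poisson"} (counts), \code{"tweedie"} (non-negative
#'   flux with exact zeros) or \code{"gaussian"}.
#' @param time,treatment,plot names of the time, treatment and plot columns
#'   (\code{plot = NULL} drops plot smooths).
#' @param k_treatment,k_plot basis dimensions of treatment and plot smooths.
#' @param tweedie_power Tweedie variance power (1 < p < 2).
#' @param select smoothing-parameter selection criterion; \code{"none"}
#'   fixes them at \code{lambda}.
#' @param lambda fixed smoothing parameters (recycled) when
#'   \code{select = "none"}, otherwise used as the search start.
#' @param control a \code{\link{gam_control}} list.
#' @return An object of class \code{"treatment_gam"} with elements
#'   \code{beta}, \code{V_beta}, \code{lambda}, \code{phi}, \code{edf}
#'   (per smooth), \code{edf_total}, \code{deviance}, \code{null_deviance},
#'   \code{fitted}, design information, and the selection criterion value.
#' @seealso \code{\link{predict_treatment_curve}},
#'   \code{\link{difference_smooth}}
#' @export
fit_gam <- function(data, response = "count",
                    family = c("poisson", "tweedie", "gaussian"),
                    time = "month", treatment = "treatment", plot = "plot",
                    k_treatment = 20, k_plot = 8, tweedie_power = 1.5,
                    select = c("GCV", "REML", "none"), lambda = NULL,
                    control = gam_control()) {
  family <- match.arg(family)
  select <- match.arg(select)
  fam <- gam_family(family, tweedie_power)
  need <- c(response, time, treatment)
  if (!all(need %in% names(data))) {
    stop_param("data lacks columns: ",
               paste(setdiff(need, names(data)), collapse = ", "))
  }
  y <- data[[response]]
  if (any(y < 0)) stop_param("response must be non-negative")
  plot_vals <- if (!is.null(plot) && plot %in% names(data)) data[[plot]] else NULL
  design <- assemble_design(data[[time]], data[[treatment]], plot_vals,
                            k_treatment, k_plot,
                            include_plot_smooths = !is.null(plot_vals))
  X <- design$X
  n <- nrow(X)
  n_lambda <- length(design$penalties)
  rho <- rep(log(lambda %||% 1), length.out = max(n_lambda, 1L))
  warm <- new.env(parent = emptyenv())
  warm$beta <- NULL

  fit_at <- function(rho) {
    Spen <- embed_penalties(design, exp(rho))
    f <- pirls(X, y, Spen, fam, control, beta0 = warm$beta)
    warm$beta <- f$beta
    Rh <- tryCatch(chol(f$H), error = function(e) {
      chol(f$H + diag(1e-8 * mean(diag(f$H)), nrow(f$H)))
    })
    Finv_XtWX <- backsolve(Rh, forwardsolve(t(Rh), f$XtWX))
    f$edf_total <- sum(diag(Finv_XtWX))
    f$edf_diag <- diag(Finv_XtWX)
    f$Spen <- Spen
    f$Rh <- Rh
    f
  }
  criterion <- function(f, rho) {
    if (select == "REML") {
      phi <- if (fam$name == "poisson") 1 else {
        max(sum((y - f$mu)^2 / fam$variance(f$mu)) /
              max(n - f$edf_total, 1), 1e-8)
      }
      ldetH <- 2 * sum(log(diag(f$Rh)))
      ldetS <- 0
      for (j in seq_along(design$penalties)) {
        ev <- eigen(design$penalties[[j]]$S, symmetric = TRUE,
                    only.values = TRUE)$values
        pos <- ev[ev > max(ev) * 1e-10]
        ldetS <- ldetS + length(pos) * rho[j] + sum(log(pos))
      }
      (f$penalized_deviance) / phi + ldetH - ldetS
    } else {
      n * f$deviance / (n - f$edf_total)^2
    }
  }
  if (n_lambda > 0 && select != "none") {
    crit_at <- function(rho) {
      f <- fit_at(rho)
      criterion(f, rho)
    }
    cur <- crit_at(rho)
    for (sweep in seq_len(control$max_sweeps)) {
      prev <- cur
      for (j in seq_len(n_lambda)) {
        crit_j <- function(r) {
          rho_j <- rho
          rho_j[j] <- r
          crit_at(rho_j)
        }
        opt <- stats::optimize(crit_j, interval = control$lambda_range,
                               tol = 0.05)
        # parsimony tie-break: if maximal smoothing is as good as the
        # optimum (flat criterion, e.g. no signal), take it
        hi <- crit_j(control$lambda_range[2])
        tol_tie <- 1e-9 * (abs(cur) + 1)
        if (hi <= min(opt$objective, cur) + tol_tie) {
          rho[j] <- control$lambda_range[2]
          cur <- hi
        } else if (opt$objective < cur) {
          rho[j] <- opt$minimum
          cur <- opt$objective
        }
      }
      if (abs(prev - cur) < control$select_tol * (abs(cur) + 1)) break
    }
  }
  f <- fit_at(rho)
  lambda_out <- if (n_lambda) {
    stats::setNames(exp(rho),
                    vapply(design$penalties, `[[`, "", "label"))
  } else numeric(0)
  phi <- if (fam$name == "poisson") 1 else {
    sum((y - f$mu)^2 / fam$variance(f$mu)) / max(n - f$edf_total, 1)
  }
  V_beta <- backsolve(f$Rh, forwardsolve(t(f$Rh), diag(design$p))) * phi
  V_beta <- (V_beta + t(V_beta)) / 2
  edf <- vapply(design$blocks, function(b) {
    if (b$type == "intercept") return(NA_real_)
    sum(f$edf_diag[b$cols])
  }, 0)
  names(edf) <- vapply(design$blocks, function(b) {
    switch(b$type, intercept = "intercepts",
           treatment_smooth = paste0("s(time):", b$level),
           plot_smooth = paste0("s(time):plot", b$plot))
  }, "")
  edf <- edf[!is.na(edf)]
  mu0 <- if (fam$link == "log") mean(y) else mean(y)
  structure(
    list(beta = stats::setNames(f$beta, colnames(X)), V_beta = V_beta,
         lambda = lambda_out, phi = phi, edf = edf,
         edf_total = f$edf_total, deviance = f$deviance,
         null_deviance = fam$dev(y, rep(mu0, n)),
         fitted = f$mu, linear_predictor = f$eta,
         family = fam$name, tweedie_power = if (fam$name == "tweedie")
           fam$power else NULL,
         link = fam$link, design = design, y = y,
         select = select, criterion = criterion(f, rho),
         iterations = f$iterations, converged = f$converged),
    class = "treatment_gam")
}

#' @export
print.treatment_gam <- function(x, ...) {
  cat("Treatment-by-time GAM (", x$family, ", ", x$link, " link)\n", sep = "")
  cat("deviance:", signif(x$deviance, 6),
      " total edf:", signif(x$edf_total, 4),
      " scale:", signif(x$phi, 4), "\n")
  cat("smooth edf:\n")
  print(round(x$edf, 2))
  invisible(x)
}

# Rows of the prediction design for one treatment's curve (intercept +
# treatment smooth; plot deviations excluded unless a plot is named).
prediction_rows <- function(fit, treatment, grid, plot = NULL) {
  design <- fit$design
  if (!treatment %in% design$treatment_levels) {
    stop_param("unknown treatment level: ", treatment)
  }
  if (any(grid < design$time_range[1] - 1e-8 |
          grid > design$time_range[2] + 1e-8)) {
    stop_param("prediction grid outside the fitted time range")
  }
  Cp <- matrix(0, length(grid), design$p)
  for (b in design$blocks) {
    if (b$type == "intercept") {
      Cp[, b$cols[match(treatment, b$levels)]] <- 1
    } else if (b$type == "treatment_smooth" && b$level == treatment) {
      Cp[, b$cols] <- eval_basis(b$basis, grid)
    } else if (b$type == "plot_smooth" && !is.null(plot) &&
               identical(b$plot, plot)) {
      Cp[, b$cols] <- eval_basis(b$basis, grid)
    }
  }
  Cp
}

#' Predict one treatment's smooth on the link scale
#'
#' Evaluates the fitted treatment curve (treatment intercept plus treatment
#' smooth, plot deviations excluded by default) with its posterior standard
#' error on the link scale.
#'
#' @param fit a \code{\link{fit_gam}} result.
#' @param treatment treatment level to predict.
#' @param grid time values within the fitted range.
#' @param include_plot_effects include one plot's deviation smooth.
#' @param plot plot id when \code{include_plot_effects} is \code{TRUE}.
#' @return Data frame with columns \code{time}, \code{estimate}, \code{se}
#'   (link scale).
#' @export
predict_treatment_curve <- function(fit, treatment, grid,
                                    include_plot_effects = FALSE,
                                    plot = NULL) {
  Cp <- prediction_rows(fit, treatment, grid,
                        plot = if (include_plot_effects) plot else NULL)
  est <- drop(Cp %*% fit$beta)
  se <- sqrt(pmax(rowSums((Cp %*% fit$V_beta) * Cp), 0))
  data.frame(time = grid, estimate = est, se = se)
}
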