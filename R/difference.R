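#' Difference between two treatment smooths
#'
#' Computes the link-scale difference between two treatments' fitted curves
#' (treatment A minus treatment B, plot deviations excluded) with Bayesian
#' credible bounds from the posterior covariance of the GAM coefficients.
#' Pointwise bounds are \eqn{d \pm z \sqrt{c' V_\beta c}}; simultaneous
#' bounds replace \eqn{z} by the max-|t| quantile over posterior draws of
#' the coefficient vector.
#'
#' @param fit a \code{\link{fit_gam}} result containing both levels.
#' @param treatA,treatB treatment levels to difference (A minus B).
#'   \code{treatA = treatB} is allowed and returns exact zeros.
#' @param grid time values; defaults to the fitted censuses' range at
#'   monthly resolution.
#' @param level credible level (default 0.95).
#' @param simultaneous compute simultaneous rather than pointwise bounds.
#' @param n_draws posterior draws for the simultaneous criterion.
#' @param seed seed for the posterior draws (simultaneous only).
#' @return An object of class \code{"difference_curve"}: a data frame with
#'   columns \code{grid}, \code{diff}, \code{se}, \code{lower}, \code{upper}
#'   and attributes \code{level}, \code{simultaneous}, \code{comparison}.
#' @export
difference_smooth <- function(fit, treatA, treatB, grid = NULL, level = 0.95,
                              simultaneous = FALSE, n_draws = 10000,
                              seed = NULL) {
  if (is.null(grid)) {
    tr <- fit$design$time_range
    grid <- seq(tr[1], tr[2], by = 1)
  }
  if (any(diff(grid) <= 0)) stop_param("grid must be strictly increasing")
  Ca <- prediction_rows(fit, treatA, grid)
  Cb <- prediction_rows(fit, treatB, grid)
  Cd <- Ca - Cb
  d <- drop(Cd %*% fit$beta)
  se <- sqrt(pmax(rowSums((Cd %*% fit$V_beta) * Cd), 0))
  if (identical(treatA, treatB)) {
    d <- rep(0, length(grid))
    se <- rep(0, length(grid))
  }
  crit <- stats::qnorm(1 - (1 - level) / 2)
  if (simultaneous && any(se > 0)) {
    if (!is.null(seed)) set.seed(substream_seed(seed, 5L))
    V <- Cd %*% fit$V_beta %*% t(Cd)
    R <- chol(V + diag(1e-12 * max(diag(V)) + 1e-300, nrow(V)))
    Zd <- matrix(stats::rnorm(n_draws * nrow(R)), n_draws, nrow(R)) %*% R
    tmax <- apply(abs(sweep(Zd, 2, pmax(se, 1e-300), "/")), 1, max)
    crit <- stats::quantile(tmax, probs = level, names = FALSE)
  }
  out <- data.frame(grid = grid, diff = d, se = se,
                    lower = d - crit * se, upper = d + crit * se)
  structure(out, class = c("difference_curve", "data.frame"),
            level = level, simultaneous = simultaneous,
            comparison = c(treatA, treatB))
}

#' Detect convergence of a difference curve to zero
#'
#' Finds the earliest post-intervention time from which the credible
#' interval on the difference of smooths contains zero in a sustained way:
#' zero must be contained at every grid point from the candidate time
#' through \code{sustain} further months (through the end of the series when
#' \code{sustain = Inf}, the default).  With a finite \code{sustain},
#' post-convergence intervals where zero is excluded again are reported as
#' excursions rather than resetting the convergence time.
#'
#' @param curve a \code{\link{difference_smooth}} result (or any data frame
#'   with columns \code{grid}, \code{lower}, \code{upper}).
#' @param intervention time of the treatment change (within the grid range).
#' @param sustain minimum number of months the interval must keep containing
#'   zero (default \code{Inf}: through the end of the series).
#' @return An object of class \code{"convergence_report"}: a list with
#'   \code{converge_month} (or \code{NA} if never), \code{months_since_change},
#'   and \code{excursions} (data frame of post-convergence windows excluding
#'   zero).
#' @export
detect_convergence <- function(curve, intervention, sustain = Inf) {
  grid <- curve$grid
  if (intervention < min(grid) || intervention > max(grid)) {
    stop_param("intervention time outside the grid range")
  }
  contains0 <- curve$lower <= 0 & curve$upper >= 0
  post <- which(grid >= intervention)
  converge_month <- NA_real_
  for (i in post) {
    window <- post[grid[post] >= grid[i] &
                     grid[post] <= min(grid[i] + sustain, max(grid))]
    if (all(contains0[window])) {
      converge_month <- grid[i]
      break
    }
  }
  excursions <- data.frame(start = numeric(0), end = numeric(0))
  if (!is.na(converge_month)) {
    after <- post[grid[post] >= converge_month]
    excl <- !contains0[after]
    if (any(excl)) {
      r <- rle(excl)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- which(r$values)
      excursions <- data.frame(start = grid[after][starts[keep]],
                               end = grid[after][ends[keep]])
    }
  }
  structure(
    list(converge_month = converge_month,
         months_since_change = converge_month - intervention,
         intervention = intervention, sustain = sustain,
         excursions = excursions),
    class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  if (is.na(x$converge_month)) {
    cat("No convergence detected after the intervention\n")
  } else {
    cat("Convergence at month", x$converge_month, "(",
        x$months_since_change, "months after the intervention )\n")
    if (nrow(x$excursions)) {
      cat("post-convergence excursions excluding zero:\n")
      print(x$excursions)
    }
  }
  invisible(x)
}
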