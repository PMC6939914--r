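#' Experimental plot layout
#'
#' Describes a plot-level manipulation experiment: a set of fenced plots,
#' each assigned to one of three treatments (long-term control, kangaroo-rat
#' exclosure opened to kangaroo rats, or total rodent exclosure opened to all
#' rodents), censused monthly, with a single treatment change part-way
#' through the series.
#'
#' Month indices are 0-based from the start of the analysis window.  The
#' default layout has 10 plots (4 control, 3 \code{kr_plus}, 3
#' \code{rodent_plus}) censused for 72 months with the treatment change at
#' month 26 (March of year 3 for a window starting in January of year 1).
#'
#' @param n_control,n_kr_plus,n_rodent_plus number of plots per treatment
#'   (each must be at least 2).
#' @param n_months number of monthly censuses.
#' @param change_month 0-based month index of the treatment change; must lie
#'   strictly inside the census range.
#' @return An object of class \code{"experiment_layout"}: a list with
#'   elements \code{plots}, \code{treatment_of_plot} (named factor),
#'   \code{census_months} (integer vector) and \code{change_month}.
#' @examples
#' layout <- experiment_layout()
#' table(layout$treatment_of_plot)
#' @export
experiment_layout <- function(n_control = 4, n_kr_plus = 3, n_rodent_plus = 3,
                              n_months = 72, change_month = 26) {
  counts <- c(control = n_control, kr_plus = n_kr_plus,
              rodent_plus = n_rodent_plus)
  if (any(counts < 2)) {
    stop_param("each treatment needs at least 2 plots")
  }
  census_months <- seq.int(0L, n_months - 1L)
  if (!(change_month > min(census_months) && change_month < max(census_months))) {
    stop_param("change_month must lie strictly inside the census range")
  }
  plots <- sprintf("P%02d", seq_len(sum(counts)))
  trt <- factor(rep(names(counts), counts), levels = treatment_levels())
  names(trt) <- plots
  structure(
    list(plots = plots, treatment_of_plot = trt,
         census_months = as.integer(census_months),
         change_month = as.integer(change_month)),
    class = "experiment_layout")
}

#' @export
print.experiment_layout <- function(x, ...) {
  cat("Experiment layout:", length(x$plots), "plots,",
      length(x$census_months), "monthly censuses\n")
  print(table(x$treatment_of_plot))
  cat("treatment change at month", x$change_month, "\n")
  invisible(x)
}

treatment_levels <- function() c("control", "kr_plus", "rodent_plus")

treated_levels <- function() c("kr_plus", "rodent_plus")

validate_layout <- function(layout) {
  if (!inherits(layout, "experiment_layout")) {
    stop_param("'layout' must be created by experiment_layout()")
  }
  if (any(diff(layout$census_months) <= 0)) {
    stop_param("census months must be strictly increasing")
  }
  invisible(layout)
}

#' Latent abundance trajectory parameters
#'
#' Parameters of the latent (log-scale) per-plot abundance trajectory used by
#' \code{\link{simulate_counts}}.  Control plots sit at a constant mean
#' \code{control_level}.  Treated plots sit at their pre-change level until
#' the treatment change; \code{recovery_delay} months after the change the
#' log-mean rises towards the control level along a logistic-in-time curve
#' with rate \code{recovery_rate}.  Plots recovering without an established
#' resident community additionally oscillate around the control level with a
#' damped seasonal-period sinusoid of initial relative amplitude
#' \code{overshoot_amplitude}.
#'
#' @param control_level mean count (individuals per plot per month) on
#'   control plots; must be positive.
#' @param prechange_level named vector: mean count on each treated plot type
#'   before the treatment change (the exclosure-era level).
#' @param recovery_delay named vector: months after the change before the
#'   rise begins, per treated treatment.
#' @param recovery_rate named vector: logistic rate (per month) of the rise.
#' @param overshoot_amplitude named vector: multiplicative oscillation size
#'   on the log scale (0 disables the oscillation).
#' @param overshoot_period,overshoot_decay period (months) and exponential
#'   decay rate of the post-recovery oscillation.
#' @param plot_sd standard deviation of smooth plot-level deviations on the
#'   log scale.
#' @return An object of class \code{"trajectory_params"}.
#' @seealso \code{\link{latent_mean}}, \code{\link{simulate_counts}}
#' @export
trajectory_params <- function(control_level = 8,
                              prechange_level = c(kr_plus = 0.3, rodent_plus = 0.15),
                              recovery_delay = c(kr_plus = 21, rodent_plus = 0),
                              recovery_rate = c(kr_plus = 0.6, rodent_plus = 0.8),
                              overshoot_amplitude = c(kr_plus = 0, rodent_plus = 0.35),
                              overshoot_period = 12,
                              overshoot_decay = 0.06,
                              plot_sd = 0.15) {
  if (!is.numeric(control_level) || control_level <= 0) {
    stop_param("control_level must be positive")
  }
  named_for <- function(x, what) {
    x <- if (length(x) == 1L && is.null(names(x))) {
      stats::setNames(rep(x, 2L), treated_levels())
    } else x
    if (!all(treated_levels() %in% names(x))) {
      stop_param(what, " must be named for treatments ",
                 paste(treated_levels(), collapse = ", "))
    }
    x[treated_levels()]
  }
  prechange_level <- named_for(prechange_level, "prechange_level")
  recovery_delay <- named_for(recovery_delay, "recovery_delay")
  recovery_rate <- named_for(recovery_rate, "recovery_rate")
  overshoot_amplitude <- named_for(overshoot_amplitude, "overshoot_amplitude")
  if (any(prechange_level <= 0)) stop_param("prechange_level must be positive")
  if (any(recovery_delay < 0)) stop_param("recovery_delay must be >= 0")
  if (plot_sd < 0) stop_param("plot_sd must be >= 0")
  structure(
    list(control_level = control_level, prechange_level = prechange_level,
         recovery_delay = recovery_delay, recovery_rate = recovery_rate,
         overshoot_amplitude = overshoot_amplitude,
         overshoot_period = overshoot_period,
         overshoot_decay = overshoot_decay, plot_sd = plot_sd),
    class = "trajectory_params")
}

#' Latent mean abundance of a treatment trajectory
#'
#' Evaluates the noise-free latent mean count (response scale, excluding
#' plot-level deviations) for each treatment at given census months.
#'
#' @param layout an \code{\link{experiment_layout}}.
#' @param params a \code{\link{trajectory_params}}.
#' @param months month indices at which to evaluate; defaults to the
#'   layout's census months.
#' @return Data frame with columns \code{treatment}, \code{month}, \code{mu}.
#' @export
latent_mean <- function(layout, params, months = layout$census_months) {
  validate_layout(layout)
  out <- expand.grid(treatment = treatment_levels(), month = months,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$mu <- exp(latent_log_mean(out$treatment, out$month,
                                layout$change_month, params))
  out
}

# Log-scale latent trajectory.  The recovery fraction g rises from 0 at the
# end of the delay to 1, as the upper half of a logistic curve
# (g = tanh(rate * dt / 2)), so the latent mean equals the pre-change level
# exactly until change_month + delay.
latent_log_mean <- function(treatment, month, change_month, params) {
  eta <- rep(log(params$control_level), length(month))
  for (trt in treated_levels()) {
    idx <- treatment == trt
    if (!any(idx)) next
    dt <- month[idx] - change_month - params$recovery_delay[[trt]]
    g <- ifelse(dt > 0, tanh(params$recovery_rate[[trt]] * dt / 2), 0)
    a <- log(params$prechange_level[[trt]] / params$control_level)
    osc <- params$overshoot_amplitude[[trt]] * g *
      sin(2 * pi * pmax(dt, 0) / params$overshoot_period) *
      exp(-params$overshoot_decay * pmax(dt, 0))
    eta[idx] <- eta[idx] + a * (1 - g) + osc
  }
  eta
}

# Smooth, mean-zero plot-level deviations: random coefficients on a low-rank
# cubic B-spline basis whose columns are orthonormalized in the empirical
# norm, scaled so the time-averaged deviation variance equals plot_sd^2.
plot_deviations <- function(months, n_plots, plot_sd, n_basis = 6) {
  if (plot_sd == 0 || n_plots == 0) {
    return(matrix(0, length(months), n_plots))
  }
  rng <- range(months)
  inner <- seq(rng[1], rng[2], length.out = n_basis - 2)[-c(1, n_basis - 2)]
  knots <- c(rep(rng[1], 4), inner, rep(rng[2], 4))
  B <- splines::splineDesign(knots, months, ord = 4)
  B <- scale(B, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(B))[, seq_len(n_basis - 1), drop = FALSE] * sqrt(length(months))
  coef <- matrix(stats::rnorm((n_basis - 1) * n_plots,
                              sd = plot_sd / sqrt(n_basis - 1)),
                 n_basis - 1, n_plots)
  Q %*% coef
}

#' Simulate monthly plot-level counts
#'
#' Draws Poisson counts around the latent treatment trajectory of
#' \code{\link{trajectory_params}} plus smooth plot-level deviations.
#'
#' @inheritParams latent_mean
#' @param seed integer seed; identical seeds give byte-identical tables.
#' @return Data frame with one row per plot and census month: columns
#'   \code{plot}, \code{treatment}, \code{month}, \code{count}.
#' @examples
#' counts <- simulate_counts(experiment_layout(), trajectory_params(), seed = 1)
#' head(counts)
#' @export
simulate_counts <- function(layout, params, seed) {
  validate_layout(layout)
  if (!inherits(params, "trajectory_params")) {
    stop_param("'params' must be created by trajectory_params()")
  }
  set.seed(substream_seed(seed, 1L))
  months <- layout$census_months
  plots <- layout$plots
  dev <- plot_deviations(months, length(plots), params$plot_sd)
  out <- expand.grid(plot = plots, month = months,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$treatment <- as.character(layout$treatment_of_plot[out$plot])
  eta <- latent_log_mean(out$treatment, out$month, layout$change_month, params)
  eta <- eta + dev[cbind(match(out$month, months), match(out$plot, plots))]
  out$count <- stats::rpois(nrow(out), exp(eta))
  out <- out[order(out$plot, out$month), c("plot", "treatment", "month", "count")]
  rownames(out) <- NULL
  out
}
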