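#' Plant community simulation parameters
#'
#' Parameters for \code{\link{simulate_plants}}.  Species counts are
#' negative-binomial around a log-linear model with a species main effect, a
#' dominant year-by-species effect and a weak treatment-by-species effect;
#' the year effect is intended to dwarf the treatment effect, as in plant
#' communities whose composition turns over strongly between years.
#'
#' @param n_species number of species (>= 2).
#' @param year_effect_sd log-scale spread of year-by-species effects.
#' @param treatment_effect_sd log-scale spread of treatment-by-species
#'   effects (small relative to \code{year_effect_sd}).
#' @param dispersion negative-binomial size parameter per quadrat.
#' @param quadrats_per_plot number of quadrats pooled into each sample.
#' @return An object of class \code{"plant_sim_params"}.
#' @export
plant_sim_params <- function(n_species = 20, year_effect_sd = 0.8,
                             treatment_effect_sd = 0.18, dispersion = 2,
                             quadrats_per_plot = 16) {
  if (n_species < 2) stop_param("n_species must be >= 2")
  if (year_effect_sd < 0 || treatment_effect_sd < 0) {
    stop_param("effect sds must be >= 0")
  }
  structure(
    list(n_species = as.integer(n_species), year_effect_sd = year_effect_sd,
         treatment_effect_sd = treatment_effect_sd, dispersion = dispersion,
         quadrats_per_plot = as.integer(quadrats_per_plot)),
    class = "plant_sim_params")
}

#' Simulate seasonal plant quadrat abundances
#'
#' One sample per plot, year and season: species counts pooled over the
#' plot's quadrats, negative-binomial around
#' \code{quadrats * exp(base + year:species + treatment:species)} effects.
#'
#' @param layout an \code{\link{experiment_layout}}.
#' @param params a \code{\link{plant_sim_params}}.
#' @param years integer vector of sampling years (>= 2 values).
#' @param seasons character vector of seasons sampled each year.
#' @param seed integer seed.
#' @return Data frame with columns \code{sample}, \code{plot}, \code{year},
#'   \code{season}, \code{treatment} followed by one integer abundance
#'   column per species (\code{sp01}, \code{sp02}, ...).
#' @export
simulate_plants <- function(layout, params, years = 2009:2014,
                            seasons = c("winter", "summer"), seed) {
  validate_layout(layout)
  if (!inherits(params, "plant_sim_params")) {
    stop_param("'params' must be created by plant_sim_params()")
  }
  if (length(years) < 2) stop_param("need at least 2 years")
  if (!length(seasons)) stop_param("need at least one season")
  set.seed(substream_seed(seed, 3L))
  ns <- params$n_species
  species <- sprintf("sp%02d", seq_len(ns))
  trts <- treatment_levels()
  grid <- expand.grid(plot = layout$plots, year = years, season = seasons,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$treatment <- as.character(layout$treatment_of_plot[grid$plot])
  grid$sample <- sprintf("S%03d", seq_len(nrow(grid)))
  Y <- matrix(0L, nrow(grid), ns, dimnames = list(grid$sample, species))
  for (ssn in seasons) {
    base <- stats::rnorm(ns, log(5), 1)
    year_eff <- matrix(stats::rnorm(length(years) * ns, 0, params$year_effect_sd),
                       length(years), ns, dimnames = list(years, species))
    trt_eff <- matrix(stats::rnorm(length(trts) * ns, 0,
                                   params$treatment_effect_sd),
                      length(trts), ns, dimnames = list(trts, species))
    idx <- which(grid$season == ssn)
    for (i in idx) {
      eta <- base + year_eff[as.character(grid$year[i]), ] +
        trt_eff[grid$treatment[i], ]
      mu <- params$quadrats_per_plot * exp(eta)
      Y[i, ] <- stats::rnbinom(ns, mu = mu,
                               size = params$dispersion *
                                 params$quadrats_per_plot)
    }
  }
  cbind(grid[, c("sample", "plot", "year", "season", "treatment")],
        as.data.frame(Y))
}
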