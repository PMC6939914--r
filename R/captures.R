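#' Simulate individual capture records
#'
#' Generates monthly individual capture events (period, plot, species, tag,
#' body mass) consistent with two latent abundance trajectories: one for the
#' kangaroo-rat group and one for the smaller granivores.  Within each
#' plot-month the number of captured individuals per group is Poisson around
#' the group's latent mean; individuals are either returning tags (drawn
#' from the plot's previously captured pool) or new tags.  Each tag keeps a
#' fixed species and lognormal body mass from its first capture.
#'
#' @param layout an \code{\link{experiment_layout}}.
#' @param traj_kr \code{\link{trajectory_params}} for the kangaroo-rat group.
#' @param traj_granivore \code{\link{trajectory_params}} for the granivore
#'   group.
#' @param params an \code{\link{individual_sim_params}} (body-mass tables).
#' @param seed integer seed.
#' @param return_prob probability that a captured individual is a returning
#'   tag from the plot's pool rather than a new individual.
#' @return Data frame of capture records: \code{period} (month index),
#'   \code{plot}, \code{treatment}, \code{species}, \code{tag},
#'   \code{mass_g}.
#' @export
simulate_captures <- function(layout, traj_kr, traj_granivore,
                              params = individual_sim_params(), seed,
                              return_prob = 0.65) {
  validate_layout(layout)
  set.seed(substream_seed(seed, 4L))
  sp <- default_species_masses()
  groups <- list(
    kangaroo_rat = list(traj = traj_kr,
                        species = sp$species[sp$group == "kangaroo_rat"],
                        weights = c(0.6, 0.35, 0.05)),
    granivore = list(traj = traj_granivore,
                     species = sp$species[sp$group == "granivore"],
                     weights = c(0.05, 0.2, 0.25, 0.08, 0.1, 0.08, 0.1,
                                 0.05, 0.06, 0.03)))
  mass_mean <- params$mass_mean_by_species
  mass_sd <- params$mass_sd_by_species
  recs <- list()
  tag_counter <- 0L
  for (gname in names(groups)) {
    g <- groups[[gname]]
    pools <- stats::setNames(vector("list", length(layout$plots)), layout$plots)
    for (m in layout$census_months) {
      for (pl in layout$plots) {
        trt <- as.character(layout$treatment_of_plot[[pl]])
        mu <- exp(latent_log_mean(trt, m, layout$change_month, g$traj))
        n_cap <- stats::rpois(1L, mu)
        if (n_cap == 0L) next
        pool <- pools[[pl]]
        old_size <- if (is.null(pool)) 0L else nrow(pool)
        n_ret <- min(sum(stats::runif(n_cap) < return_prob), old_size)
        n_new <- n_cap - n_ret
        new_tags <- character(0)
        if (n_new > 0L) {
          species_new <- sample(g$species, n_new, replace = TRUE,
                                prob = g$weights)
          new_tags <- sprintf("T%06d", tag_counter + seq_len(n_new))
          tag_counter <- tag_counter + n_new
          mu_m <- mass_mean[species_new]
          sd_m <- mass_sd[species_new]
          sdlog <- sqrt(log(1 + (sd_m / mu_m)^2))
          mass_new <- stats::rlnorm(n_new, log(mu_m) - sdlog^2 / 2, sdlog)
          pool <- rbind(pool, data.frame(tag = new_tags,
                                         species = species_new,
                                         mass_g = round(mass_new, 1),
                                         stringsAsFactors = FALSE))
          pools[[pl]] <- pool
        }
        ret_idx <- if (n_ret > 0L) sample.int(old_size, n_ret) else integer(0)
        idx <- c(ret_idx, match(new_tags, pool$tag))
        recs[[length(recs) + 1L]] <- data.frame(
          period = m, plot = pl, treatment = trt,
          species = pool$species[idx], tag = pool$tag[idx],
          mass_g = pool$mass_g[idx], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, recs)
  out <- out[order(out$period, out$plot, out$tag), ]
  rownames(out) <- NULL
  out
}
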