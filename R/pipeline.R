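#' Pipeline configuration
#'
#' Assembles and validates the configuration for \code{\link{run_all}}.
#' By default the pipeline simulates a full synthetic experiment (10 plots,
#' 72 monthly censuses, treatment change at month 26) and analyses three
#' metrics: kangaroo-rat counts, non-kangaroo-rat granivore counts
#' (both Poisson) and community metabolic flux (Tweedie).
#'
#' @param seed master seed (mandatory when simulating).
#' @param simulate simulate inputs (\code{TRUE}) or read them from
#'   \code{input_paths}.
#' @param input_paths named list of CSV paths (\code{counts_kr},
#'   \code{counts_granivore}, \code{captures}, \code{plants}) when
#'   \code{simulate = FALSE}.
#' @param layout an \code{\link{experiment_layout}}.
#' @param traj_kr,traj_granivore \code{\link{trajectory_params}} for the two
#'   count metrics (granivore defaults follow pre-change levels of 7.8 on
#'   kangaroo-rat exclosures, 5.7 on controls and 3.1 on rodent exclosures,
#'   with fast post-change convergence).
#' @param metrics which metrics to analyse (subset of \code{"kr_counts"},
#'   \code{"granivore_counts"}, \code{"metabolic_flux"}).
#' @param comparisons list of ordered treatment pairs to difference.
#' @param k_treatment,k_plot GAM basis dimensions.
#' @param tweedie_power Tweedie variance power for the flux metric.
#' @param level credible level for difference curves.
#' @param sustain sustain rule for \code{\link{detect_convergence}}; the
#'   pipeline default of 6 months tolerates transient post-convergence
#'   oscillation excursions (reported, not resetting the clock) instead of
#'   requiring containment through the end of the series.
#' @param n_individuals,n_occasions size of the simulated capture-history
#'   set for the multistate model.
#' @param ind_params an \code{\link{individual_sim_params}}.
#' @param plant_params a \code{\link{plant_sim_params}}.
#' @param plant_years years of plant sampling.
#' @param n_perm pCCA permutations.
#' @param stages which analysis stages to run (subset of \code{"gam"},
#'   \code{"influx"}, \code{"multistrata"}, \code{"pcca"}).
#' @return An object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(seed = 1, simulate = TRUE, input_paths = list(),
                            layout = experiment_layout(),
                            traj_kr = trajectory_params(),
                            traj_granivore = granivore_trajectory(),
                            metrics = c("kr_counts", "granivore_counts",
                                        "metabolic_flux"),
                            comparisons = list(c("control", "kr_plus"),
                                               c("control", "rodent_plus")),
                            k_treatment = 20, k_plot = 8,
                            tweedie_power = 1.5, level = 0.95, sustain = 6,
                            n_individuals = 1500, n_occasions = 24,
                            ind_params = individual_sim_params(),
                            plant_params = plant_sim_params(),
                            plant_years = 2009:2014, n_perm = 999,
                            stages = c("gam", "influx", "multistrata",
                                       "pcca")) {
  if (simulate && is.null(seed)) stop_param("seed is mandatory when simulating")
  metrics <- match.arg(metrics, several.ok = TRUE)
  stages <- match.arg(stages, several.ok = TRUE)
  trts <- treatment_levels()
  for (cmp in comparisons) {
    if (!all(cmp %in% trts)) {
      stop_param("unknown treatment in comparison: ",
                 paste(cmp, collapse = " vs "))
    }
  }
  structure(
    list(seed = seed, simulate = simulate, input_paths = input_paths,
         layout = layout, traj_kr = traj_kr,
         traj_granivore = traj_granivore, metrics = metrics,
         comparisons = comparisons, k_treatment = k_treatment,
         k_plot = k_plot, tweedie_power = tweedie_power, level = level,
         sustain = sustain, n_individuals = n_individuals,
         n_occasions = n_occasions, ind_params = ind_params,
         plant_params = plant_params, plant_years = plant_years,
         n_perm = n_perm, stages = stages),
    class = "pipeline_config")
}

#' Granivore-count trajectory defaults
#'
#' Latent trajectory for the non-kangaroo-rat granivores: elevated on
#' kangaroo-rat exclosures and suppressed on rodent exclosures before the
#' change, converging to control levels within a few months afterwards.
#'
#' @return A \code{\link{trajectory_params}} object.
#' @export
granivore_trajectory <- function() {
  trajectory_params(
    control_level = 5.7,
    prechange_level = c(kr_plus = 7.8, rodent_plus = 3.1),
    recovery_delay = c(kr_plus = 0, rodent_plus = 0),
    recovery_rate = c(kr_plus = 0.8, rodent_plus = 0.8),
    overshoot_amplitude = c(kr_plus = 0, rodent_plus = 0),
    plot_sd = 0.12)
}

#' Write / read a pipeline configuration as YAML
#'
#' Serializes the scalar and vector settings of a
#' \code{\link{pipeline_config}} (complex components are reduced to their
#' constructor arguments) and reloads them to an equal object.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param path YAML file path.
#' @return \code{read_config} returns a \code{pipeline_config};
#'   \code{write_config} returns \code{path} invisibly.
#' @export
write_config <- function(config, path) {
  ser <- list(
    seed = config$seed, simulate = config$simulate,
    input_paths = config$input_paths,
    layout = list(
      n_control = sum(config$layout$treatment_of_plot == "control"),
      n_kr_plus = sum(config$layout$treatment_of_plot == "kr_plus"),
      n_rodent_plus = sum(config$layout$treatment_of_plot == "rodent_plus"),
      n_months = length(config$layout$census_months),
      change_month = config$layout$change_month),
    traj_kr = lapply(unclass(config$traj_kr), yamlify),
    traj_granivore = lapply(unclass(config$traj_granivore), yamlify),
    metrics = config$metrics,
    comparisons = lapply(config$comparisons, as.list),
    k_treatment = config$k_treatment, k_plot = config$k_plot,
    tweedie_power = config$tweedie_power, level = config$level,
    sustain = if (is.finite(config$sustain)) config$sustain else "Inf",
    n_individuals = config$n_individuals, n_occasions = config$n_occasions,
    plant_params = unclass(config$plant_params),
    plant_years = config$plant_years, n_perm = config$n_perm,
    stages = config$stages)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  s <- yaml::read_yaml(path)
  pipeline_config(
    seed = s$seed, simulate = s$simulate,
    input_paths = s$input_paths %||% list(),
    layout = do.call(experiment_layout, s$layout),
    traj_kr = do.call(trajectory_params,
                      lapply(s$traj_kr, relist_named)),
    traj_granivore = do.call(trajectory_params,
                             lapply(s$traj_granivore, relist_named)),
    metrics = unlist(s$metrics),
    comparisons = lapply(s$comparisons, unlist),
    k_treatment = s$k_treatment, k_plot = s$k_plot,
    tweedie_power = s$tweedie_power, level = s$level,
    sustain = if (identical(s$sustain, "Inf")) Inf else s$sustain,
    n_individuals = s$n_individuals, n_occasions = s$n_occasions,
    plant_params = do.call(plant_sim_params, s$plant_params[
      c("n_species", "year_effect_sd", "treatment_effect_sd", "dispersion",
        "quadrats_per_plot")]),
    plant_years = unlist(s$plant_years), n_perm = s$n_perm,
    stages = unlist(s$stages) %||% c("gam", "influx", "multistrata", "pcca"))
}

relist_named <- function(x) {
  if (is.list(x)) unlist(x) else x
}

# yaml drops the names of named atomic vectors; write them as maps instead
yamlify <- function(x) {
  if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
}

#' Ingest capture records from CSV
#'
#' Reads and validates a capture-record table.  Rows with negative mass are
#' rejected and counted (reported via a warning and the
#' \code{"n_rejected"} attribute).
#'
#' @param path CSV path with columns \code{period}, \code{plot},
#'   \code{species}, \code{tag}, \code{mass_g} (optionally
#'   \code{treatment}).
#' @return Data frame of validated capture records.
#' @export
ingest_captures <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("period", "plot", "species", "tag", "mass_g")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop_param("captures file lacks mandatory column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  bad <- !is.na(d$mass_g) & d$mass_g < 0
  if (any(bad)) {
    warning(sum(bad), " row(s) with negative mass rejected")
    d <- d[!bad, , drop = FALSE]
  }
  attr(d, "n_rejected") <- sum(bad)
  d
}

#' Ingest a plant abundance table from CSV
#'
#' @param path CSV path with columns \code{sample}, \code{plot},
#'   \code{year}, \code{season}, \code{treatment} and one column per
#'   species.
#' @return Data frame in the layout of \code{\link{simulate_plants}}.
#' @export
ingest_plants <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample", "plot", "year", "season", "treatment")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop_param("plants file lacks mandatory column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  sp <- setdiff(names(d), need)
  if (length(sp) < 2) stop_param("plants file needs at least 2 species columns")
  if (any(as.matrix(d[, sp]) < 0)) stop_param("negative abundances in plants file")
  d
}

#' Ingest a counts table from CSV
#'
#' @param path CSV path with columns \code{plot}, \code{treatment},
#'   \code{month}, \code{count}.
#' @return Data frame of validated counts.
#' @export
ingest_counts <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot", "treatment", "month", "count")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop_param("counts file lacks mandatory column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  d
}

#' Run the full analysis pipeline
#'
#' Simulates (or ingests) the experiment's data and runs every analysis
#' stage: per-metric GAM fits with treatment and plot smooths, link-scale
#' difference curves with credible intervals for each configured treatment
#' pair, convergence reports, the new-individual influx table, the
#' multistate capture-recapture candidate set with AIC selection, and the
#' seasonal plant pCCA permutation tests.  All outputs are written as CSV
#' (plus a YAML run manifest) under \code{output_dir} and returned
#' invisibly.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param output_dir directory for outputs (created if needed);
#'   \code{NULL} skips writing.
#' @param verbose log stage progress.
#' @return Invisibly, a list with elements \code{data}, \code{gam}
#'   (per metric: fit, curves, differences, convergence), \code{influx},
#'   \code{multistrata}, \code{pcca}, \code{convergence_summary}.
#' @export
run_all <- function(config = pipeline_config(), output_dir = NULL,
                    verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_stage <- function(...) if (verbose) message("[run_all] ", ...)
  layout <- config$layout
  seed <- config$seed

  log_stage("stage: data (", if (config$simulate) "simulate" else "ingest", ")")
  stages <- config$stages %||% c("gam", "influx", "multistrata", "pcca")
  need_captures <- "influx" %in% stages ||
    ("gam" %in% stages && "metabolic_flux" %in% config$metrics)
  data <- with_stage("data", {
    if (config$simulate) {
      list(
        counts_kr = if ("gam" %in% stages)
          simulate_counts(layout, config$traj_kr, seed = seed) else NULL,
        counts_granivore = if ("gam" %in% stages)
          simulate_counts(layout, config$traj_granivore, seed = seed + 1)
          else NULL,
        captures = if (need_captures)
          simulate_captures(layout, config$traj_kr, config$traj_granivore,
                            config$ind_params, seed = seed) else NULL,
        histories = if ("multistrata" %in% stages)
          simulate_histories(layout, config$ind_params,
                             config$n_individuals, seed = seed,
                             n_occasions = config$n_occasions) else NULL,
        plants = if ("pcca" %in% stages)
          simulate_plants(layout, config$plant_params,
                          years = config$plant_years, seed = seed)
          else NULL)
    } else {
      ip <- config$input_paths
      list(counts_kr = ingest_counts(ip$counts_kr),
           counts_granivore = if (!is.null(ip$counts_granivore))
             ingest_counts(ip$counts_granivore) else NULL,
           captures = if (!is.null(ip$captures))
             ingest_captures(ip$captures) else NULL,
           histories = if (!is.null(ip$histories))
             read_inp(ip$histories, treatment_levels()) else NULL,
           plants = if (!is.null(ip$plants)) ingest_plants(ip$plants)
             else NULL)
    }
  })

  kr_species <- default_species_masses()
  flux <- if ("metabolic_flux" %in% config$metrics && !is.null(data$captures)) {
    community_flux(data$captures, species_filter = kr_species$species)
  } else NULL

  metric_inputs <- list(
    kr_counts = list(data = data$counts_kr, response = "count",
                     family = "poisson"),
    granivore_counts = list(data = data$counts_granivore, response = "count",
                            family = "poisson"),
    metabolic_flux = list(data = flux, response = "E_total",
                          family = "tweedie"))

  gam_results <- list()
  for (metric in config$metrics) {
    mi <- metric_inputs[[metric]]
    if (is.null(mi$data)) next
    log_stage("stage: gam (", metric, ", ", mi$family, ")")
    res <- with_stage(paste0("gam:", metric), {
      fit <- fit_gam(mi$data, response = mi$response, family = mi$family,
                     k_treatment = config$k_treatment,
                     k_plot = config$k_plot,
                     tweedie_power = config$tweedie_power)
      grid <- layout$census_months
      curves <- lapply(stats::setNames(nm = fit$design$treatment_levels),
                       function(trt) predict_treatment_curve(fit, trt, grid))
      diffs <- list()
      conv <- list()
      for (cmp in config$comparisons) {
        key <- paste(cmp, collapse = "_vs_")
        dc <- difference_smooth(fit, cmp[1], cmp[2], grid = grid,
                                level = config$level)
        diffs[[key]] <- dc
        conv[[key]] <- detect_convergence(dc, layout$change_month,
                                          sustain = config$sustain)
      }
      list(fit = fit, curves = curves, differences = diffs,
           convergence = conv)
    })
    gam_results[[metric]] <- res
  }

  influx <- NULL
  if (!is.null(data$captures) && "influx" %in% stages) {
    log_stage("stage: influx")
    influx <- with_stage("influx", {
      kr_only <- data$captures[
        data$captures$species %in%
          kr_species$species[kr_species$group == "kangaroo_rat"], ,
        drop = FALSE]
      tabulate_new_individuals(kr_only, layout$change_month)
    })
  }

  mstrata <- NULL
  if (!is.null(data$histories)) {
    log_stage("stage: multistrata (", config$n_individuals, " histories)")
    mstrata <- with_stage("multistrata", {
      cand <- multistrata_candidates(data$histories, seed = seed,
                                     n_restarts = 1)
      list(candidates = cand, best = select_model(cand$fits))
    })
  }

  pcca_res <- NULL
  if (!is.null(data$plants)) {
    log_stage("stage: pcca (", config$n_perm, " permutations per season)")
    pcca_res <- with_stage("pcca", {
      plant_pcca(data$plants, n_perm = config$n_perm, seed = seed)
    })
  }

  conv_summary <- do.call(rbind, lapply(names(gam_results), function(metric) {
    cv <- gam_results[[metric]]$convergence
    do.call(rbind, lapply(names(cv), function(key) {
      data.frame(metric = metric, comparison = key,
                 converge_month = cv[[key]]$converge_month,
                 months_since_change = cv[[key]]$months_since_change)
    }))
  }))

  results <- list(data = data, flux = flux, gam = gam_results,
                  influx = influx, multistrata = mstrata, pcca = pcca_res,
                  convergence_summary = conv_summary, config = config)
  if (!is.null(output_dir)) {
    log_stage("stage: write (", output_dir, ")")
    write_pipeline_outputs(results, output_dir)
  }
  invisible(results)
}

# Run a stage, rethrowing any failure labelled with the stage name so a
# partial pipeline can be diagnosed (earlier outputs are already on disk).
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(paste0("stage '", stage, "' failed: ",
                               conditionMessage(e)),
                        class = c("recolonize_stage_error", "error")))
  })
}

write_pipeline_outputs <- function(results, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name) {
    utils::write.csv(x, file.path(output_dir, name), row.names = FALSE)
  }
  for (metric in names(results$gam)) {
    g <- results$gam[[metric]]
    curves <- do.call(rbind, lapply(names(g$curves), function(trt) {
      cbind(treatment = trt, g$curves[[trt]])
    }))
    wcsv(curves, paste0(metric, "_fitted_curves.csv"))
    for (key in names(g$differences)) {
      wcsv(as.data.frame(g$differences[[key]]),
           paste0(metric, "_difference_", key, ".csv"))
    }
    wcsv(results$convergence_summary, "convergence_summary.csv")
  }
  if (!is.null(results$influx)) {
    wcsv(results$influx$influx, "influx_by_plot_year.csv")
    wcsv(results$influx$means, "influx_treatment_means.csv")
  }
  if (!is.null(results$multistrata)) {
    wcsv(results$multistrata$candidates$aic, "multistrata_aic.csv")
    best <- results$multistrata$best
    est <- data.frame(
      parameter = c(paste0("S_", names(best$params$S)),
                    paste0("p_", names(best$params$p)),
                    paste0("Psi_", outer(best$params$strata,
                                         best$params$strata, paste,
                                         sep = "_to_"))),
      estimate = c(best$params$S, best$params$p, as.vector(best$params$Psi)))
    wcsv(est, "multistrata_estimates.csv")
  }
  if (!is.null(results$pcca)) {
    wcsv(results$pcca$summary, "pcca_summary.csv")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("recolonize")),
    r_version = R.version.string,
    seed = results$config$seed,
    config_hash = fnv1a_hash(results$config),
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  yaml::write_yaml(manifest, file.path(output_dir, "run_manifest.yaml"))
  invisible(output_dir)
}
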