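#' Metabolic rate from body mass
#'
#' Three-quarter-power metabolic scaling with unit proportionality constant:
#' \eqn{E = m^{3/4}} for mass \eqn{m} in grams.  Units are arbitrary; the
#' flux is used only comparatively.
#'
#' @param mass_g positive body mass in grams (vectorized).
#' @return Metabolic rate(s), \code{mass_g^0.75}.
#' @examples
#' metabolic_rate(16)  # 8
#' metabolic_rate(81)  # 27
#' @export
metabolic_rate <- function(mass_g) {
  if (any(!is.finite(mass_g)) || any(mass_g <= 0)) {
    stop_param("mass_g must be positive")
  }
  mass_g^0.75
}

#' Community metabolic flux per plot and census
#'
#' Sums individual metabolic rates (\code{mass^(3/4)}) over the seed-eating
#' community by plot and census period.  Each tagged individual is counted
#' once per plot-month even if recaptured within the month.  Missing masses
#' are imputed by the species mean within the dataset (with a message);
#' individuals with no mass and no conspecific masses are excluded with a
#' warning.
#'
#' @param captures data frame of capture records with columns \code{period},
#'   \code{plot}, \code{species}, \code{tag}, \code{mass_g} (and optionally
#'   \code{treatment}).
#' @param species_filter character vector of species codes to include
#'   (default: the kangaroo-rat and granivore codes of
#'   \code{\link{default_species_masses}}); \code{NULL} keeps all species.
#' @return Data frame with one row per plot and period present in
#'   \code{captures}: columns \code{plot}, \code{month}, \code{E_total}
#'   (plus \code{treatment} when present in the input).
#' @export
community_flux <- function(captures,
                           species_filter = default_species_masses()$species) {
  need <- c("period", "plot", "species", "tag", "mass_g")
  if (!all(need %in% names(captures))) {
    stop_param("captures lacks columns: ",
               paste(setdiff(need, names(captures)), collapse = ", "))
  }
  frame <- unique(captures[, c("plot", "period")])
  keep <- captures
  if (!is.null(species_filter)) {
    keep <- keep[keep$species %in% species_filter, , drop = FALSE]
  }
  # one tagged individual counted once per plot-month
  keep <- keep[!duplicated(keep[, c("plot", "period", "tag")]), , drop = FALSE]
  miss <- is.na(keep$mass_g)
  if (any(miss)) {
    sp_mean <- tapply(keep$mass_g, keep$species, mean, na.rm = TRUE)
    imput <- sp_mean[keep$species[miss]]
    keep$mass_g[miss] <- imput
    n_bad <- sum(is.na(keep$mass_g))
    if (n_bad) {
      warning(n_bad, " individual(s) with no mass and no conspecific ",
              "masses excluded from flux")
      keep <- keep[!is.na(keep$mass_g), , drop = FALSE]
    }
    message(sum(miss) - n_bad, " missing mass(es) imputed by species mean")
  }
  keep$E <- metabolic_rate(keep$mass_g)
  agg <- stats::aggregate(E ~ plot + period, data = keep, FUN = sum)
  out <- merge(frame, agg, by = c("plot", "period"), all.x = TRUE)
  out$E[is.na(out$E)] <- 0
  names(out)[names(out) == "period"] <- "month"
  names(out)[names(out) == "E"] <- "E_total"
  if ("treatment" %in% names(captures)) {
    trt <- unique(captures[, c("plot", "treatment")])
    out <- merge(out, trt, by = "plot")
  }
  out <- out[order(out$plot, out$month), ]
  rownames(out) <- NULL
  out
}
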