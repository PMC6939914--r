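#' Individual-level simulation parameters
#'
#' Monthly apparent-survival, recapture and stratum-transition probabilities
#' used by \code{\link{simulate_histories}}, together with lognormal
#' body-mass parameters per species used by \code{\link{simulate_captures}}.
#' Strata are the experimental treatment types.
#'
#' @param S named per-stratum monthly apparent-survival probabilities.
#' @param p named per-stratum recapture probabilities.
#' @param Psi row-stochastic stratum-transition probability matrix with
#'   dimnames equal to the strata; each row must sum to 1 within 1e-12.
#' @param mass_mean_by_species,mass_sd_by_species named vectors of lognormal
#'   body-mass parameters (grams; mean and sd on the natural scale).
#' @return An object of class \code{"individual_sim_params"}.
#' @export
individual_sim_params <- function(S = c(control = 0.85, kr_plus = 0.92,
                                        rodent_plus = 0.85),
                                  p = c(control = 0.6, kr_plus = 0.6,
                                        rodent_plus = 0.6),
                                  Psi = default_psi(),
                                  mass_mean_by_species = NULL,
                                  mass_sd_by_species = NULL) {
  if (is.null(mass_mean_by_species)) {
    sp <- default_species_masses()
    mass_mean_by_species <- stats::setNames(sp$mass_mean, sp$species)
    mass_sd_by_species <- stats::setNames(sp$mass_sd, sp$species)
  }
  strata <- names(S)
  if (is.null(strata) || !identical(strata, names(p))) {
    stop_param("S and p must be named for the same strata")
  }
  if (any(S <= 0 | S >= 1) || any(p <= 0 | p >= 1)) {
    stop_param("all survival and recapture probabilities must lie in (0,1)")
  }
  Psi <- as.matrix(Psi)
  if (!identical(dim(Psi), c(length(strata), length(strata)))) {
    stop_param("Psi must be a square matrix over the strata")
  }
  if (any(Psi < 0) || any(abs(rowSums(Psi) - 1) > 1e-12)) {
    stop_param("each Psi row must sum to 1 (within 1e-12)")
  }
  dimnames(Psi) <- list(strata, strata)
  structure(
    list(S = S, p = p, Psi = Psi, strata = strata,
         mass_mean_by_species = mass_mean_by_species,
         mass_sd_by_species = mass_sd_by_species),
    class = "individual_sim_params")
}

# Defaults emulate site-fidelity-dominated movement with rare transitions,
# rarest into plots holding an established community.  Diagonals are
# computed by complement so rows sum to 1 exactly.
default_psi <- function() {
  off <- rbind(control     = c(NA, 0.01, 0.04),
               kr_plus     = c(0.02, NA, 0.01),
               rodent_plus = c(0.05, 0.01, NA))
  K <- nrow(off)
  for (k in seq_len(K)) off[k, k] <- 1 - sum(off[k, -k])
  colnames(off) <- rownames(off)
  off
}

#' Default species body-mass table
#'
#' Generator defaults for a desert granivore assemblage: three kangaroo-rat
#' species (genus \emph{Dipodomys}) and ten smaller seed-eating species.
#' Masses are generator defaults in grams, not field estimates.
#'
#' @return Data frame with columns \code{species} (code), \code{group}
#'   (\code{"kangaroo_rat"} or \code{"granivore"}), \code{mass_mean},
#'   \code{mass_sd}.
#' @export
default_species_masses <- function() {
  data.frame(
    species = c("DM", "DO", "DS",
                "BA", "CB", "CP", "PF", "PE", "PL", "PM", "RF", "RM", "RO"),
    group = c(rep("kangaroo_rat", 3), rep("granivore", 10)),
    mass_mean = c(45, 52, 120, 8, 30, 17, 8, 20, 22, 22, 12, 11, 10),
    mass_sd = c(6, 7, 15, 1.5, 4, 2.5, 1.5, 3, 3, 3, 2, 2, 2),
    stringsAsFactors = FALSE)
}

#' Capture-history set
#'
#' Container for multistate capture histories: an integer matrix with one
#' row per tagged individual and one column per census occasion; 0 denotes
#' non-detection and positive entries index the stratum of detection.
#'
#' @param histories integer matrix (individuals x occasions).
#' @param strata character vector of stratum labels (matrix entries index
#'   into it).
#' @param tags optional individual identifiers (defaults to row numbers).
#' @return An object of class \code{"capture_histories"}.
#' @export
capture_histories <- function(histories, strata, tags = NULL) {
  histories <- as.matrix(histories)
  storage.mode(histories) <- "integer"
  if (any(histories < 0L) || any(histories > length(strata))) {
    stop_param("history entries must be 0 (non-detection) or a stratum index")
  }
  first <- apply(histories != 0L, 1L, function(z) {
    w <- which(z)
    if (!length(w)) NA_integer_ else w[1L]
  })
  if (anyNA(first)) stop_param("every history must contain a detection")
  tags <- tags %||% sprintf("ind%05d", seq_len(nrow(histories)))
  structure(
    list(histories = histories, strata = strata, first = first, tags = tags),
    class = "capture_histories")
}

#' @export
print.capture_histories <- function(x, ...) {
  cat("Capture histories:", nrow(x$histories), "individuals,",
      ncol(x$histories), "occasions, strata:",
      paste(x$strata, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.character.capture_histories <- function(x, ...) {
  symbols <- c("0", LETTERS[seq_along(x$strata)])
  apply(x$histories, 1L, function(h) paste(symbols[h + 1L], collapse = ""))
}

#' Simulate multistate capture histories
#'
#' Simulates individual encounter histories over monthly occasions.  Each
#' individual is first captured (released) at a uniformly drawn occasion and
#' stratum; thereafter state evolves per interval as survive (stratum-specific
#' \code{S}), then move (row of \code{Psi}), then detect (destination-stratum
#' \code{p}).  Dead individuals never reappear; apparent survival confounds
#' death and permanent emigration.
#'
#' @param layout an \code{\link{experiment_layout}} (supplies the stratum
#'   labels via its treatment levels).
#' @param params an \code{\link{individual_sim_params}}.
#' @param n_individuals number of tagged individuals (>= 1).
#' @param seed integer seed.
#' @param n_occasions number of monthly capture occasions; defaults to the
#'   number of census months after the treatment change.
#' @return A \code{\link{capture_histories}} object.
#' @export
simulate_histories <- function(layout, params, n_individuals, seed,
                               n_occasions = NULL) {
  validate_layout(layout)
  if (!inherits(params, "individual_sim_params")) {
    stop_param("'params' must be created by individual_sim_params()")
  }
  if (n_individuals < 1) stop_param("n_individuals must be >= 1")
  T_ <- n_occasions %||%
    sum(layout$census_months >= layout$change_month)
  if (T_ < 2) stop_param("need at least 2 occasions")
  set.seed(substream_seed(seed, 2L))
  K <- length(params$strata)
  n <- as.integer(n_individuals)
  first <- sample.int(T_ - 1L, n, replace = TRUE)
  state <- sample.int(K, n, replace = TRUE)
  hist <- matrix(0L, n, T_)
  hist[cbind(seq_len(n), first)] <- state
  alive <- rep(TRUE, n)
  for (t in seq_len(T_)[-1L]) {
    act <- alive & first < t
    if (!any(act)) next
    surv <- stats::runif(n) < params$S[state]
    alive[act & !surv] <- FALSE
    act <- alive & first < t
    if (any(act)) {
      # move along the Psi row of the current stratum, then detect
      u <- stats::runif(n)
      cum <- t(apply(params$Psi, 1L, cumsum))
      newstate <- state
      for (k in seq_len(K)) {
        ik <- act & state == k
        newstate[ik] <- findInterval(u[ik], cum[k, ], left.open = TRUE) + 1L
      }
      state[act] <- newstate[act]
      det <- act & stats::runif(n) < params$p[state]
      hist[cbind(which(det), rep(t, sum(det)))] <- state[det]
    }
  }
  capture_histories(hist, params$strata)
}

#' Write / read MARK-style multistate encounter histories
#'
#' \code{write_inp} writes one line per individual in the MARK \code{.inp}
#' multistate format (e.g. \code{"A0B 1;"}); \code{read_inp} parses such a
#' file back into a \code{\link{capture_histories}} object, expanding
#' frequency counts.
#'
#' @param histories a \code{\link{capture_histories}} object.
#' @param path file path.
#' @param strata stratum labels to associate with letters A, B, ... when
#'   reading.
#' @return \code{read_inp} returns a \code{\link{capture_histories}};
#'   \code{write_inp} returns \code{path} invisibly.
#' @export
write_inp <- function(histories, path) {
  lines <- paste0(as.character.capture_histories(histories), " 1;")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_inp
#' @export
read_inp <- function(path, strata) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec("^([A-Z0]+)\\s+(\\d+)\\s*;", lines))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop_param("malformed .inp line: ", lines[which(bad)[1L]])
  hs <- vapply(m, `[`, "", 2L)
  freq <- as.integer(vapply(m, `[`, "", 3L))
  hs <- rep(hs, freq)
  letters_ <- LETTERS[seq_along(strata)]
  mat <- t(vapply(strsplit(hs, ""), function(ch) {
    out <- match(ch, letters_)
    out[is.na(out)] <- 0L
    out
  }, integer(nchar(hs[1L]))))
  capture_histories(mat, strata)
}
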