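#' Square-root transform abundances
#'
#' Element-wise square root of a non-negative abundance table, applied once
#' before ordination to damp large differences in total abundance between
#' samples and species.
#'
#' @param Y non-negative matrix or data frame of abundances.
#' @return Transformed matrix.
#' @export
sqrt_transform <- function(Y) {
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop_param("abundances must be non-negative")
  sqrt(Y)
}

# Chi-square standardization of correspondence analysis:
# Q = diag(1/sqrt(r)) (P - r c') diag(1/sqrt(c)) with P = Y/sum(Y).
# Rows of Q are orthogonal to sqrt(r), so the trivial axis is already
# removed; weighted regressions on Q become ordinary projections of the
# sqrt(r)-scaled design.
ca_standardize <- function(Y) {
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop_param("abundances must be non-negative")
  zr <- rowSums(Y) == 0
  zc <- colSums(Y) == 0
  if (any(zr) || any(zc)) {
    stop_param("all-zero sample rows/species columns must be filtered ",
               "before ordination (", sum(zr), " rows, ", sum(zc), " columns)")
  }
  P <- Y / sum(Y)
  r <- rowSums(P)
  cm <- colSums(P)
  Q <- (P - outer(r, cm)) / sqrt(outer(r, cm))
  list(Q = Q, r = r, c = cm)
}

#' Partial canonical correspondence analysis
#'
#' Correspondence-analysis ordination of a sample-by-species table
#' constrained by one factor after conditioning out another: the chi-square
#' standardized table is first projected onto the condition (weighted by row
#' masses); the residual is then projected onto the constraint, and the
#' constrained part is eigen-decomposed into canonical axes.  The inertia
#' decomposition (conditional + constrained + residual = total) and
#' \eqn{R^2} = constrained / total inertia are returned.
#'
#' @param Y non-negative sample-by-species abundance matrix (transform
#'   first with \code{\link{sqrt_transform}} if desired).
#' @param constraint factor of interest (e.g. treatment), one value per
#'   sample.
#' @param condition factor to condition out (e.g. year), or \code{NULL} for
#'   plain CCA.
#' @return An object of class \code{"pcca"}: total, conditional,
#'   constrained and residual inertia, \code{R2}, canonical eigenvalues,
#'   site and species scores on the constrained axes, and the model
#'   degrees of freedom.
#' @export
pcca <- function(Y, constraint, condition = NULL) {
  std <- ca_standardize(Y)
  Q <- std$Q
  n <- nrow(Q)
  total <- sum(Q^2)
  if (total < 1e-12) {
    stop_degenerate("composition identical across samples: total inertia 0")
  }
  sw <- sqrt(std$r)
  constraint <- factor(constraint)
  Zd <- if (!is.null(condition)) {
    stats::model.matrix(~ factor(condition))
  } else {
    matrix(1, n, 1)
  }
  qz <- qr(Zd * sw)
  fitZ <- qr.fitted(qz, Q)
  conditional <- sum(fitZ^2)
  Q1 <- Q - fitZ
  Xd <- stats::model.matrix(~ 0 + constraint)
  Xw <- Xd * sw
  Xr <- Xw - qr.fitted(qz, Xw)
  qx <- qr(Xr)
  q_rank <- qx$rank
  if (max(abs(Xr)) < 1e-8 * max(abs(Xw))) q_rank <- 0L
  if (q_rank == 0L) {
    stop_param("constraint is collinear with the condition: levels ",
               paste(levels(constraint), collapse = ", "),
               " are aliased")
  }
  fitX <- qr.fitted(qx, Q1)
  constrained <- sum(fitX^2)
  residual <- sum((Q1 - fitX)^2)
  sv <- svd(fitX, nu = q_rank, nv = q_rank)
  eig <- sv$d[seq_len(q_rank)]^2
  site_scores <- sweep(sv$u, 1, sw, "/")[, seq_len(q_rank), drop = FALSE] *
    rep(sv$d[seq_len(q_rank)], each = n)
  species_scores <- sweep(sv$v, 1, sqrt(std$c), "/")
  df_condition <- qz$rank
  df_resid <- n - df_condition - q_rank
  structure(
    list(total_inertia = total, conditional_inertia = conditional,
         constrained_inertia = constrained, residual_inertia = residual,
         R2 = constrained / total, eig = eig,
         site_scores = site_scores, species_scores = species_scores,
         rank = q_rank, df_condition = df_condition, df_resid = df_resid,
         n_samples = n),
    class = "pcca")
}

#' @export
print.pcca <- function(x, ...) {
  cat("Partial CCA:", x$n_samples, "samples\n")
  cat(sprintf("  total inertia       %.5f\n", x$total_inertia))
  cat(sprintf("  conditional         %.5f\n", x$conditional_inertia))
  cat(sprintf("  constrained         %.5f  (R2 = %.4f)\n",
              x$constrained_inertia, x$R2))
  cat(sprintf("  residual            %.5f\n", x$residual_inertia))
  if (!is.null(x$pseudo_F)) {
    cat(sprintf("  pseudo-F = %.3f, permutation p = %.4g (%d permutations)\n",
                x$pseudo_F, x$perm_p, x$n_perm))
  }
  invisible(x)
}

#' Permutation test for the constrained effect of a partial CCA
#'
#' Tests the constraint's effect with the pseudo-F statistic
#' \eqn{F = (I_{constr}/q) / (I_{resid}/df_{resid})}.  The null
#' distribution permutes the condition-model residuals of the standardized
#' table across samples (reduced-model permutation), re-projecting the
#' condition each time; \code{scheme = "within_year"} restricts the
#' permutation to blocks of the condition factor.
#'
#' @inheritParams pcca
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @param scheme \code{"free"} or \code{"within_year"} (blocks of
#'   \code{condition}).
#' @return A \code{\link{pcca}} object with added \code{pseudo_F},
#'   \code{perm_p}, \code{n_perm} and \code{scheme}.
#' @export
permutation_test <- function(Y, constraint, condition = NULL, n_perm = 999,
                             seed = 1, scheme = c("free", "within_year")) {
  scheme <- match.arg(scheme)
  if (n_perm < 99) stop_param("n_perm must be >= 99")
  obs <- pcca(Y, constraint, condition)
  std <- ca_standardize(Y)
  Q <- std$Q
  n <- nrow(Q)
  sw <- sqrt(std$r)
  Zd <- if (!is.null(condition)) {
    stats::model.matrix(~ factor(condition))
  } else matrix(1, n, 1)
  qz <- qr(Zd * sw)
  fitZ <- qr.fitted(qz, Q)
  Q1 <- Q - fitZ
  Xr <- stats::model.matrix(~ 0 + factor(constraint)) * sw
  Xr <- Xr - qr.fitted(qz, Xr)
  qx <- qr(Xr)
  q_rank <- qx$rank
  fstat <- function(Q1p) {
    fitX <- qr.fitted(qx, Q1p)
    constr <- sum(fitX^2)
    resid <- sum((Q1p - fitX)^2)
    (constr / q_rank) / (resid / obs$df_resid)
  }
  F_obs <- fstat(Q1)
  if (scheme == "within_year") {
    if (is.null(condition)) stop_param("within_year scheme needs a condition")
    blocks <- split(seq_len(n), factor(condition))
    if (any(lengths(blocks) < 2)) {
      stop_param("within_year permutation impossible: a condition block ",
                 "has fewer than 2 samples")
    }
  }
  set.seed(substream_seed(seed, 7L))
  F_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- if (scheme == "free") {
      sample.int(n)
    } else {
      idx <- seq_len(n)
      for (blk in blocks) idx[blk] <- blk[sample.int(length(blk))]
      idx
    }
    Qp <- fitZ + Q1[perm, , drop = FALSE]
    # re-project the condition on the permuted table
    fitZp <- qr.fitted(qz, Qp)
    F_perm[b] <- fstat(Qp - fitZp)
  }
  obs$pseudo_F <- F_obs
  obs$perm_p <- (1 + sum(F_perm >= F_obs - 1e-12)) / (n_perm + 1)
  obs$n_perm <- n_perm
  obs$scheme <- scheme
  obs$F_perm <- F_perm
  obs
}

#' Seasonal plant pCCA
#'
#' Convenience wrapper running \code{\link{permutation_test}} separately per
#' season of a simulated or ingested plant table (samples x species with
#' \code{plot}, \code{year}, \code{season}, \code{treatment} factors),
#' square-root transforming the abundances, constraining by treatment and
#' conditioning on year.
#'
#' @param plants plant table as returned by \code{\link{simulate_plants}}.
#' @param n_perm,seed,scheme passed to \code{\link{permutation_test}}.
#' @return Named list of \code{\link{pcca}} results, one per season, plus a
#'   \code{summary} data frame (season, R2, pseudo_F, perm_p, n_perm).
#' @export
plant_pcca <- function(plants, n_perm = 999, seed = 1, scheme = "free") {
  meta_cols <- c("sample", "plot", "year", "season", "treatment")
  sp_cols <- setdiff(names(plants), meta_cols)
  out <- list()
  for (ssn in unique(plants$season)) {
    d <- plants[plants$season == ssn, , drop = FALSE]
    Y <- sqrt_transform(d[, sp_cols, drop = FALSE])
    keep_c <- colSums(Y) > 0
    keep_r <- rowSums(Y) > 0
    res <- permutation_test(Y[keep_r, keep_c, drop = FALSE],
                            constraint = d$treatment[keep_r],
                            condition = d$year[keep_r],
                            n_perm = n_perm, seed = seed, scheme = scheme)
    out[[as.character(ssn)]] <- res
  }
  out$summary <- data.frame(
    season = setdiff(names(out), "summary"),
    R2 = vapply(out[setdiff(names(out), "summary")], `[[`, 0, "R2"),
    pseudo_F = vapply(out[setdiff(names(out), "summary")], `[[`, 0, "pseudo_F"),
    perm_p = vapply(out[setdiff(names(out), "summary")], `[[`, 0, "perm_p"),
    n_perm = n_perm, row.names = NULL)
  out
}
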