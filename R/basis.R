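#' Penalized spline smooth specification
#'
#' Describes one smooth term: a cubic B-spline of a covariate with a
#' derivative-based quadratic penalty, optionally restricted to one level of
#' a by-factor (treatment or plot) and optionally carrying a null-space
#' shrinkage penalty so the whole smooth (including its polynomial null
#' space) can be shrunk to zero.
#'
#' @param covariate name of the covariate the smooth applies to.
#' @param by factor level the smooth is restricted to, or \code{NULL}.
#' @param k basis dimension before centering (>= 3).
#' @param penalty_order derivative order penalized (1 or 2).
#' @param shrink if \code{TRUE}, add a penalty on the penalty null space so
#'   large smoothing parameters shrink the term to zero (used for plot-level
#'   deviation smooths, which behave like random smooth deviations).
#' @return An object of class \code{"smooth_spec"}.
#' @export
smooth_spec <- function(covariate = "time", by = NULL, k = 10,
                        penalty_order = 2, shrink = FALSE) {
  if (k < 3) stop_param("k must be >= 3")
  if (!penalty_order %in% c(1, 2)) stop_param("penalty_order must be 1 or 2")
  structure(list(covariate = covariate, by = by, k = as.integer(k),
                 penalty_order = as.integer(penalty_order), shrink = shrink),
            class = "smooth_spec")
}

# Gauss-Legendre nodes/weights on [a, b]; 3 points are exact to degree 5,
# enough for products of spline derivatives of orders 1 and 2.
gauss3 <- function(a, b) {
  x <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  w <- c(5, 8, 5) / 9
  list(x = (a + b) / 2 + (b - a) / 2 * x, w = (b - a) / 2 * w)
}

#' Build a penalized B-spline basis
#'
#' Evaluates a cubic B-spline basis (quadratic when \code{k = 3}) on
#' quantile-spaced knots at the data points, computes the derivative-based
#' penalty \eqn{S = \int f^{(d)}(x)^2 dx} exactly by Gauss quadrature, and
#' (by default) applies a sum-to-zero centering constraint so the smooth is
#' identifiable next to an intercept.
#'
#' @param x covariate values (need at least \code{k} distinct values).
#' @param spec a \code{\link{smooth_spec}}.
#' @param center apply the sum-to-zero constraint (drops one column).
#' @return An object of class \code{"basis_block"} with elements \code{X}
#'   (design columns), \code{S} (penalty), \code{null_dim} (penalty
#'   null-space dimension after centering and shrinkage), plus the knot and
#'   constraint information needed to evaluate the basis at new points.
#' @examples
#' b <- build_basis(seq(0, 1, length.out = 50), smooth_spec(k = 10))
#' dim(b$X)   # 50 x 9
#' @export
build_basis <- function(x, spec, center = TRUE) {
  ux <- sort(unique(x))
  if (length(ux) < spec$k) {
    stop_degenerate("need at least k = ", spec$k, " distinct covariate ",
                    "values, got ", length(ux))
  }
  ord <- min(4L, spec$k)
  n_inner <- spec$k - ord
  inner <- if (n_inner > 0) {
    stats::quantile(ux, probs = seq_len(n_inner) / (n_inner + 1), names = FALSE)
  } else numeric(0)
  knots <- c(rep(min(ux), ord), inner, rep(max(ux), ord))
  X <- splines::splineDesign(knots, x, ord = ord)
  S <- penalty_matrix(knots, ord, spec$penalty_order)
  Z <- NULL
  if (center) {
    cs <- colSums(X)
    Z <- qr.Q(qr(matrix(cs, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
    X <- X %*% Z
    S <- crossprod(Z, S %*% Z)
  }
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  null_idx <- which(es$values < max(es$values) * 1e-10)
  null_dim <- length(null_idx)
  M <- NULL
  if (null_dim > 0) {
    U0 <- es$vectors[, null_idx, drop = FALSE]
    M <- max(es$values) * tcrossprod(U0)
    if (spec$shrink) {
      # fold the null-space penalty into S: the whole term shrinks to zero
      S <- S + M
      M <- NULL
      null_dim <- 0L
    }
  }
  structure(list(spec = spec, X = X, S = S, M = M, knots = knots, ord = ord,
                 Z = Z, null_dim = null_dim, x_range = range(ux)),
            class = "basis_block")
}

# Gram matrix of order-d derivatives of the B-spline basis, integrated over
# the knot span (exact Gauss-Legendre quadrature per knot interval).
penalty_matrix <- function(knots, ord, d) {
  nb <- length(knots) - ord
  S <- matrix(0, nb, nb)
  breaks <- unique(knots)
  for (i in seq_len(length(breaks) - 1L)) {
    gq <- gauss3(breaks[i], breaks[i + 1L])
    D <- splines::splineDesign(knots, gq$x, ord = ord, derivs = d)
    S <- S + crossprod(D * sqrt(gq$w))
  }
  S
}

#' Evaluate a basis block at new covariate values
#'
#' @param block a \code{\link{build_basis}} result.
#' @param newx covariate values within the fitted range.
#' @return Matrix of design columns (centering constraint applied).
#' @export
eval_basis <- function(block, newx) {
  if (any(newx < block$x_range[1] - 1e-8 | newx > block$x_range[2] + 1e-8)) {
    stop_param("evaluation points outside the fitted covariate range")
  }
  newx <- pmin(pmax(newx, block$x_range[1]), block$x_range[2])
  X <- splines::splineDesign(block$knots, newx, ord = block$ord)
  if (!is.null(block$Z)) X <- X %*% block$Z
  X
}
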