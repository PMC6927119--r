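#' Symmetrically normalized graph Laplacian
#'
#' \code{L = I - D^{-1/2} S D^{-1/2}} with D the diagonal of row sums of S
#' (zero-degree rows get degree 1 so the scaling stays finite). The quadratic
#' form of L penalizes score differences between similar nodes.
#'
#' @param sim symmetric nonnegative similarity matrix.
#' @return symmetric positive semidefinite Laplacian matrix.
#' @export
normalized_laplacian <- function(sim) {
  if (any(sim < 0)) stop("similarity must be nonnegative")
  if (max(abs(sim - t(sim))) > 1e-8) stop("similarity must be symmetric")
  d <- rowSums(sim)
  d[d == 0] <- 1
  isq <- 1 / sqrt(d)
  l <- diag(nrow(sim)) - sim * outer(isq, isq)
  (l + t(l)) / 2
}

#' Bidirectional propagation objective
#'
#' \code{||F - Y||_F^2 + lambda_m/2 tr(F' L_m F) + lambda_d/2 tr(F L_d F')}:
#' fidelity to the known interactions plus Laplacian smoothness over the
#' miRNA graph (rows) and the disease graph (columns). Convex in F.
#'
#' @param f score matrix.
#' @param y known-interaction matrix (same shape).
#' @param l_m,l_d normalized Laplacians of the miRNA and disease similarity
#'   networks.
#' @param lambda_m,lambda_d nonnegative regularization weights.
#' @return scalar objective value (>= 0 for PSD Laplacians).
#' @export
propagation_objective <- function(f, y, l_m, l_d, lambda_m, lambda_d) {
  sum((f - y)^2) +
    lambda_m / 2 * sum(f * (l_m %*% f)) +
    lambda_d / 2 * sum(f * (f %*% l_d))
}

#' Gradient of the bidirectional propagation objective
#'
#' \code{2 (F - Y) + lambda_m L_m F + lambda_d F L_d}; vanishes at the unique
#' minimizer for nonnegative weights.
#'
#' @inheritParams propagation_objective
#' @return gradient matrix of the same shape as \code{f}.
#' @export
propagation_gradient <- function(f, y, l_m, l_d, lambda_m, lambda_d) {
  2 * (f - y) + lambda_m * (l_m %*% f) + lambda_d * (f %*% l_d)
}

#' Solve the propagation objective by AdaGrad
#'
#' Gradient descent from \code{F0 = Y} with per-element step sizes
#' \code{eta0 / sqrt(G + eps)}, G the running sum of squared gradients.
#' Stops when the relative objective change falls below \code{tol} or at
#' \code{max_iter}. If the objective increases for 10 consecutive iterations
#' the base step is halved and the run restarted; repeated divergence is an
#' error. Deterministic.
#'
#' @inheritParams propagation_objective
#' @param y known-interaction matrix (initial F).
#' @param eta0 base learning rate (default 0.1).
#' @param tol relative objective-change tolerance (default 1e-6).
#' @param max_iter iteration cap (default 1000).
#' @param adagrad_eps numerical floor inside the square root (default 1e-8).
#' @return list with \code{f} (the score matrix), \code{objective} (final
#'   value), \code{iterations}, \code{converged}.
#' @export
adagrad_solve <- function(y, l_m, l_d, lambda_m, lambda_d, eta0 = 0.1,
                          tol = 1e-6, max_iter = 1000, adagrad_eps = 1e-8) {
  stopifnot(eta0 > 0, tol > 0, lambda_m >= 0, lambda_d >= 0)
  for (attempt in 1:6) {
    f <- y
    g2 <- matrix(0, nrow(y), ncol(y))
    obj <- propagation_objective(f, y, l_m, l_d, lambda_m, lambda_d)
    bad <- 0L
    it <- 0L
    converged <- FALSE
    diverged <- FALSE
    while (it < max_iter) {
      it <- it + 1L
      g <- propagation_gradient(f, y, l_m, l_d, lambda_m, lambda_d)
      g2 <- g2 + g^2
      f <- f - eta0 / sqrt(g2 + adagrad_eps) * g
      obj_new <- propagation_objective(f, y, l_m, l_d, lambda_m, lambda_d)
      if (obj_new > obj) {
        bad <- bad + 1L
        if (bad >= 10L) { diverged <- TRUE; break }
      } else bad <- 0L
      if (abs(obj - obj_new) <= tol * max(obj, .Machine$double.eps)) {
        obj <- obj_new
        converged <- TRUE
        break
      }
      obj <- obj_new
    }
    if (!diverged)
      return(list(f = f, objective = obj, iterations = it,
                  converged = converged, eta0 = eta0))
    eta0 <- eta0 / 2
  }
  stop("AdaGrad diverged repeatedly despite step halving")
}

#' Closed-form minimizer of the propagation objective
#'
#' Solves the stationarity condition
#' \code{(2I + lambda_m L_m) F + lambda_d F L_d = 2 Y} exactly through the
#' vectorized Kronecker linear system. Dense: intended for small problems and
#' for validating the iterative solver.
#'
#' @inheritParams propagation_objective
#' @return the exact score matrix.
#' @export
propagation_exact <- function(y, l_m, l_d, lambda_m, lambda_d) {
  nm <- nrow(y); nd <- ncol(y)
  a <- kronecker(diag(nd), 2 * diag(nm) + lambda_m * l_m) +
    lambda_d * kronecker(t(l_d), diag(nm))
  matrix(solve(a, as.vector(2 * y)), nm, nd, dimnames = dimnames(y))
}
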