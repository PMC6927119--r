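#' Fit the kernel-neighbourhood multi-network propagation model
#'
#' Runs the full prediction pipeline on a binary miRNA--disease interaction
#' matrix and a pair of base similarity networks:
#' \enumerate{
#'   \item WKNNP correction of the sparse interaction profiles
#'     (\code{\link{wknnp}}, K and alpha fixed at their standard values by
#'     default);
#'   \item kernel neighbourhood similarity of the corrected miRNA and disease
#'     profiles (\code{\link{ksns_similarity}});
#'   \item diffusion-embedding fusion of each base similarity with its kernel
#'     neighbourhood similarity (\code{\link{fuse_similarity}});
#'   \item bidirectional label propagation over both fused graphs by AdaGrad
#'     minimization of the Laplacian-regularized objective
#'     (\code{\link{adagrad_solve}}).
#' }
#'
#' @param x binary interaction matrix, miRNAs in rows, diseases in columns.
#'   Row/column names label the entities.
#' @param mirna_sim miRNA functional similarity matrix (rows of \code{x}).
#' @param disease_sim disease semantic similarity matrix (columns of \code{x}).
#' @param lambda Laplacian regularization weight, applied to both graphs
#'   unless \code{lambda_m}/\code{lambda_d} are given (default 1).
#' @param lambda_m,lambda_d per-graph regularization weights.
#' @param k,alpha WKNNP neighbour count and decay factor (defaults 15, 0.8).
#' @param pn neighbour proportion for the kernel neighbourhood similarity
#'   (default 0.5).
#' @param mu1,mu2 KSNS penalty parameters (default 4 each).
#' @param fusion_dim embedding dimension for fusion; default
#'   \code{min(100, N - 1)} per side.
#' @param restart_p restart probability of the fusion diffusion (default 0.5).
#' @param propagate_on \code{"modified"} (default) propagates the
#'   WKNNP-corrected matrix; \code{"raw"} propagates the binary matrix.
#' @param wknnp_weight neighbour weight form for WKNNP, see
#'   \code{\link{wknnp_axis}}.
#' @param control list of solver controls overriding
#'   \code{\link{knmbp_control}} defaults.
#'
#' @return An object of class \code{"knmbp"}: list with \code{scores} (the
#'   predicted score matrix F), \code{y} (propagation input), \code{x},
#'   \code{xhat}, \code{similarities} (list \code{mirna_base},
#'   \code{disease_base}, \code{mirna_kernel}, \code{disease_kernel},
#'   \code{mirna_fused}, \code{disease_fused}), \code{params},
#'   \code{solver} (iterations/convergence), and \code{call}.
#'
#' @examples
#' set.seed(1)
#' dat <- simulate_knmbp_data(n_mirnas = 25, n_diseases = 20, n_genes = 40,
#'                            latent_rank = 2, seed = 1)
#' fit <- knmbp(dat$x, dat$mirna_sim, dat$disease_sim, k = 5)
#' fit
#' head(predict(fit, diseases = colnames(dat$x)[1], n = 5))
#' @export
knmbp <- function(x, mirna_sim, disease_sim, lambda = 1,
                  lambda_m = lambda, lambda_d = lambda,
                  k = 15, alpha = 0.8, pn = 0.5, mu1 = 4, mu2 = 4,
                  fusion_dim = NULL, restart_p = 0.5,
                  propagate_on = c("modified", "raw"),
                  wknnp_weight = c("similarity", "rank"),
                  control = list()) {
  propagate_on <- match.arg(propagate_on)
  wknnp_weight <- match.arg(wknnp_weight)
  ctrl <- utils::modifyList(knmbp_control(), control)
  x <- as.matrix(x)
  stopifnot(nrow(mirna_sim) == nrow(x), nrow(disease_sim) == ncol(x))

  xhat <- wknnp(x, mirna_sim, disease_sim, k = k, alpha = alpha,
                weight = wknnp_weight)
  si_m <- ksns_similarity(xhat, mirna_sim, pn = pn, mu1 = mu1, mu2 = mu2,
                          tol = ctrl$ksns_tol, max_iter = ctrl$ksns_max_iter)
  si_d <- ksns_similarity(t(xhat), disease_sim, pn = pn, mu1 = mu1, mu2 = mu2,
                          tol = ctrl$ksns_tol, max_iter = ctrl$ksns_max_iter)
  s_m <- fuse_similarity(list(as.matrix(mirna_sim), si_m), d = fusion_dim,
                         restart_p = restart_p)
  s_d <- fuse_similarity(list(as.matrix(disease_sim), si_d), d = fusion_dim,
                         restart_p = restart_p)
  l_m <- normalized_laplacian(s_m)
  l_d <- normalized_laplacian(s_d)
  y <- if (propagate_on == "modified") xhat else x
  sol <- adagrad_solve(y, l_m, l_d, lambda_m = lambda_m, lambda_d = lambda_d,
                       eta0 = ctrl$eta0, tol = ctrl$solver_tol,
                       max_iter = ctrl$solver_max_iter,
                       adagrad_eps = ctrl$adagrad_eps)
  structure(list(
    scores = sol$f, y = y, x = x, xhat = xhat,
    similarities = list(mirna_base = as.matrix(mirna_sim),
                        disease_base = as.matrix(disease_sim),
                        mirna_kernel = si_m, disease_kernel = si_d,
                        mirna_fused = s_m, disease_fused = s_d),
    params = list(lambda_m = lambda_m, lambda_d = lambda_d, k = k,
                  alpha = alpha, pn = pn, mu1 = mu1, mu2 = mu2,
                  fusion_dim = fusion_dim, restart_p = restart_p,
                  propagate_on = propagate_on, wknnp_weight = wknnp_weight),
    solver = sol[c("objective", "iterations", "converged", "eta0")],
    call = match.call()
  ), class = "knmbp")
}

#' Solver control settings for \code{\link{knmbp}}
#'
#' @param ksns_tol,ksns_max_iter convergence controls of the KSNS
#'   multiplicative updates.
#' @param eta0,solver_tol,solver_max_iter,adagrad_eps AdaGrad controls.
#' @return named list of control values.
#' @export
knmbp_control <- function(ksns_tol = 1e-6, ksns_max_iter = 500,
                          eta0 = 0.1, solver_tol = 1e-6,
                          solver_max_iter = 1000, adagrad_eps = 1e-8) {
  list(ksns_tol = ksns_tol, ksns_max_iter = ksns_max_iter, eta0 = eta0,
       solver_tol = solver_tol, solver_max_iter = solver_max_iter,
       adagrad_eps = adagrad_eps)
}

#' @export
print.knmbp <- function(x, ...) {
  cat("Kernel neighbourhood multi-network propagation fit\n")
  cat(sprintf("  %d miRNAs x %d diseases, %d known interactions (density %.3f)\n",
              nrow(x$x), ncol(x$x), sum(x$x), mean(x$x)))
  cat(sprintf("  lambda_m = %g, lambda_d = %g, pn = %g, mu1 = %g, mu2 = %g\n",
              x$params$lambda_m, x$params$lambda_d, x$params$pn,
              x$params$mu1, x$params$mu2))
  cat(sprintf("  solver: %d iterations, objective %.6g%s\n",
              x$solver$iterations, x$solver$objective,
              if (x$solver$converged) "" else " (iteration cap reached)"))
  invisible(x)
}

#' @export
summary.knmbp <- function(object, ...) {
  known <- object$x == 1
  out <- list(
    dim = dim(object$x), n_known = sum(known), density = mean(object$x),
    params = object$params, solver = object$solver,
    score_known = summary(object$scores[known]),
    score_unknown = summary(object$scores[!known]))
  class(out) <- "summary.knmbp"
  out
}

#' @export
print.summary.knmbp <- function(x, ...) {
  cat(sprintf("knmbp fit: %d miRNAs x %d diseases, %d known pairs\n",
              x$dim[1], x$dim[2], x$n_known))
  cat("Scores at known pairs:\n"); print(x$score_known)
  cat("Scores at unknown pairs:\n"); print(x$score_unknown)
  invisible(x)
}

#' @export
coef.knmbp <- function(object, ...) object$scores

#' @export
fitted.knmbp <- function(object, ...) object$scores

#' @export
residuals.knmbp <- function(object, ...) object$scores - object$y

#' Ranked candidate predictions from a fitted model
#'
#' Returns predicted interaction scores as a long table, optionally restricted
#' to chosen diseases/miRNAs, ranked per disease. Known interactions can be
#' kept (flagged) or dropped from the candidate lists.
#'
#' @param object a fitted \code{\link{knmbp}} model.
#' @param diseases,mirnas optional identifier subsets.
#' @param n keep the top n candidates per disease (default all).
#' @param exclude_known drop pairs already known to interact (default TRUE).
#' @param ... unused.
#' @return data frame with columns \code{disease}, \code{mirna}, \code{score},
#'   \code{rank}, \code{known}, sorted by disease then descending score.
#' @export
predict.knmbp <- function(object, diseases = NULL, mirnas = NULL, n = Inf,
                          exclude_known = TRUE, ...) {
  f <- object$scores
  if (is.null(rownames(f))) rownames(f) <- paste0("m", seq_len(nrow(f)))
  if (is.null(colnames(f))) colnames(f) <- paste0("d", seq_len(ncol(f)))
  if (is.null(diseases)) diseases <- colnames(f)
  if (is.null(mirnas)) mirnas <- rownames(f)
  out <- do.call(rbind, lapply(diseases, function(dis) {
    sc <- f[mirnas, dis]
    kn <- object$x[mirnas, dis] == 1
    df <- data.frame(disease = dis, mirna = mirnas, score = sc, known = kn,
                     row.names = NULL)
    if (exclude_known) df <- df[!df$known, , drop = FALSE]
    df <- df[order(-df$score), , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    utils::head(df, n)
  }))
  rownames(out) <- NULL
  out[, c("disease", "mirna", "score", "rank", "known")]
}

#' Plot a fitted model's score separation
#'
#' Density of predicted scores at known interactions versus unknown pairs; a
#' well-behaved fit concentrates known pairs at high scores.
#'
#' @param x a fitted \code{\link{knmbp}} model.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @export
plot.knmbp <- function(x, ...) {
  known <- x$scores[x$x == 1]
  unknown <- x$scores[x$x == 0]
  dk <- stats::density(known)
  du <- stats::density(unknown)
  graphics::plot(du, col = "grey40", main = "Predicted score separation",
                 xlab = "score", ylim = range(0, dk$y, du$y), ...)
  graphics::lines(dk, col = "firebrick")
  graphics::legend("topright", legend = c("known pairs", "unknown pairs"),
                   col = c("firebrick", "grey40"), lty = 1, bty = "n")
  invisible(x)
}
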